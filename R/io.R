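#' Construct/validate a feature table
#'
#' A `feature_table` is a data.frame with a unique `case_id` column, an
#' optional `label`/`subtype` column pair, and one numeric column per
#' registered panel feature.
#'
#' @param df a data.frame.
#' @return The validated data.frame with class `feature_table` prepended.
#' @export
feature_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"case_id" %in% names(df)) stop("feature table needs a 'case_id' column")
  if (anyDuplicated(df$case_id))
    stop("duplicate case ids: ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "))
  feats <- setdiff(names(df), c("case_id", "label", "subtype"))
  unknown <- setdiff(feats, feature_panel())
  if (length(unknown))
    stop("unknown feature name(s) not in the registered panel: ",
         paste(unknown, collapse = ", "))
  if (!all(vapply(df[feats], is.numeric, logical(1))))
    stop("feature columns must be numeric")
  class(df) <- c("feature_table", "data.frame")
  df
}

# Feature (non-metadata) column names of a feature table, in table order.
feature_columns <- function(tab) {
  setdiff(names(tab), c("case_id", "label", "subtype"))
}

#' Write / read a NIfTI volume or mask
#'
#' Volumes are stored as double-precision NIfTI so that save/load
#' round-trips are bit exact; masks are stored as 8-bit 0/1.
#'
#' @param x an [image_volume()] or [segmentation_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an `image_volume`; `read_mask` a `segmentation_mask`.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("image_volume", "segmentation_mask")))
  vox <- if (is.logical(x$voxels))
    array(as.integer(x$voxels), dim = dim(x$voxels)) else x$voxels
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- x$spacing_mm
  dt <- if (is.logical(x$voxels)) "uint8" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname write_volume
#' @param path input path.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: '", path, "' not found")
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: '", path, "' not found")
  img <- RNifti::readNifti(path)
  segmentation_mask(array(as.numeric(img) > 0, dim = dim(img)),
                    spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Load one lesion case from NIfTI files
#'
#' Reads the volume and mask(s), checks grid alignment (any shape or
#' spacing mismatch is an error -- no silent resampling) and that the
#' primary mask is nonempty.
#'
#' @param volume_path,mask_path,mask2_path NIfTI file paths; `mask2_path`
#'   is optional.
#' @param case_id identifier for the returned case.
#' @param label,subtype optional labels.
#' @return A [lesion_case()].
#' @export
load_case <- function(volume_path, mask_path, mask2_path = NULL,
                      case_id = "case", label = NA_character_,
                      subtype = NULL) {
  vol <- read_volume(volume_path)
  m1 <- read_mask(mask_path)
  m2 <- if (!is.null(mask2_path)) read_mask(mask2_path) else NULL
  lesion_case(case_id, vol, m1, m2, label = label, subtype = subtype)
}

#' Write / read a feature table as CSV with a JSON sidecar
#'
#' The CSV stores values at full double precision (17 significant
#' digits); the sidecar (`<path>.json`) records panel version and any
#' extraction settings for provenance. Reading validates the schema
#' (unique ids, registered feature names) and restores numeric types.
#'
#' @param tab a [feature_table()].
#' @param path CSV output path.
#' @param settings named list stored in the sidecar.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(tab, path, settings = list()) {
  tab <- feature_table(as.data.frame(tab))
  out <- tab
  feats <- feature_columns(tab)
  for (f in feats) out[[f]] <- sprintf("%.17g", tab[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  sidecar <- c(list(panel_version = attr(feature_panel(), "panel_version"),
                    n_cases = nrow(tab), features = feats), settings)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("cannot read feature table: '", path, "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  feats <- setdiff(names(df), c("case_id", "label", "subtype"))
  for (f in feats) df[[f]] <- as.numeric(df[[f]])
  feature_table(df)
}

#' Write a phantom cohort to disk
#'
#' Saves each case as NIfTI volume/mask pairs plus a cohort manifest CSV
#' (`case_id`, `label`, `subtype`, `reader2_present`, file names).
#'
#' @param cases list of voxelized [lesion_case()]s.
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cases, function(cs) {
    vfile <- paste0(cs$case_id, "_vol.nii.gz")
    mfile <- paste0(cs$case_id, "_mask1.nii.gz")
    write_volume(cs$volume, file.path(dir, vfile))
    write_volume(cs$mask_reader1, file.path(dir, mfile))
    m2file <- NA_character_
    if (!is.null(cs$mask_reader2)) {
      m2file <- paste0(cs$case_id, "_mask2.nii.gz")
      write_volume(cs$mask_reader2, file.path(dir, m2file))
    }
    data.frame(case_id = cs$case_id, label = cs$label,
               subtype = if (is.null(cs$subtype)) NA_character_
                         else cs$subtype,
               reader2_present = !is.null(cs$mask_reader2),
               volume_file = vfile, mask_file = mfile,
               mask2_file = m2file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and NIfTI files.
#' @return List of [lesion_case()]s.
#' @export
read_cohort <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    load_case(file.path(dir, mf$volume_file[i]),
              file.path(dir, mf$mask_file[i]),
              if (!is.na(mf$mask2_file[i]))
                file.path(dir, mf$mask2_file[i]) else NULL,
              case_id = mf$case_id[i], label = mf$label[i],
              subtype = if (is.na(mf$subtype[i])) NULL else mf$subtype[i])
  })
}

#' Serialize / restore a fitted radiomic score model as JSON
#'
#' Stores normalization parameters, the selected penalty, intercept and
#' coefficients, and the CV curve; [read_score_model()] restores an object
#' usable with [predict.radscore()].
#'
#' @param model a [fit_radiomic_score()] result.
#' @param path JSON output path.
#' @return `write_score_model` returns `path` invisibly;
#'   `read_score_model` a `radscore` object.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "radscore"))
  payload <- list(
    feature_names = model$feature_names,
    normalization = list(mean = as.list(model$normalization$mean),
                         sd = as.list(model$normalization$sd)),
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    alpha = model$alpha, lambda_selected = model$lambda_selected,
    lambda_grid = model$lambda_grid, cv_folds = model$cv_folds,
    cv_curve = model$cv_curve, positive_class = model$positive_class,
    classes = model$classes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- structure(
    list(mean = unlist(p$normalization$mean),
         sd = unlist(p$normalization$sd),
         features = p$feature_names,
         excluded_zero_variance = character(0)),
    class = "zscore_params")
  structure(
    list(feature_names = p$feature_names,
         normalization = norm,
         intercept = p$intercept,
         coefficients = unlist(p$coefficients),
         alpha = p$alpha, lambda_selected = p$lambda_selected,
         lambda_grid = p$lambda_grid, cv_folds = p$cv_folds,
         cv_curve = as.data.frame(p$cv_curve),
         positive_class = p$positive_class, classes = p$classes),
    class = "radscore")
}
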