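#' Construct a 3D image volume
#'
#' An `image_volume` is a 3D grid of CT attenuation values (Hounsfield
#' units) together with its physical voxel spacing and world origin.
#'
#' @param voxels numeric 3D array of attenuation values (HU).
#' @param spacing_mm numeric length-3 vector of positive voxel spacings (mm).
#' @param origin_mm numeric length-3 vector, world position of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array, got ", length(dim(voxels)),
         " dimensions")
  if (!all(is.finite(voxels)))
    stop("volume contains non-finite voxel values")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive values")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "image_volume")
}

#' Construct a binary segmentation mask
#'
#' A `segmentation_mask` shares the grid geometry of its paired volume;
#' values are strictly 0/1 (stored as logical).
#'
#' @param voxels logical or 0/1 numeric 3D array.
#' @param spacing_mm,origin_mm grid geometry, as for [image_volume()].
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(voxels, spacing_mm = c(1, 1, 1),
                              origin_mm = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("mask values must be 0 or 1")
    voxels <- array(voxels > 0, dim = dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask must be logical or 0/1 numeric")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive values")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "segmentation_mask")
}

#' Bundle a volume, mask(s) and labels into one lesion case
#'
#' One case corresponds to one segmented tumor: the attenuation volume, the
#' primary reader's mask, optionally a second reader's mask of the same
#' lesion, and the class/subtype labels used by the classification tasks.
#'
#' @param case_id character scalar, unique case identifier.
#' @param volume an [image_volume()], or `NULL` for geometry-only cases.
#' @param mask_reader1 primary [segmentation_mask()]; must be nonempty.
#' @param mask_reader2 optional second-reader mask, or `NULL`.
#' @param label class label (e.g. `"UTUC"` or `"RCC"`).
#' @param subtype optional histological subtype (e.g. `"ccRCC"`,
#'   `"high-grade UTUC"`).
#' @param geometry optional named list of generator-side geometry
#'   (long/short axis, volume) recorded for provenance.
#' @return An object of class `lesion_case`.
#' @export
lesion_case <- function(case_id, volume, mask_reader1, mask_reader2 = NULL,
                        label, subtype = NULL, geometry = NULL) {
  stopifnot(is.character(case_id), length(case_id) == 1L)
  if (!is.null(volume)) {
    stopifnot(inherits(volume, "image_volume"),
              inherits(mask_reader1, "segmentation_mask"))
    check_aligned(volume, mask_reader1, what = c("volume", "mask_reader1"))
    if (!any(mask_reader1$voxels))
      stop("empty segmentation: mask_reader1 of case '", case_id,
           "' contains no voxels")
    if (!is.null(mask_reader2)) {
      stopifnot(inherits(mask_reader2, "segmentation_mask"))
      check_aligned(volume, mask_reader2, what = c("volume", "mask_reader2"))
    }
  }
  structure(
    list(case_id = case_id, volume = volume, mask_reader1 = mask_reader1,
         mask_reader2 = mask_reader2, label = label, subtype = subtype,
         geometry = geometry),
    class = "lesion_case")
}

# Error (not resample) on any grid mismatch between two gridded objects.
check_aligned <- function(a, b, tol = 1e-6, what = c("volume", "mask")) {
  da <- dim(a$voxels); db <- dim(b$voxels)
  if (!identical(da, db))
    stop("grid mismatch: ", what[1], " is ", paste(da, collapse = "x"),
         " but ", what[2], " is ", paste(db, collapse = "x"))
  if (any(abs(a$spacing_mm - b$spacing_mm) > tol))
    stop("spacing mismatch between ", what[1], " (",
         paste(signif(a$spacing_mm, 6), collapse = ", "), ") and ", what[2],
         " (", paste(signif(b$spacing_mm, 6), collapse = ", "), ")")
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm, HU range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " in mask\n", sep = "")
  invisible(x)
}

#' @export
print.lesion_case <- function(x, ...) {
  cat("<lesion_case> ", x$case_id, ": ", x$label,
      if (!is.null(x$subtype)) paste0(" (", x$subtype, ")"),
      if (is.null(x$volume)) " [geometry only]",
      if (!is.null(x$mask_reader2)) " [dual read]", "\n", sep = "")
  invisible(x)
}

# Run expr with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
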