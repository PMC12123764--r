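#' Parameters of one phantom tumor class
#'
#' Describes the class-conditional generative law for synthetic tumors:
#' a log-normal long-axis size distribution, a uniform short/long axis
#' ratio, a mean venous-phase attenuation with spatially correlated
#' Gaussian texture, and an optional concentric hypodense (necrotic) core.
#'
#' @param label top-level class name the phantoms carry (e.g. `"UTUC"`).
#' @param size_median_mm median of the long-axis length (mm), > 0.
#' @param size_log_sd standard deviation of log long-axis (log-mm scale).
#' @param axis_ratio_range length-2 vector in (0, 1]: the short/long axis
#'   ratio is drawn uniformly from this interval.
#' @param mean_hu mean in-lesion attenuation (HU).
#' @param noise_sd_hu standard deviation of the voxelwise texture (HU), >= 0.
#' @param texture_corr_mm Gaussian correlation length of the texture (mm);
#'   0 gives white noise.
#' @param necrosis_prob probability in [0, 1] that a lesion carries a
#'   concentric core at half the lesion's linear scale.
#' @param necrosis_hu_offset signed HU offset added inside the core
#'   (negative for a hypodense/necrotic center).
#' @return An object of class `phantom_class_params`.
#' @export
phantom_class_params <- function(label, size_median_mm, size_log_sd,
                                 axis_ratio_range = c(0.5, 0.85),
                                 mean_hu = 50, noise_sd_hu = 15,
                                 texture_corr_mm = 2,
                                 necrosis_prob = 0,
                                 necrosis_hu_offset = -40) {
  stopifnot(is.character(label), length(label) == 1L)
  if (size_median_mm <= 0) stop("'size_median_mm' must be > 0")
  if (size_log_sd < 0) stop("'size_log_sd' must be >= 0")
  if (length(axis_ratio_range) != 2L || any(axis_ratio_range <= 0) ||
      any(axis_ratio_range > 1) ||
      axis_ratio_range[1] > axis_ratio_range[2])
    stop("'axis_ratio_range' must be an increasing interval within (0, 1]")
  if (noise_sd_hu < 0) stop("'noise_sd_hu' must be >= 0")
  if (texture_corr_mm < 0) stop("'texture_corr_mm' must be >= 0")
  if (necrosis_prob < 0 || necrosis_prob > 1)
    stop("'necrosis_prob' must be in [0, 1]")
  structure(
    list(label = label, size_median_mm = size_median_mm,
         size_log_sd = size_log_sd, axis_ratio_range = axis_ratio_range,
         mean_hu = mean_hu, noise_sd_hu = noise_sd_hu,
         texture_corr_mm = texture_corr_mm, necrosis_prob = necrosis_prob,
         necrosis_hu_offset = necrosis_hu_offset),
    class = "phantom_class_params")
}

# One geometry draw (3 RNG consumptions, in this fixed order) so that
# voxelized and geometry-only cohort paths see identical sizes per seed.
draw_lesion_geometry <- function(params) {
  long_axis <- stats::rlnorm(1, meanlog = log(params$size_median_mm),
                             sdlog = params$size_log_sd)
  ratio <- stats::runif(1, params$axis_ratio_range[1],
                        params$axis_ratio_range[2])
  necrotic <- stats::runif(1) < params$necrosis_prob
  list(long_axis_mm = long_axis, axis_ratio = ratio,
       short_axis_mm = long_axis * ratio, necrotic = necrotic,
       volume_cm3 = pi / 6 * long_axis * (long_axis * ratio)^2 / 1000)
}

#' Sample lesion geometry from a phantom class
#'
#' Draws long-axis lengths, axis ratios and necrosis indicators from a
#' class's generative law without voxelizing the lesions. Each row uses the
#' same draw order as [generate_tumor_volume()], so the sampled sizes are
#' exactly the sizes the voxelizer realizes.
#'
#' @param params a [phantom_class_params()] object.
#' @param n number of lesions to sample.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `long_axis_mm`, `short_axis_mm`,
#'   `axis_ratio`, `necrotic`, `volume_cm3`.
#' @export
sample_geometry <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "phantom_class_params"), n >= 0)
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      g <- draw_lesion_geometry(params)
      data.frame(long_axis_mm = g$long_axis_mm,
                 short_axis_mm = g$short_axis_mm,
                 axis_ratio = g$axis_ratio, necrotic = g$necrotic,
                 volume_cm3 = g$volume_cm3)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

# Gaussian smoothing of a 3D field on its periodic grid via FFT.
# sigma_vox: per-axis kernel SD in voxel units; 0 disables that axis.
gaussian_smooth3d <- function(x, sigma_vox) {
  d <- dim(x)
  k1 <- lapply(seq_len(3L), function(ax) {
    n <- d[ax]; s <- sigma_vox[ax]
    if (s <= 0) {
      k <- numeric(n); k[1] <- 1; k
    } else {
      idx <- seq_len(n) - 1L
      dist <- pmin(idx, n - idx)
      k <- exp(-0.5 * (dist / s)^2)
      k / sum(k)
    }
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(kern) <- d
  Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) /
    prod(d)
}

# Ellipsoid membership on a centered voxel grid: semi-axes in mm.
ellipsoid_mask_array <- function(dims, spacing, semi_axes) {
  ctr <- (dims + 1) / 2
  u <- lapply(seq_len(3L), function(ax) {
    ((seq_len(dims[ax]) - ctr[ax]) * spacing[ax] / semi_axes[ax])^2
  })
  s <- rep(u[[1]], times = dims[2] * dims[3]) +
    rep(rep(u[[2]], each = dims[1]), times = dims[3]) +
    rep(u[[3]], each = dims[1] * dims[2])
  array(s <= 1, dim = dims)
}

#' Generate one synthetic tumor volume and mask
#'
#' Voxelizes an ellipsoidal lesion whose long axis and axis ratio are drawn
#' from the class law, fills it with mean attenuation plus a spatially
#' correlated Gaussian texture (white noise smoothed to the configured
#' correlation length and rescaled to the configured SD), optionally
#' carves a concentric core with an HU offset, and embeds it in a
#' homogeneous background slab. Identical `(params, seed)` give
#' bit-identical output.
#'
#' @param params a [phantom_class_params()] object.
#' @param spacing_mm voxel spacing (mm), 3 positive values.
#' @param grid_shape integer length-3 grid dimensions, or `NULL` to size
#'   the grid to the sampled lesion plus a margin.
#' @param seed integer RNG seed.
#' @param background_hu attenuation outside the lesion (HU).
#' @param margin_mm margin around the lesion when auto-sizing the grid.
#' @param case_id identifier used in error messages.
#' @return A list with elements `volume` ([image_volume()]), `mask`
#'   ([segmentation_mask()]) and `geometry` (sampled sizes).
#' @export
generate_tumor_volume <- function(params, spacing_mm = c(1, 1, 3),
                                  grid_shape = NULL, seed = NULL,
                                  background_hu = -50, margin_mm = 4,
                                  case_id = "phantom") {
  stopifnot(inherits(params, "phantom_class_params"))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("non-positive voxel spacing")
  with_seed(seed, {
    geom <- draw_lesion_geometry(params)
    semi <- c(geom$long_axis_mm / 2,
              geom$short_axis_mm / 2, geom$short_axis_mm / 2)
    if (is.null(grid_shape)) {
      grid_shape <- as.integer(ceiling(2 * (semi + margin_mm) / spacing_mm))
    } else {
      grid_shape <- as.integer(grid_shape)
      extent <- grid_shape * spacing_mm
      if (any(2 * semi >= extent))
        stop("case '", case_id, "': sampled ellipsoid (axes ",
             paste(signif(2 * semi, 4), collapse = " x "),
             " mm) exceeds the grid (",
             paste(signif(extent, 4), collapse = " x "), " mm)")
    }
    mask <- ellipsoid_mask_array(grid_shape, spacing_mm, semi)
    vol <- array(background_hu, dim = grid_shape)
    if (params$noise_sd_hu > 0) {
      noise <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
      if (params$texture_corr_mm > 0)
        noise <- gaussian_smooth3d(noise,
                                   params$texture_corr_mm / spacing_mm)
      s <- stats::sd(noise)
      if (s > 0) noise <- noise * (params$noise_sd_hu / s)
      vol[mask] <- params$mean_hu + noise[mask]
    } else {
      vol[mask] <- params$mean_hu
    }
    if (geom$necrotic) {
      core <- ellipsoid_mask_array(grid_shape, spacing_mm, semi / 2)
      vol[core & mask] <- vol[core & mask] + params$necrosis_hu_offset
    }
    list(volume = image_volume(vol, spacing_mm),
         mask = segmentation_mask(mask, spacing_mm),
         geometry = geom)
  })
}

#' Perturb a segmentation mask to emulate a second reader
#'
#' Applies a boundary-localized stochastic deformation: the binary mask is
#' smoothed with a Gaussian of width `jitter_mm`, a correlated noise field
#' is added, and the 0.5 level set is re-thresholded. Voxels deep inside
#' (smoothed value > 0.99) or far outside (< 0.01) the lesion are never
#' touched, so only the boundary shell is dilated/eroded, by displacements
#' on the order of `jitter_mm`. Deterministic under `seed`.
#'
#' @param mask a nonempty [segmentation_mask()].
#' @param jitter_mm perturbation length scale (mm); 0 returns the input.
#' @param seed integer RNG seed.
#' @param noise_scale relative amplitude of the level-set noise.
#' @return A perturbed [segmentation_mask()] on the same grid.
#' @export
perturb_mask <- function(mask, jitter_mm, seed = NULL, noise_scale = 0.2) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (!any(mask$voxels)) stop("cannot perturb an empty mask")
  if (jitter_mm < 0) stop("'jitter_mm' must be >= 0")
  if (jitter_mm == 0) return(mask)
  d <- dim(mask$voxels)
  sig <- jitter_mm / mask$spacing_mm
  s <- gaussian_smooth3d(array(as.numeric(mask$voxels), dim = d), sig)
  with_seed(seed, {
    eps <- gaussian_smooth3d(array(stats::rnorm(prod(d)), dim = d), sig)
    sde <- stats::sd(eps)
    if (sde > 0) eps <- eps * (noise_scale / sde)
    out <- (s + eps) >= 0.5
    out[s > 0.99] <- TRUE
    out[s < 0.01] <- FALSE
    if (!any(out))
      stop("mask perturbation with jitter_mm = ", jitter_mm,
           " emptied the mask")
    segmentation_mask(out, mask$spacing_mm, mask$origin_mm)
  })
}

#' Configure a synthetic phantom cohort
#'
#' @param n_cases total number of cases, >= 0.
#' @param class_counts named integer vector of per-subtype case counts;
#'   names must match `class_params` and counts must sum to `n_cases`.
#' @param class_params named list of [phantom_class_params()], one per
#'   subtype; each carries the top-level class via its `label` field.
#' @param voxel_spacing_mm voxel spacing (mm); the default 1 x 1 x 3 mm
#'   mimics soft-kernel axial CT with 3 mm slices.
#' @param grid_shape fixed grid dimensions, or `NULL` to size each grid to
#'   its lesion.
#' @param background_hu background attenuation (HU).
#' @param second_reader_fraction fraction of cases re-read by a second
#'   reader (dual-segmented), in [0, 1].
#' @param reader_jitter_mm boundary perturbation magnitude of the second
#'   reader's mask (mm).
#' @param seed integer master seed; the cohort is a pure function of the
#'   configuration including this seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases, class_counts, class_params,
                          voxel_spacing_mm = c(1, 1, 3), grid_shape = NULL,
                          background_hu = -50,
                          second_reader_fraction = 0.30,
                          reader_jitter_mm = 1.5, seed = 1L) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 0) stop("'n_cases' must be >= 0")
  class_counts <- as.integer(round(class_counts))
  names(class_counts) <- names(class_params)[seq_along(class_counts)]
  if (is.null(names(class_counts)) || is.null(names(class_params)) ||
      !setequal(names(class_counts), names(class_params)))
    stop("'class_counts' and 'class_params' must share subtype names")
  if (sum(class_counts) != n_cases)
    stop("class counts sum to ", sum(class_counts), ", not n_cases = ",
         n_cases)
  ok <- vapply(class_params, inherits, logical(1), "phantom_class_params")
  if (!all(ok)) stop("every element of 'class_params' must be a ",
                     "phantom_class_params object")
  if (any(voxel_spacing_mm <= 0)) stop("non-positive voxel spacing")
  if (second_reader_fraction < 0 || second_reader_fraction > 1)
    stop("'second_reader_fraction' must be in [0, 1]")
  structure(
    list(n_cases = n_cases, class_counts = class_counts,
         class_params = class_params,
         voxel_spacing_mm = as.numeric(voxel_spacing_mm),
         grid_shape = grid_shape, background_hu = background_hu,
         second_reader_fraction = second_reader_fraction,
         reader_jitter_mm = reader_jitter_mm, seed = as.integer(seed)),
    class = "cohort_config")
}

# Largest-remainder integer allocation of `total` across `weights`.
allocate_counts <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Default study-calibrated cohort configuration
#'
#' The default configuration emulates a 236-case renal-mass cohort:
#' 117 UTUC (85 high-grade, 32 low-grade) and 119 RCC (87 clear cell, 20
#' papillary, 5 chromophobe, 3 sarcomatoid, 4 other), with class-wise
#' median long axes of 42 mm (UTUC) and 81 mm (RCC), log-normal size
#' spread matched to the reported interquartile ranges, venous-phase-like
#' attenuation/texture contrasts between subtypes, and a 30% dual-read
#' subsample. For `n_cases` other than 236 the subtype counts are scaled
#' by largest-remainder allocation.
#'
#' @param n_cases cohort size (default 236).
#' @param seed master RNG seed.
#' @param ... further arguments passed to [cohort_config()].
#' @return A `cohort_config` object.
#' @export
default_cohort_config <- function(n_cases = 236, seed = 1L, ...) {
  params <- list(
    "ccRCC" = phantom_class_params(
      "RCC", size_median_mm = 81, size_log_sd = 0.397,
      mean_hu = 95, noise_sd_hu = 22, texture_corr_mm = 4,
      necrosis_prob = 0.35),
    "papillary RCC" = phantom_class_params(
      "RCC", size_median_mm = 81, size_log_sd = 0.397,
      mean_hu = 45, noise_sd_hu = 12, texture_corr_mm = 2,
      necrosis_prob = 0.15),
    "chromophobe RCC" = phantom_class_params(
      "RCC", size_median_mm = 81, size_log_sd = 0.397,
      mean_hu = 60, noise_sd_hu = 14, texture_corr_mm = 2.5,
      necrosis_prob = 0.10),
    "sarcomatoid RCC" = phantom_class_params(
      "RCC", size_median_mm = 81, size_log_sd = 0.397,
      mean_hu = 70, noise_sd_hu = 20, texture_corr_mm = 3.5,
      necrosis_prob = 0.50),
    "other RCC" = phantom_class_params(
      "RCC", size_median_mm = 81, size_log_sd = 0.397,
      mean_hu = 60, noise_sd_hu = 15, texture_corr_mm = 3,
      necrosis_prob = 0.20),
    "high-grade UTUC" = phantom_class_params(
      "UTUC", size_median_mm = 42, size_log_sd = 0.514,
      mean_hu = 50, noise_sd_hu = 18, texture_corr_mm = 3,
      necrosis_prob = 0.20),
    "low-grade UTUC" = phantom_class_params(
      "UTUC", size_median_mm = 42, size_log_sd = 0.514,
      mean_hu = 42, noise_sd_hu = 11, texture_corr_mm = 1.5,
      necrosis_prob = 0.05))
  ref_counts <- c("ccRCC" = 87, "papillary RCC" = 20,
                  "chromophobe RCC" = 5, "sarcomatoid RCC" = 3,
                  "other RCC" = 4, "high-grade UTUC" = 85,
                  "low-grade UTUC" = 32)
  counts <- if (n_cases == 236) ref_counts else
    stats::setNames(allocate_counts(ref_counts, n_cases), names(ref_counts))
  cohort_config(n_cases = n_cases, class_counts = counts,
                class_params = params, seed = seed, ...)
}

#' Generate a synthetic phantom cohort
#'
#' Produces `n_cases` [lesion_case()] objects with the configured subtype
#' mix; a randomly chosen `ceiling(second_reader_fraction * n)` cases also
#' carry a second-reader mask obtained with [perturb_mask()]. The whole
#' cohort is a pure function of the configuration (including its seed).
#'
#' @param config a [cohort_config()] object.
#' @param voxelize if `FALSE`, skip voxelization and return geometry-only
#'   cases (fast path for cohort-level size statistics; such cases cannot
#'   be fed to feature extraction).
#' @return A list of `lesion_case` objects.
#' @export
generate_cohort <- function(config, voxelize = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases
  if (n == 0L) return(list())
  subtype <- rep(names(config$class_counts), times = config$class_counts)
  with_seed(config$seed, {
    case_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n),
                         nrow = n, ncol = 2L)
    n_r2 <- ceiling(config$second_reader_fraction * n)
    dual <- sort(sample.int(n, n_r2))
  })
  lapply(seq_len(n), function(i) {
    pars <- config$class_params[[subtype[i]]]
    id <- sprintf("case_%03d", i)
    if (voxelize) {
      tv <- generate_tumor_volume(
        pars, spacing_mm = config$voxel_spacing_mm,
        grid_shape = config$grid_shape, seed = case_seeds[i, 1],
        background_hu = config$background_hu, case_id = id)
      m2 <- if (i %in% dual)
        perturb_mask(tv$mask, config$reader_jitter_mm,
                     seed = case_seeds[i, 2]) else NULL
      lesion_case(id, tv$volume, tv$mask, m2, label = pars$label,
                  subtype = subtype[i], geometry = tv$geometry)
    } else {
      geom <- with_seed(case_seeds[i, 1], draw_lesion_geometry(pars))
      structure(
        list(case_id = id, volume = NULL, mask_reader1 = NULL,
             mask_reader2 = NULL, label = pars$label,
             subtype = subtype[i], geometry = geom,
             reader2_present = i %in% dual),
        class = "lesion_case")
    }
  })
}

# Dice overlap between two masks on the same grid.
#' Dice similarity coefficient of two masks
#' @param a,b [segmentation_mask()] objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  check_aligned(a, b, what = c("mask a", "mask b"))
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}
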