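#' The registered 59-feature radiomic panel
#'
#' Returns the ordered roster of the panel: 16 histogram-domain first-order
#' features (computed on the discretized gray levels), 19 intensity-domain
#' first-order features (computed on raw in-mask HU values), 22 gray-level
#' co-occurrence matrix (GLCM) texture features, and the two
#' ellipsoid-equivalent tumor axes. The roster is versioned so it can be
#' swapped without code changes.
#'
#' @return Character vector of 59 feature names, with attribute
#'   `panel_version`.
#' @export
feature_panel <- function() {
  histo <- paste0("Firstorder.histogram.",
                  c("Entropy", "Mean", "Std", "Variance", "Median", "Min",
                    "Max", "Range", "Mean.abs.deviation",
                    "Median.abs.deviation", "Skewness", "Kurtosis",
                    "Uniformity", "Mode", "P10", "P90"))
  intens <- paste0("Firstorder.intensity.",
                   c("Mean", "Std", "Variance", "Median", "Min", "Max",
                     "Range", "Root.mean.square", "Energy",
                     "Mean.abs.deviation", "Median.abs.deviation",
                     "Robust.mean.abs.deviation", "Skewness", "Kurtosis",
                     "P10", "P25", "P75", "P90", "Interquartile.range"))
  glcm <- paste0("Glcm.",
                 c("Joint.entropy", "Joint.average", "Joint.variance",
                   "Std", "Energy", "Joint.max", "Contrast",
                   "Dissimilarity", "Inverse.difference",
                   "Inverse.difference.moment", "Inverse.variance",
                   "Correlation", "Autocorrelation", "Cluster.tendency",
                   "Cluster.shade", "Cluster.prominence",
                   "Difference.average", "Difference.variance",
                   "Difference.entropy", "Sum.of.averages", "Sum.variance",
                   "Sum.entropy"))
  structure(c(histo, intens, glcm, "Tumor.long.axis", "Tumor.short.axis"),
            panel_version = "panel-59-v1")
}

#' Discretize the in-mask intensities of a lesion
#'
#' Fixed-bin-number discretization over the in-mask intensity range
#' `[min, max]`: the range is cut into `n_bins` equal-width bins, the
#' maximum maps to bin `n_bins`, and a constant region of interest maps
#' every voxel to bin 1.
#'
#' @param volume an [image_volume()].
#' @param mask an aligned nonempty [segmentation_mask()].
#' @param n_bins number of gray levels, >= 2.
#' @return An object of class `discretized_roi` with elements
#'   `raw_values`, `bin_index`, `n_levels`, `bin_edges`, `voxel_coords`,
#'   `spacing_mm`.
#' @export
discretize <- function(volume, mask, n_bins = 32) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(mask, "segmentation_mask"))
  check_aligned(volume, mask)
  if (n_bins < 2) stop("'n_bins' must be >= 2")
  inside <- mask$voxels
  if (!any(inside)) stop("empty segmentation: mask contains no voxels")
  vals <- volume$voxels[inside]
  lo <- min(vals); hi <- max(vals)
  if (hi > lo) {
    edges <- seq(lo, hi, length.out = n_bins + 1)
    bins <- pmin(findInterval(vals, edges, rightmost.closed = TRUE),
                 n_bins)
  } else {
    edges <- c(lo, lo)
    bins <- rep.int(1L, length(vals))
  }
  structure(
    list(raw_values = vals, bin_index = as.integer(bins),
         n_levels = as.integer(n_bins), bin_edges = edges,
         voxel_coords = which(inside, arr.ind = TRUE),
         spacing_mm = volume$spacing_mm),
    class = "discretized_roi")
}

# Central moments helpers (population conventions, as usual in radiomics).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
skewness_pop <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
kurtosis_pop <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

#' First-order features of a discretized lesion
#'
#' Histogram-domain statistics are computed on the discretized gray levels
#' (entropy is the Shannon entropy in bits over occupied bins); intensity-
#' domain statistics are computed on the raw in-mask HU values. The robust
#' mean absolute deviation is the mean absolute deviation from the mean of
#' the values lying within the 10th-90th percentile of the lesion.
#'
#' @param roi a [discretize()]d region of interest.
#' @return Named numeric vector of the panel's 35 first-order features.
#' @export
first_order_features <- function(roi) {
  stopifnot(inherits(roi, "discretized_roi"))
  b <- roi$bin_index
  p <- tabulate(b, nbins = roi$n_levels) / length(b)
  occ <- p[p > 0]
  q <- stats::quantile(b, c(0.10, 0.90), names = FALSE, type = 7)
  hfeat <- c(
    Entropy = -sum(occ * log2(occ)),
    Mean = mean(b),
    Std = pop_sd(b),
    Variance = pop_sd(b)^2,
    Median = stats::median(b),
    Min = min(b),
    Max = max(b),
    Range = max(b) - min(b),
    Mean.abs.deviation = mean(abs(b - mean(b))),
    Median.abs.deviation = mean(abs(b - stats::median(b))),
    Skewness = skewness_pop(b),
    Kurtosis = kurtosis_pop(b),
    Uniformity = sum(p^2),
    Mode = which.max(p),
    P10 = q[1], P90 = q[2])
  x <- roi$raw_values
  qx <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE,
                        type = 7)
  trimmed <- x[x >= qx[1] & x <= qx[4]]
  ifeat <- c(
    Mean = mean(x),
    Std = pop_sd(x),
    Variance = pop_sd(x)^2,
    Median = stats::median(x),
    Min = min(x),
    Max = max(x),
    Range = max(x) - min(x),
    Root.mean.square = sqrt(mean(x^2)),
    Energy = sum(x^2),
    Mean.abs.deviation = mean(abs(x - mean(x))),
    Median.abs.deviation = mean(abs(x - stats::median(x))),
    Robust.mean.abs.deviation = mean(abs(trimmed - mean(trimmed))),
    Skewness = skewness_pop(x),
    Kurtosis = kurtosis_pop(x),
    P10 = qx[1], P25 = qx[2], P75 = qx[3], P90 = qx[4],
    Interquartile.range = qx[3] - qx[2])
  c(stats::setNames(hfeat, paste0("Firstorder.histogram.", names(hfeat))),
    stats::setNames(ifeat, paste0("Firstorder.intensity.", names(ifeat))))
}

# The 13 unique 3D direction offsets (half of the 26-neighborhood).
glcm_directions <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- dirs$dz > 0 | (dirs$dz == 0 & dirs$dy > 0) |
    (dirs$dz == 0 & dirs$dy == 0 & dirs$dx > 0)
  as.matrix(dirs[keep, ])
}

#' Build the gray-level co-occurrence matrix of a lesion
#'
#' Counts symmetric gray-level pairs (each pair in both orders) between
#' in-mask voxels separated by `distance` voxels along each of the 13
#' unique 3D directions; per-direction matrices are normalized to sum 1
#' and then averaged (`policy = "average"`, over directions that contain
#' at least one pair), or all counts are pooled before normalization
#' (`policy = "merge"`). A region with no valid pair in any direction
#' yields a degenerate flagged matrix.
#'
#' @param roi a [discretize()]d region of interest.
#' @param distance offset magnitude in voxel units, >= 1.
#' @param policy direction aggregation, `"average"` or `"merge"`.
#' @return An object of class `glcm_matrix`: elements `P` (Ng x Ng),
#'   `n_levels`, `distance`, `policy`, `degenerate`.
#' @export
build_glcm <- function(roi, distance = 1, policy = c("average", "merge")) {
  stopifnot(inherits(roi, "discretized_roi"))
  policy <- match.arg(policy)
  if (distance < 1) stop("'distance' must be >= 1")
  ng <- roi$n_levels
  dims <- apply(roi$voxel_coords, 2, max)
  barr <- array(NA_integer_, dim = dims)
  barr[roi$voxel_coords] <- roi$bin_index
  dirs <- glcm_directions() * distance
  mats <- list()
  for (k in seq_len(nrow(dirs))) {
    off <- dirs[k, ]
    src <- lapply(1:3, function(ax) {
      i <- seq_len(dims[ax])
      i[i + off[ax] >= 1 & i + off[ax] <= dims[ax]]
    })
    if (any(lengths(src) == 0)) next
    dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
    b1 <- barr[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b2 <- barr[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- !is.na(b1) & !is.na(b2)
    if (!any(ok)) next
    counts <- tabulate((b1[ok] - 1L) * ng + b2[ok], nbins = ng * ng)
    m <- matrix(counts, ng, ng, byrow = TRUE)
    mats[[length(mats) + 1L]] <- m + t(m)  # symmetric: both orders
  }
  if (length(mats) == 0L) {
    return(structure(
      list(P = matrix(0, ng, ng), n_levels = ng, distance = distance,
           policy = policy, degenerate = TRUE),
      class = "glcm_matrix"))
  }
  P <- if (policy == "average") {
    Reduce(`+`, lapply(mats, function(m) m / sum(m))) / length(mats)
  } else {
    tot <- Reduce(`+`, mats)
    tot / sum(tot)
  }
  structure(
    list(P = P, n_levels = ng, distance = distance, policy = policy,
         degenerate = FALSE),
    class = "glcm_matrix")
}

#' GLCM texture features
#'
#' Evaluates the panel's 22 co-occurrence features on a normalized GLCM:
#' joint statistics (entropy in bits, average, variance, SD, energy,
#' maximum probability), contrast-family features (contrast,
#' dissimilarity, inverse difference, inverse difference moment, inverse
#' variance), correlation and autocorrelation, cluster moments, and the
#' moments/entropies of the gray-level difference distribution
#' \eqn{p_{|i-j|}} and sum distribution \eqn{p_{i+j}}. A degenerate GLCM
#' (no voxel pair) returns all features as 0.
#'
#' @param G a [build_glcm()] result.
#' @return Named numeric vector of 22 features (names prefixed `Glcm.`).
#' @export
glcm_features <- function(G) {
  stopifnot(inherits(G, "glcm_matrix"))
  ng <- G$n_levels
  nm <- grep("^Glcm\\.", feature_panel(), value = TRUE)
  if (isTRUE(G$degenerate))
    return(stats::setNames(numeric(length(nm)), nm))
  P <- G$P
  if (abs(sum(P) - 1) > 1e-8)
    stop("GLCM is not normalized (sum = ", format(sum(P)), ")")
  i <- row(P); j <- col(P)
  mu <- sum(i * P)
  jvar <- sum((i - mu)^2 * P)
  # difference distribution p_{|i-j|}, k = 0..Ng-1
  dk <- 0:(ng - 1)
  pd <- vapply(dk, function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum(dk * pd)
  # sum distribution p_{i+j}, k = 2..2Ng
  sk <- 2:(2 * ng)
  ps <- vapply(sk, function(k) sum(P[(i + j) == k]), numeric(1))
  sa <- sum(sk * ps)
  nz <- P[P > 0]
  pdnz <- pd[pd > 0]; psnz <- ps[ps > 0]
  corr <- if (jvar > 0) (sum(i * j * P) - mu^2) / jvar else 1
  out <- c(
    Joint.entropy = -sum(nz * log2(nz)),
    Joint.average = mu,
    Joint.variance = jvar,
    Std = sqrt(jvar),
    Energy = sum(P^2),
    Joint.max = max(P),
    Contrast = sum((i - j)^2 * P),
    Dissimilarity = sum(abs(i - j) * P),
    Inverse.difference = sum(P / (1 + abs(i - j))),
    Inverse.difference.moment = sum(P / (1 + (i - j)^2)),
    Inverse.variance = sum(P[i != j] / (i - j)[i != j]^2),
    Correlation = corr,
    Autocorrelation = sum(i * j * P),
    Cluster.tendency = sum((i + j - 2 * mu)^2 * P),
    Cluster.shade = sum((i + j - 2 * mu)^3 * P),
    Cluster.prominence = sum((i + j - 2 * mu)^4 * P),
    Difference.average = da,
    Difference.variance = sum((dk - da)^2 * pd),
    Difference.entropy = -sum(pdnz * log2(pdnz)),
    Sum.of.averages = sa,
    Sum.variance = sum((sk - sa)^2 * ps),
    Sum.entropy = -sum(psnz * log2(psnz)))
  stats::setNames(as.numeric(out), paste0("Glcm.", names(out)))
}

#' Ellipsoid-equivalent tumor axes
#'
#' Principal-component analysis of the physical coordinates of the in-mask
#' voxels; each full axis length is `2 * sqrt(5 * eigenvalue)`, the axis of
#' the uniform solid ellipsoid with the same second moment (a uniform
#' ellipsoid with semi-axis a has coordinate variance a^2/5 along that
#' axis).
#'
#' @param mask a nonempty [segmentation_mask()].
#' @return Named numeric vector `c(long_axis_mm, short_axis_mm)` (largest
#'   and second-largest axis).
#' @export
shape_axes <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty segmentation: mask contains no voxels")
  xyz <- sweep(idx, 2, mask$spacing_mm, `*`)
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  cov3 <- crossprod(cc) / nrow(cc)
  ev <- sort(eigen(cov3, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  axes <- 2 * sqrt(5 * ev)
  c(long_axis_mm = axes[1], short_axis_mm = axes[2])
}

#' Extract the full 59-feature panel from one lesion case
#'
#' Runs discretization, first-order, GLCM and shape stages and assembles
#' the ordered 59-feature vector. Deterministic given the case and
#' settings.
#'
#' @param case a [lesion_case()] with voxel data, or a `volume`/`mask`
#'   pair via the `volume` and `mask` arguments.
#' @param n_bins gray levels for discretization (default 32).
#' @param glcm_distance GLCM offset in voxels (default 1).
#' @param glcm_policy GLCM direction aggregation (default `"average"`).
#' @param reader which mask to use, 1 or 2.
#' @param volume,mask optional explicit volume and mask overriding `case`.
#' @return Named numeric vector of 59 features with attributes
#'   `panel_version` and `glcm_degenerate`.
#' @export
extract_panel <- function(case = NULL, n_bins = 32, glcm_distance = 1,
                          glcm_policy = "average", reader = 1,
                          volume = NULL, mask = NULL) {
  if (is.null(volume) || is.null(mask)) {
    stopifnot(inherits(case, "lesion_case"))
    if (is.null(case$volume))
      stop("case '", case$case_id, "' carries no voxel data ",
           "(geometry-only cohort)")
    volume <- case$volume
    mask <- if (reader == 2) {
      if (is.null(case$mask_reader2))
        stop("case '", case$case_id, "' has no second-reader mask")
      case$mask_reader2
    } else case$mask_reader1
  }
  roi <- discretize(volume, mask, n_bins = n_bins)
  fo <- first_order_features(roi)
  G <- build_glcm(roi, distance = glcm_distance, policy = glcm_policy)
  gl <- glcm_features(G)
  ax <- shape_axes(mask)
  panel <- feature_panel()
  vec <- c(fo, gl,
           Tumor.long.axis = unname(ax["long_axis_mm"]),
           Tumor.short.axis = unname(ax["short_axis_mm"]))
  if (!setequal(names(vec), panel) || length(vec) != length(panel))
    stop("internal panel mismatch")  # registry and stages must agree
  structure(vec[panel], panel_version = attr(panel, "panel_version"),
            glcm_degenerate = G$degenerate)
}

#' Extract the feature panel for a whole cohort
#'
#' @param cases list of [lesion_case()] objects with voxel data.
#' @param reader which reader's mask to extract from (1 or 2); with
#'   `reader = 2` only dual-read cases are returned.
#' @param ... settings passed to [extract_panel()].
#' @return A `feature_table`: data.frame with `case_id`, `label`,
#'   `subtype` columns followed by the 59 feature columns.
#' @export
extract_cohort_features <- function(cases, reader = 1, ...) {
  if (reader == 2)
    cases <- Filter(function(cs) !is.null(cs$mask_reader2), cases)
  if (length(cases) == 0L)
    stop("no cases to extract (reader = ", reader, ")")
  rows <- lapply(cases, function(cs) {
    v <- extract_panel(cs, reader = reader, ...)
    cbind(data.frame(case_id = cs$case_id, label = cs$label,
                     subtype = if (is.null(cs$subtype)) NA_character_
                               else cs$subtype,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v), check.names = FALSE))
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  feature_table(tab)
}
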