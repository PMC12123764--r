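#' Two-reader intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation from the ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{k = 2} raters, \eqn{MS_R} the between-case, \eqn{MS_C} the
#' between-rater and \eqn{MS_E} the residual mean square. This is the
#' standard form for interreader reliability of radiomic features.
#'
#' @param x,y paired feature values from reader 1 and reader 2, length
#'   n >= 3.
#' @return ICC value in [-1, 1]. Identical constant readings (zero total
#'   variance) return 1 with a `"degenerate"` attribute.
#' @export
icc_two_readers <- function(x, y) {
  if (length(x) != length(y)) stop("readers must rate the same cases")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 paired cases, got ", n)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  if (all(dat == dat[1])) {
    return(structure(1, degenerate = TRUE))
  }
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Screen features by interreader reliability
#'
#' Computes ICC(2,1) per feature over the cases segmented by both readers
#' and retains the features whose ICC meets the threshold (default 0.8).
#' Features with (near-)zero variance across both readers' values are
#' dropped with an explicit report entry rather than given an undefined
#' ICC -- unless the two readers agree exactly, in which case agreement is
#' perfect by construction and the feature is retained.
#'
#' @param table_r1,table_r2 [feature_table()]s from reader 1 and reader 2;
#'   ICC uses the intersection of their case ids.
#' @param threshold retention threshold on ICC (default 0.8).
#' @return An object of class `icc_report`: `icc` (named vector),
#'   `retained` (feature names in panel order), `dropped_degenerate`,
#'   `n_cases_used`, `threshold`.
#' @export
filter_features <- function(table_r1, table_r2, threshold = 0.8) {
  f1 <- feature_columns(table_r1)
  f2 <- feature_columns(table_r2)
  if (!identical(f1, f2))
    stop("reader tables carry different feature panels")
  ids <- intersect(table_r1$case_id, table_r2$case_id)
  if (length(ids) == 0L) stop("no overlapping case ids between readers")
  m1 <- table_r1[match(ids, table_r1$case_id), f1, drop = FALSE]
  m2 <- table_r2[match(ids, table_r2$case_id), f2, drop = FALSE]
  icc <- numeric(length(f1))
  names(icc) <- f1
  degen <- character(0)
  for (f in f1) {
    a <- m1[[f]]; b <- m2[[f]]
    if (isTRUE(all.equal(a, b, tolerance = 0))) {
      icc[f] <- 1
      next
    }
    if (stats::sd(c(a, b)) < 1e-12) {
      icc[f] <- NA_real_
      degen <- c(degen, f)
      next
    }
    icc[f] <- icc_two_readers(a, b)
  }
  retained <- f1[!is.na(icc) & icc >= threshold]
  if (length(retained) == 0L)
    warning("no feature reaches ICC >= ", threshold,
            "; retained set is empty")
  structure(
    list(icc = icc, retained = retained, dropped_degenerate = degen,
         n_cases_used = length(ids), threshold = threshold),
    class = "icc_report")
}

#' @export
print.icc_report <- function(x, ...) {
  cat("Interreader reliability (ICC(2,1)) over", x$n_cases_used,
      "dual-read cases\n")
  cat("  retained:", length(x$retained), "of", length(x$icc),
      "features at ICC >=", x$threshold, "\n")
  if (length(x$dropped_degenerate))
    cat("  dropped (degenerate variance):",
        paste(x$dropped_degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.icc_report <- function(object, ...) {
  df <- data.frame(feature = names(object$icc), icc = unname(object$icc),
                   retained = names(object$icc) %in% object$retained,
                   row.names = NULL)
  df[order(-df$icc), ]
}
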