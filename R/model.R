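#' Fit / apply z-score normalization
#'
#' Per-feature mean and standard deviation are estimated on the training
#' table only; test data are always transformed with the training
#' parameters. Features with (near-)zero training variance are excluded
#' and reported, never divided by zero.
#'
#' @param train a [feature_table()] or numeric matrix (training split).
#' @param features feature columns to normalize (default: all).
#' @return `zscore_fit` returns a `zscore_params` object with `mean`,
#'   `sd`, `features`, `excluded_zero_variance`.
#' @export
zscore_fit <- function(train, features = NULL) {
  m <- as_feature_matrix(train, features)
  mu <- colMeans(m)
  sdev <- apply(m, 2, stats::sd)
  keep <- sdev > 1e-12
  structure(
    list(mean = mu[keep], sd = sdev[keep], features = colnames(m)[keep],
         excluded_zero_variance = colnames(m)[!keep]),
    class = "zscore_params")
}

#' @rdname zscore_fit
#' @param params a `zscore_params` object fitted on the training split.
#' @param table table or matrix to transform.
#' @return `zscore_apply` returns a numeric matrix of z-scored features
#'   (columns restricted to the fitted features, in fitted order).
#' @export
zscore_apply <- function(params, table) {
  stopifnot(inherits(params, "zscore_params"))
  m <- as_feature_matrix(table, params$features)
  sweep(sweep(m, 2, params$mean), 2, params$sd, `/`)
}

# Coerce a feature table / data.frame / matrix to a features-only matrix.
as_feature_matrix <- function(x, features = NULL) {
  if (is.matrix(x)) {
    m <- x
  } else {
    stopifnot(is.data.frame(x))
    m <- as.matrix(x[, setdiff(names(x), c("case_id", "label", "subtype")),
                     drop = FALSE])
    if (!is.null(x$case_id)) rownames(m) <- x$case_id
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(m))
    if (length(missing))
      stop("missing feature(s): ", paste(missing, collapse = ", "))
    m <- m[, features, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, folds, seed = NULL) {
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  foldid
}

#' Fit a cross-validated L1-penalized logistic radiomic score
#'
#' The radiomic score is the predicted probability of the positive class
#' from a logistic model with an L1 (LASSO) penalty: the objective is the
#' mean negative binomial log-likelihood plus \eqn{\lambda \sum_j |\beta_j|}
#' (intercept unpenalized), fitted with glmnet on z-scored features. The
#' penalty is chosen as `lambda.min` -- the grid value minimizing the mean
#' cross-validated error over stratified, seeded folds -- and the model is
#' refitted on the full training data at that penalty.
#'
#' @param x training features: a [feature_table()] (with a `label`
#'   column, unless `y` is given) or numeric matrix.
#' @param y binary labels (factor or character); first sorted level is
#'   taken as negative unless `positive` is given.
#' @param positive label of the positive class (scored towards 1).
#' @param folds number of cross-validation folds (default 10).
#' @param alpha elastic-net mixing parameter in (0, 1]; 1 is the pure
#'   LASSO.
#' @param cv_metric CV selection metric: `"deviance"` (binomial deviance,
#'   the default) or `"class"` (misclassification rate).
#' @param nlambda,lambda_min_ratio geometry of the automatic penalty
#'   grid: `nlambda` log-spaced values from the smallest
#'   all-coefficients-zero penalty down to that value times
#'   `lambda_min_ratio`.
#' @param lambda optional explicit penalty grid (decreasing).
#' @param lambda_fixed optional fixed penalty: skips cross-validation and
#'   fits at exactly this value (0 gives the unpenalized logistic fit).
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `radscore` with fields `feature_names`,
#'   `normalization`, `intercept`, `coefficients` (named, sparse in the
#'   sense that most entries are exactly 0), `alpha`, `lambda_selected`,
#'   `lambda_grid`, `cv_folds`, `cv_curve`, `nonzero_path`, `classes`,
#'   `positive_class`.
#' @seealso [predict.radscore()], [roc_analysis()]
#' @export
fit_radiomic_score <- function(x, y = NULL, positive = NULL, folds = 10,
                               alpha = 1, cv_metric = c("deviance", "class"),
                               nlambda = 100, lambda_min_ratio = 1e-4,
                               lambda = NULL, lambda_fixed = NULL,
                               seed = NULL) {
  cv_metric <- match.arg(cv_metric)
  if (is.null(y)) {
    if (!is.data.frame(x) || is.null(x$label))
      stop("'y' is missing and 'x' has no label column")
    y <- x$label
  }
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop("need exactly 2 classes, got: ", paste(classes, collapse = ", "))
  if (is.null(positive)) positive <- classes[2]
  if (!positive %in% classes) stop("'positive' must be one of the labels")
  classes <- c(setdiff(classes, positive), positive)
  ybin <- as.integer(y == positive)
  norm <- zscore_fit(x)
  xz <- zscore_apply(norm, x)
  n <- nrow(xz)
  if (!is.null(lambda_fixed)) {
    fit <- glmnet::glmnet(xz, ybin, family = "binomial", alpha = alpha,
                          lambda = fixed_lambda_path(xz, ybin, alpha,
                                                     lambda_fixed),
                          standardize = FALSE, thresh = 1e-12,
                          maxit = 1e6)
    cf <- stats::coef(fit, s = lambda_fixed, exact = FALSE)
    lambda_sel <- lambda_fixed
    grid <- fit$lambda
    cvc <- NULL
    nz_path <- fit$df
  } else {
    if (n < folds)
      stop("n = ", n, " is smaller than the number of folds (", folds, ")")
    if (min(table(y)) < folds / 2)
      stop("too few cases in the minority class for stratified ", folds,
           "-fold CV")
    foldid <- stratified_folds(ybin, folds, seed = seed)
    cv <- glmnet::cv.glmnet(xz, ybin, family = "binomial", alpha = alpha,
                            foldid = foldid, type.measure = cv_metric,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            lambda = lambda, standardize = FALSE)
    lambda_sel <- cv$lambda.min
    grid <- cv$lambda
    cvc <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
    cf <- stats::coef(cv$glmnet.fit, s = lambda_sel, exact = FALSE)
    nz_path <- cv$glmnet.fit$df
  }
  beta <- stats::setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  structure(
    list(feature_names = norm$features, normalization = norm,
         intercept = as.numeric(cf)[1], coefficients = beta,
         alpha = alpha, lambda_selected = lambda_sel, lambda_grid = grid,
         cv_folds = if (is.null(lambda_fixed)) folds else NA_integer_,
         cv_curve = cvc, cv_metric = cv_metric, nonzero_path = nz_path,
         classes = classes, positive_class = positive, n_train = n,
         call = match.call()),
    class = "radscore")
}

# glmnet is unreliable when asked for a single lambda; give it a short
# descending path ending at the requested value.
fixed_lambda_path <- function(xz, ybin, alpha, lambda_fixed) {
  p <- mean(ybin)
  lmax <- max(abs(crossprod(xz, ybin - p))) / length(ybin) /
    max(alpha, 1e-3)
  lmax <- max(lmax, lambda_fixed * 1.01, 1e-3)
  unique(sort(c(exp(seq(log(lmax), log(max(lambda_fixed, lmax * 1e-5)),
                        length.out = 25)), lambda_fixed),
              decreasing = TRUE))
}

#' @export
print.radscore <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("L1-penalized logistic radiomic score (alpha =", x$alpha, ")\n")
  cat("  classes: ", x$classes[1], " (0) vs ", x$classes[2],
      " (1, scored)\n", sep = "")
  cat("  trained on", x$n_train, "cases,", length(x$feature_names),
      "features\n")
  if (!is.na(x$cv_folds))
    cat("  lambda.min = ", signif(x$lambda_selected, 4), " (",
        x$cv_folds, "-fold CV, ", x$cv_metric, ")\n", sep = "")
  else
    cat("  fixed lambda =", signif(x$lambda_selected, 4), "\n")
  cat("  ", nz, " of ", length(x$coefficients),
      " coefficients nonzero\n", sep = "")
  invisible(x)
}

#' @export
summary.radscore <- function(object, ...) {
  beta <- object$coefficients
  sel <- beta[beta != 0]
  df <- data.frame(feature = names(sel), coefficient = unname(sel),
                   row.names = NULL)
  df <- df[order(-abs(df$coefficient)), ]
  structure(list(selected = df, intercept = object$intercept,
                 lambda = object$lambda_selected,
                 classes = object$classes, model = object),
            class = "summary.radscore")
}

#' @export
print.summary.radscore <- function(x, ...) {
  cat("Radiomic score: ", nrow(x$selected), " selected features (",
      x$classes[2], " vs ", x$classes[1], "), lambda = ",
      signif(x$lambda, 4), "\n\n", sep = "")
  cat("  intercept: ", signif(x$intercept, 6), "\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' @export
coef.radscore <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict radiomic scores for new cases
#'
#' Applies the training normalization and the fitted coefficients:
#' `score = plogis(intercept + beta' z(x))`, a probability in [0, 1] for
#' the positive class. A case missing any model feature is an error
#' naming the feature.
#'
#' @param object a `radscore` model.
#' @param newdata [feature_table()], data.frame, matrix, or a single
#'   named feature vector.
#' @param type `"response"` (probability, default) or `"link"` (linear
#'   predictor).
#' @param ... unused.
#' @return Numeric vector of scores.
#' @export
predict.radscore <- function(object, newdata,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  z <- zscore_apply(object$normalization, newdata)
  eta <- drop(z %*% object$coefficients) + object$intercept
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
plot.radscore <- function(x, ...) {
  if (is.null(x$cv_curve)) {
    plot(x$lambda_grid, x$nonzero_path, log = "x", type = "s",
         xlab = expression(lambda), ylab = "nonzero coefficients", ...)
    return(invisible(x))
  }
  cc <- x$cv_curve
  plot(log(cc$lambda), cc$cvm, type = "l",
       xlab = expression(log(lambda)),
       ylab = paste("mean CV", x$cv_metric), ...)
  graphics::arrows(log(cc$lambda), cc$cvm - cc$cvsd, log(cc$lambda),
                   cc$cvm + cc$cvsd, length = 0.02, angle = 90, code = 3,
                   col = "grey60")
  graphics::abline(v = log(x$lambda_selected), lty = 2)
  invisible(x)
}

#' Score one feature vector
#'
#' Convenience wrapper around [predict.radscore()] for a single case.
#'
#' @param model a `radscore` model.
#' @param x named numeric feature vector covering the model's features.
#' @return Score in [0, 1].
#' @export
radiomics_score <- function(model, x) {
  as.numeric(predict(model, x))
}

#' ROC analysis with a Youden operating cutoff
#'
#' Sensitivity/specificity are evaluated at every distinct score
#' (positive call: score >= threshold); the AUC is the normalized
#' Mann-Whitney U statistic (ties counted 1/2, equal to trapezoidal
#' integration of the empirical ROC curve). The operating cutoff
#' maximizes the Youden index J = sensitivity + specificity - 1; ties are
#' broken toward the lower cutoff.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels, same length.
#' @param positive label treated as positive; default: the larger of the
#'   two sorted labels.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `cutoff`, `sensitivity_at_cutoff`,
#'   `specificity_at_cutoff`, `youden`.
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("ROC needs both classes present, got: ",
         paste(classes, collapse = ", "))
  if (is.null(positive)) positive <- classes[2]
  pos <- labels == positive
  npos <- sum(pos); nneg <- sum(!pos)
  r <- rank(scores)  # midranks: ties handled by the midpoint convention
  auc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # ties -> lower cutoff
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, cutoff = thr[best],
         sensitivity_at_cutoff = sens[best],
         specificity_at_cutoff = spec[best], youden = j[best],
         positive_class = positive, n_positive = npos,
         n_negative = nneg),
    class = "roc_result")
}

#' Sensitivity/specificity at a pre-chosen cutoff
#'
#' Evaluates a fixed operating cutoff (for example one derived on the
#' training split) on new scores.
#'
#' @param scores,labels as in [roc_analysis()].
#' @param cutoff operating threshold: positive call when
#'   `score >= cutoff`.
#' @param positive positive label.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
classification_metrics <- function(scores, labels, cutoff,
                                   positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(positive)) positive <- classes[2]
  pos <- labels == positive
  c(sensitivity = mean(scores[pos] >= cutoff),
    specificity = mean(scores[!pos] < cutoff))
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC analysis (positive: ", x$positive_class, ", ", x$n_positive,
      " vs ", x$n_negative, ")\n", sep = "")
  cat("  AUC = ", signif(x$auc, 4), "\n", sep = "")
  cat("  Youden cutoff = ", signif(x$cutoff, 4), " (sensitivity ",
      signif(x$sensitivity_at_cutoff, 4), ", specificity ",
      signif(x$specificity_at_cutoff, 4), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  ord <- order(1 - x$specificity, x$sensitivity)
  plot(c(1, (1 - x$specificity)[ord], 0), c(1, x$sensitivity[ord], 0),
       type = "l", xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  i <- match(x$cutoff, x$thresholds)
  graphics::points(1 - x$specificity[i], x$sensitivity[i], pch = 19)
  invisible(x)
}
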