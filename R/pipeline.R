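#' Stratified train/test split of a cohort
#'
#' Deterministic, seeded, class-stratified split: the training set gets
#' `round(fraction * n)` cases in total, allocated across classes by
#' largest-remainder so per-class proportions are preserved within
#' rounding (236 cases at 0.70 give 165 train / 71 test). Train and test
#' are disjoint and exhaustive.
#'
#' @param labels class label per case (the split operates on indices, so
#'   it applies equally to case lists and feature tables).
#' @param fraction training fraction, strictly between 0 and 1.
#' @param seed integer RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, fraction = 0.70, seed = NULL) {
  labels <- as.character(labels)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be strictly between 0 and 1")
  tab <- table(labels)
  if (any(tab < 2))
    stop("every class needs at least 2 cases; got ",
         paste(names(tab)[tab < 2], collapse = ", "))
  n <- length(labels)
  n_train <- round(fraction * n)
  per_class <- allocate_counts(as.numeric(tab), n_train)
  names(per_class) <- names(tab)
  train <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, per_class[cl]))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

# Task registry: per task, the subtype filter and binary label mapping.
task_registry <- function() {
  list(
    UTUC_vs_RCC = list(
      keep = function(label, subtype) rep(TRUE, length(label)),
      relabel = function(label, subtype) label,
      positive = "UTUC"),
    ccRCC_vs_highgradeUTUC = list(
      keep = function(label, subtype)
        subtype %in% c("ccRCC", "high-grade UTUC"),
      relabel = function(label, subtype) subtype,
      positive = "high-grade UTUC"),
    highgrade_vs_lowgrade_UTUC = list(
      keep = function(label, subtype)
        subtype %in% c("high-grade UTUC", "low-grade UTUC"),
      relabel = function(label, subtype) subtype,
      positive = "high-grade UTUC"),
    UTUC_vs_nccRCC = list(
      # all UTUC plus every RCC subtype except clear cell
      keep = function(label, subtype)
        label == "UTUC" | (label == "RCC" & subtype != "ccRCC"),
      relabel = function(label, subtype)
        ifelse(label == "UTUC", "UTUC", "nccRCC"),
      positive = "UTUC"))
}

#' Select and relabel cases for one classification task
#'
#' The four tasks mirror the study design: the entire cohort (UTUC vs
#' RCC), clear cell RCC vs high-grade UTUC, high- vs low-grade UTUC, and
#' UTUC vs non-clear-cell RCC. The nccRCC task keeps every RCC subtype
#' except clear cell (papillary, chromophobe, sarcomatoid, other)
#' together with all UTUC cases; its size is therefore determined by the
#' configured subtype mix.
#'
#' @param cases list of [lesion_case()]s (or a `feature_table` with
#'   `label` and `subtype` columns).
#' @param task one of `"UTUC_vs_RCC"`, `"ccRCC_vs_highgradeUTUC"`,
#'   `"highgrade_vs_lowgrade_UTUC"`, `"UTUC_vs_nccRCC"`.
#' @return For a case list: list with `cases`, `labels`, `positive`,
#'   `counts`. For a feature table: the filtered, relabeled table with
#'   attribute `positive`.
#' @export
select_task_cases <- function(cases, task = names(task_registry())) {
  task <- match.arg(task)
  spec <- task_registry()[[task]]
  if (is.data.frame(cases)) {
    lab <- as.character(cases$label)
    sub <- as.character(cases$subtype)
    keep <- spec$keep(lab, sub)
    out <- cases[keep, , drop = FALSE]
    out$label <- spec$relabel(lab[keep], sub[keep])
    if (length(unique(out$label)) < 2L)
      stop("task '", task, "' leaves fewer than 2 classes")
    attr(out, "positive") <- spec$positive
    return(out)
  }
  lab <- vapply(cases, function(cs) as.character(cs$label), character(1))
  sub <- vapply(cases, function(cs)
    if (is.null(cs$subtype)) NA_character_ else cs$subtype, character(1))
  if (task != "UTUC_vs_RCC" && anyNA(sub))
    stop("task '", task, "' needs subtype annotations on every case")
  keep <- spec$keep(lab, sub)
  newlab <- spec$relabel(lab[keep], sub[keep])
  if (length(unique(newlab)) < 2L)
    stop("task '", task, "' leaves fewer than 2 classes")
  list(cases = cases[keep], labels = newlab, positive = spec$positive,
       counts = table(newlab))
}

#' Configure an end-to-end radiomics experiment
#'
#' @param cohort a [cohort_config()] (phantom source) or a pre-generated
#'   list of [lesion_case()]s.
#' @param task classification task, see [select_task_cases()].
#' @param split_fraction training fraction (default 0.70).
#' @param icc_threshold ICC retention threshold (default 0.8).
#' @param icc_scope `"all"` computes ICC on the full dual-read subsample
#'   before splitting (mirrors the study design); `"train"` restricts ICC
#'   to dual-read cases in the training split (strict no-leak mode).
#' @param n_bins,glcm_distance,glcm_policy extraction settings, see
#'   [extract_panel()].
#' @param folds,alpha,cv_metric model settings, see
#'   [fit_radiomic_score()].
#' @param seed master seed for split and CV folds.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, task = "UTUC_vs_RCC",
                              split_fraction = 0.70, icc_threshold = 0.8,
                              icc_scope = c("all", "train"),
                              n_bins = 32, glcm_distance = 1,
                              glcm_policy = "average", folds = 10,
                              alpha = 1, cv_metric = "deviance",
                              seed = 1L) {
  icc_scope <- match.arg(icc_scope)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("'split_fraction' must be strictly between 0 and 1")
  structure(
    list(cohort = cohort, task = task, split_fraction = split_fraction,
         icc_threshold = icc_threshold, icc_scope = icc_scope,
         n_bins = n_bins, glcm_distance = glcm_distance,
         glcm_policy = glcm_policy, folds = folds, alpha = alpha,
         cv_metric = cv_metric, seed = as.integer(seed)),
    class = "experiment_config")
}

#' Run the end-to-end radiomics experiment
#'
#' Pipeline stages: cohort intake (generate phantoms or use the supplied
#' cases) -> feature extraction for both readers -> ICC reliability
#' filtering -> task selection -> stratified 70/30 split -> z-score
#' normalization fitted on the training split -> cross-validated LASSO
#' logistic score -> ROC evaluation on train and test. The report carries
#' the train-derived Youden cutoff applied to the test split as well as a
#' separately optimized test-split cutoff, clearly labelled. Everything
#' is reproducible from (config, seed); no test-split value enters any
#' train-derived artifact (normalization, retained features, penalty,
#' train cutoff), with ICC scoped per `icc_scope`.
#'
#' @param config an [experiment_config()].
#' @param cases optional pre-generated cohort overriding
#'   `config$cohort` (useful to reuse one cohort across tasks).
#' @return An object of class `radiomics_experiment`.
#' @export
run_experiment <- function(config, cases = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cases)) {
    cases <- if (inherits(config$cohort, "cohort_config"))
      generate_cohort(config$cohort) else config$cohort
  }
  feats1 <- extract_cohort_features(
    cases, reader = 1, n_bins = config$n_bins,
    glcm_distance = config$glcm_distance,
    glcm_policy = config$glcm_policy)
  feats2 <- extract_cohort_features(
    cases, reader = 2, n_bins = config$n_bins,
    glcm_distance = config$glcm_distance,
    glcm_policy = config$glcm_policy)

  sel <- select_task_cases(feats1, config$task)
  positive <- attr(sel, "positive")
  split <- split_cohort(sel$label, fraction = config$split_fraction,
                        seed = config$seed)
  train_tab <- sel[split$train, , drop = FALSE]
  test_tab <- sel[split$test, , drop = FALSE]

  icc_tab1 <- if (config$icc_scope == "train")
    feats1[feats1$case_id %in% train_tab$case_id, , drop = FALSE]
  else feats1
  icc <- filter_features(icc_tab1, feats2, threshold = config$icc_threshold)
  retained <- icc$retained
  if (length(retained) < 1L)
    stop("ICC filtering retained no features")

  keep_cols <- c("case_id", "label", "subtype", retained)
  model <- fit_radiomic_score(
    feature_table(as.data.frame(train_tab)[, keep_cols]),
    positive = positive, folds = config$folds, alpha = config$alpha,
    cv_metric = config$cv_metric, seed = config$seed + 1L)

  sc_train <- predict(model, train_tab)
  sc_test <- predict(model, test_tab)
  roc_train <- roc_analysis(sc_train, train_tab$label, positive = positive)
  roc_test <- roc_analysis(sc_test, test_tab$label, positive = positive)
  at_train_cutoff <- classification_metrics(
    sc_test, test_tab$label, cutoff = roc_train$cutoff,
    positive = positive)

  structure(
    list(task = config$task, positive = positive,
         counts = table(sel$label), n_train = nrow(train_tab),
         n_test = nrow(test_tab), icc = icc, retained = retained,
         model = model, roc_train = roc_train, roc_test = roc_test,
         train_metrics = list(
           auc = roc_train$auc, cutoff = roc_train$cutoff,
           sensitivity = roc_train$sensitivity_at_cutoff,
           specificity = roc_train$specificity_at_cutoff),
         test_metrics = list(
           auc = roc_test$auc,
           train_cutoff = roc_train$cutoff,
           sensitivity_at_train_cutoff = unname(at_train_cutoff[1]),
           specificity_at_train_cutoff = unname(at_train_cutoff[2]),
           test_optimized_cutoff = roc_test$cutoff,
           sensitivity_at_test_cutoff = roc_test$sensitivity_at_cutoff,
           specificity_at_test_cutoff = roc_test$specificity_at_cutoff),
         scores = list(train = sc_train, test = sc_test,
                       train_labels = train_tab$label,
                       test_labels = test_tab$label,
                       train_ids = train_tab$case_id,
                       test_ids = test_tab$case_id),
         config = config[setdiff(names(config), "cohort")],
         seed = config$seed,
         panel_version = attr(feature_panel(), "panel_version")),
    class = "radiomics_experiment")
}

#' @export
print.radiomics_experiment <- function(x, ...) {
  cat("Radiomics experiment:", x$task, "\n")
  cat("  cohort: ", paste(sprintf("%s = %d", names(x$counts), x$counts),
                          collapse = ", "),
      " (train ", x$n_train, " / test ", x$n_test, ")\n", sep = "")
  cat("  ICC-retained features:", length(x$retained), "of",
      length(x$icc$icc), "\n")
  cat("  selected by LASSO:", sum(x$model$coefficients != 0),
      "features\n")
  cat(sprintf("  train: AUC %.3f, cutoff %.3f (sens %.3f, spec %.3f)\n",
              x$train_metrics$auc, x$train_metrics$cutoff,
              x$train_metrics$sensitivity, x$train_metrics$specificity))
  cat(sprintf(
    "  test:  AUC %.3f; at train cutoff: sens %.3f, spec %.3f\n",
    x$test_metrics$auc, x$test_metrics$sensitivity_at_train_cutoff,
    x$test_metrics$specificity_at_train_cutoff))
  cat(sprintf(
    "         test-optimized cutoff %.3f (sens %.3f, spec %.3f)\n",
    x$test_metrics$test_optimized_cutoff,
    x$test_metrics$sensitivity_at_test_cutoff,
    x$test_metrics$specificity_at_test_cutoff))
  invisible(x)
}

#' @export
summary.radiomics_experiment <- function(object, ...) {
  print(object)
  cat("\nSelected features:\n")
  print(summary(object$model)$selected, row.names = FALSE)
  invisible(object)
}
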