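test_that("z-score normalization centers training data and only training data", {
  tab <- make_sim_table(n = 80, p = 6, seed = 5)
  prm <- zscore_fit(tab)
  z <- zscore_apply(prm, tab)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)

  # means/sds equal brute-force recomputation
  m <- as.matrix(as.data.frame(tab)[, prm$features])
  expect_equal(unname(prm$mean), unname(colMeans(m)))
  expect_equal(unname(prm$sd), unname(apply(m, 2, sd)))

  # a shifted copy maps its means exactly to the shift in z units
  shifted <- tab
  for (f in prm$features) shifted[[f]] <- shifted[[f]] + 3
  z2 <- zscore_apply(prm, shifted)
  expect_equal(unname(colMeans(z2)), unname(3 / prm$sd),
               tolerance = 1e-10)

  # held-out data transformed with training parameters is generally not
  # centered
  test_tab <- make_sim_table(n = 40, p = 6, seed = 6)
  expect_gt(max(abs(colMeans(zscore_apply(prm, test_tab)))), 1e-3)

  # zero-variance features are excluded with a report, not divided by 0
  degen <- tab
  degen[[prm$features[1]]] <- 7
  prm2 <- zscore_fit(degen)
  expect_true(prm$features[1] %in% prm2$excluded_zero_variance)
  expect_false(prm$features[1] %in% prm2$features)
})

test_that("the full-shrinkage limit gives an intercept-only model at the prevalence", {
  tab <- make_sim_table(n = 90, p = 8, seed = 2)
  tab$label <- rep(c("A", "A", "B"), 30)  # prevalence 1/3
  fit <- fit_radiomic_score(tab, lambda_fixed = 10, positive = "B")
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, qlogis(1 / 3), tolerance = 1e-6)
})

test_that("the unpenalized limit matches an independent logistic optimizer", {
  tab <- make_sim_table(n = 150, p = 4, informative = 1, shift = 1,
                        seed = 3)
  fit <- fit_radiomic_score(tab, lambda_fixed = 0)
  z <- zscore_apply(fit$normalization, tab)
  ref <- glm(I(tab$label == "B") ~ z, family = binomial)
  expect_equal(unname(fit$intercept), unname(coef(ref)[1]),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-4)
})

test_that("sparsity is monotone along the penalty path", {
  tab <- make_sim_table(n = 200, p = 15, informative = c(2, 9),
                        shift = 1.2, seed = 8)
  fit <- fit_radiomic_score(tab, folds = 5, seed = 4)
  # lambda_grid is decreasing; the active set never shrinks as the
  # penalty relaxes
  expect_true(all(diff(fit$lambda_grid) < 0))
  expect_true(all(diff(fit$nonzero_path) >= 0))
})

test_that("informative features are recovered and noise shrunk to zero", {
  tab <- make_sim_table(n = 400, p = 19, informative = c(3, 11),
                        shift = 2, seed = 9)
  fit <- fit_radiomic_score(tab, folds = 10, seed = 10)
  beta <- abs(fit$coefficients)
  feats <- fit$feature_names
  top2 <- names(sort(beta, decreasing = TRUE))[1:2]
  expect_setequal(top2, feats[c(3, 11)])
  noise_beta <- fit$coefficients[setdiff(feats, feats[c(3, 11)])]
  expect_gt(mean(noise_beta == 0), 0.5)
})

test_that("scores are calibrated logistic probabilities of the linear predictor", {
  # hand-computed 3-feature toy model
  model <- structure(
    list(feature_names = c("f1", "f2", "f3"),
         normalization = structure(
           list(mean = c(f1 = 1, f2 = -2, f3 = 0),
                sd = c(f1 = 2, f2 = 1, f3 = 4),
                features = c("f1", "f2", "f3"),
                excluded_zero_variance = character(0)),
           class = "zscore_params"),
         intercept = 0.25,
         coefficients = c(f1 = 0.5, f2 = -1.2, f3 = 0),
         classes = c("A", "B"), positive_class = "B"),
    class = "radscore")
  x <- c(f1 = 3, f2 = -1, f3 = 100)
  eta <- 0.25 + 0.5 * (3 - 1) / 2 + (-1.2) * (-1 + 2) / 1
  expect_equal(radiomics_score(model, x), plogis(eta),
               tolerance = 1e-12)

  # zero coefficients and intercept: score 1/2
  m0 <- model; m0$coefficients[] <- 0; m0$intercept <- 0
  expect_equal(radiomics_score(m0, x), 0.5)

  # logistic symmetry: negating the linear predictor flips the score
  x2 <- c(f1 = 1 - (3 - 1), f2 = -2 - (-1 + 2), f3 = 0)  # z -> -z
  m1 <- model; m1$intercept <- 0
  expect_equal(radiomics_score(m1, x) + radiomics_score(m1, x2), 1,
               tolerance = 1e-12)

  # a missing feature is an error naming it
  expect_error(radiomics_score(model, c(f1 = 1, f3 = 2)), "f2")
})

test_that("ROC analysis agrees with pair counting and handles the null", {
  # perfectly separated scores
  r <- roc_analysis(c(.1, .2, .3, .8, .9), c("n", "n", "n", "p", "p"),
                    positive = "p")
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity_at_cutoff, 1)
  expect_equal(r$specificity_at_cutoff, 1)
  expect_true(r$cutoff > 0.3 && r$cutoff <= 0.8)

  # random small inputs with ties vs the pair-counting oracle
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(6:15, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lb <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    r2 <- roc_analysis(sc, lb, positive = "b")
    expect_equal(r2$auc, oracle_auc(sc, lb, "b"), tolerance = 1e-12)
  }

  # permutation null at n = 1000
  set.seed(31)
  sc <- rnorm(1000)
  lb <- sample(rep(c("x", "y"), 500))
  expect_lt(abs(roc_analysis(sc, lb, positive = "y")$auc - 0.5), 0.05)

  expect_error(roc_analysis(1:4, rep("a", 4)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(44)
  sc <- rnorm(60)
  lb <- rep(c("a", "b"), 30)
  a0 <- roc_analysis(sc, lb, positive = "b")$auc
  expect_equal(roc_analysis(plogis(3 * sc + 1), lb, positive = "b")$auc,
               a0, tolerance = 1e-12)
  expect_equal(roc_analysis(exp(sc), lb, positive = "b")$auc, a0,
               tolerance = 1e-12)
})

test_that("ROC cross-checks against an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(66)
  sc <- round(rnorm(80), 1)
  lb <- sample(c("a", "b"), 80, replace = TRUE)
  mine <- roc_analysis(sc, lb, positive = "b")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("a", "b"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("model methods print, summarize, predict and plot coherently", {
  tab <- make_sim_table(n = 100, p = 8, informative = 2, shift = 2,
                        seed = 13)
  fit <- fit_radiomic_score(tab, folds = 5, seed = 14)
  expect_output(print(fit), "radiomic score")
  expect_output(print(summary(fit)), "selected features")
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), fit$intercept)
  sc <- predict(fit, tab)
  expect_true(all(sc >= 0 & sc <= 1))
  eta <- predict(fit, tab, type = "link")
  expect_equal(plogis(eta), sc, tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
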