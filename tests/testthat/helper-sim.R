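# Feature-matrix-level simulation: Gaussian noise features with an
# optional class shift on selected columns, wrapped as a feature table
# (column names drawn from the registered panel so schema checks pass).

make_sim_table <- function(n = 120, p = 10, informative = integer(0),
                           shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("A", "B"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    for (j in informative) X[y == "B", j] <- X[y == "B", j] + shift
    colnames(X) <- sprintf("Firstorder.intensity.%s",
                           c("Mean", "Std", "Variance", "Median", "Min",
                             "Max", "Range", "Root.mean.square", "Energy",
                             "Mean.abs.deviation", "Median.abs.deviation",
                             "Robust.mean.abs.deviation", "Skewness",
                             "Kurtosis", "P10", "P25", "P75", "P90",
                             "Interquartile.range")[seq_len(p)])
    df <- data.frame(case_id = sprintf("s%03d", seq_len(n)), label = y,
                     stringsAsFactors = FALSE)
    feature_table(cbind(df, as.data.frame(X)))
  })
}
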