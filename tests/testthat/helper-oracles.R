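# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition with plain loops / direct formulas, sharing
# no code with the package internals they check.

oracle_first_order <- function(raw, bins, ng) {
  n <- length(raw)
  cnt <- sapply(seq_len(ng), function(k) sum(bins == k))
  p <- cnt / n
  ent <- 0
  for (k in seq_len(ng)) if (p[k] > 0) ent <- ent - p[k] * log2(p[k])
  psd <- function(v) sqrt(sum((v - sum(v) / length(v))^2) / length(v))
  skw <- function(v) {
    s <- psd(v); if (s == 0) 0 else
      sum((v - mean(v))^3) / length(v) / s^3
  }
  krt <- function(v) {
    s <- psd(v); if (s == 0) 0 else
      sum((v - mean(v))^4) / length(v) / s^4
  }
  qb <- quantile(bins, c(.1, .9), names = FALSE)
  qx <- quantile(raw, c(.1, .25, .75, .9), names = FALSE)
  trim <- raw[raw >= qx[1] & raw <= qx[4]]
  h <- c(Entropy = ent, Mean = sum(bins) / n, Std = psd(bins),
         Variance = psd(bins)^2, Median = median(bins), Min = min(bins),
         Max = max(bins), Range = max(bins) - min(bins),
         Mean.abs.deviation = sum(abs(bins - mean(bins))) / n,
         Median.abs.deviation = sum(abs(bins - median(bins))) / n,
         Skewness = skw(bins), Kurtosis = krt(bins),
         Uniformity = sum(p^2), Mode = which(cnt == max(cnt))[1],
         P10 = qb[1], P90 = qb[2])
  i <- c(Mean = sum(raw) / n, Std = psd(raw), Variance = psd(raw)^2,
         Median = median(raw), Min = min(raw), Max = max(raw),
         Range = max(raw) - min(raw),
         Root.mean.square = sqrt(sum(raw^2) / n), Energy = sum(raw^2),
         Mean.abs.deviation = sum(abs(raw - mean(raw))) / n,
         Median.abs.deviation = sum(abs(raw - median(raw))) / n,
         Robust.mean.abs.deviation = sum(abs(trim - mean(trim))) /
           length(trim),
         Skewness = skw(raw), Kurtosis = krt(raw),
         P10 = qx[1], P25 = qx[2], P75 = qx[3], P90 = qx[4],
         Interquartile.range = qx[3] - qx[2])
  c(setNames(h, paste0("Firstorder.histogram.", names(h))),
    setNames(i, paste0("Firstorder.intensity.", names(i))))
}

# All 13 unique 3D offsets, written out explicitly.
oracle_offsets <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# Brute-force symmetric GLCM: scan every in-mask voxel against every
# offset, count ordered pairs in both directions.
oracle_build_glcm <- function(coords, bins, ng, distance = 1,
                              policy = "average") {
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  lut <- setNames(bins, key)
  offs <- oracle_offsets() * distance
  mats <- list()
  for (d in seq_len(nrow(offs))) {
    m <- matrix(0, ng, ng)
    found <- FALSE
    for (v in seq_len(nrow(coords))) {
      nb <- coords[v, ] + offs[d, ]
      nk <- paste(nb[1], nb[2], nb[3])
      if (!is.na(lut[nk])) {
        i <- bins[v]; j <- lut[[nk]]
        m[i, j] <- m[i, j] + 1
        m[j, i] <- m[j, i] + 1
        found <- TRUE
      }
    }
    if (found) mats[[length(mats) + 1]] <- m
  }
  if (!length(mats)) return(NULL)
  if (policy == "average") {
    acc <- matrix(0, ng, ng)
    for (m in mats) acc <- acc + m / sum(m)
    acc / length(mats)
  } else {
    tot <- Reduce(`+`, mats)
    tot / sum(tot)
  }
}

# Double-loop evaluation of every GLCM feature from its definition.
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * P[i, j]
  jvar <- 0; je <- 0; en <- 0; con <- 0; dis <- 0; id <- 0; idm <- 0
  iv <- 0; ac <- 0; ct <- 0; cs <- 0; cp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    jvar <- jvar + (i - mu)^2 * p
    if (p > 0) je <- je - p * log2(p)
    en <- en + p^2
    con <- con + (i - j)^2 * p
    dis <- dis + abs(i - j) * p
    id <- id + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    if (i != j) iv <- iv + p / (i - j)^2
    ac <- ac + i * j * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    cp <- cp + (i + j - 2 * mu)^4 * p
  }
  corr <- if (jvar > 0) (ac - mu^2) / jvar else 1
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  da <- sum((0:(ng - 1)) * pd)
  dv <- sum(((0:(ng - 1)) - da)^2 * pd)
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  sa <- sum((2:(2 * ng)) * ps)
  sv <- sum(((2:(2 * ng)) - sa)^2 * ps)
  se <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  c(Glcm.Joint.entropy = je, Glcm.Joint.average = mu,
    Glcm.Joint.variance = jvar, Glcm.Std = sqrt(jvar),
    Glcm.Energy = en, Glcm.Joint.max = max(P), Glcm.Contrast = con,
    Glcm.Dissimilarity = dis, Glcm.Inverse.difference = id,
    Glcm.Inverse.difference.moment = idm, Glcm.Inverse.variance = iv,
    Glcm.Correlation = corr, Glcm.Autocorrelation = ac,
    Glcm.Cluster.tendency = ct, Glcm.Cluster.shade = cs,
    Glcm.Cluster.prominence = cp, Glcm.Difference.average = da,
    Glcm.Difference.variance = dv, Glcm.Difference.entropy = de,
    Glcm.Sum.of.averages = sa, Glcm.Sum.variance = sv,
    Glcm.Sum.entropy = se)
}

# ICC(2,1) via R's own two-way ANOVA decomposition (independent route).
oracle_icc21 <- function(x, y) {
  n <- length(x)
  d <- data.frame(val = c(x, y),
                  case = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- anova(lm(val ~ case + rater, data = d))["Mean Sq"]
  msr <- ms["case", 1]; msc <- ms["rater", 1]
  mse <- ms["Residuals", 1]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# AUC by explicit pair counting (Mann-Whitney with 1/2 for ties).
oracle_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Random small ROI on a <=5^3 grid with at least min_n in-mask voxels.
random_small_roi <- function(min_n = 4, max_dim = 5) {
  dims <- sample(3:max_dim, 3, replace = TRUE)
  repeat {
    m <- array(runif(prod(dims)) < 0.6, dim = dims)
    if (sum(m) >= min_n) break
  }
  vol <- array(round(rnorm(prod(dims), 50, 20), 2), dim = dims)
  list(volume = image_volume(vol), mask = segmentation_mask(m))
}
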