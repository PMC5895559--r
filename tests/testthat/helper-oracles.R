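# Independent brute-force oracles for the image features. These iterate
# voxel-by-voxel with explicit loops and share no code with the package
# implementations.

oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  list(skewness = m3 / m2^1.5, kurtosis_excess = m4 / m2^2 - 3)
}

# All-pairs GLCM dissimilarity: for each of the 13 unique directions,
# enumerate every ordered in-mask pair and average |i - j|; then average
# over directions with at least one pair.
oracle_glcm_dissimilarity <- function(bins, mask) {
  dm <- dim(bins)
  dirs <- list()
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    if (di > 0 || (di == 0 && dj > 0) || (di == 0 && dj == 0 && dk > 0))
      dirs[[length(dirs) + 1]] <- c(di, dj, dk)
  }
  per_dir <- c()
  for (d in dirs) {
    tot <- 0; cnt <- 0
    for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
      if (!mask[i, j, k]) next
      for (s in c(-1, 1)) {             # symmetric: both directions
        ii <- i + s * d[1]; jj <- j + s * d[2]; kk <- k + s * d[3]
        if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
            kk < 1 || kk > dm[3]) next
        if (!mask[ii, jj, kk]) next
        tot <- tot + abs(bins[i, j, k] - bins[ii, jj, kk])
        cnt <- cnt + 1
      }
    }
    if (cnt > 0) per_dir <- c(per_dir, tot / cnt)
  }
  mean(per_dir)
}

# Recursive flood fill over 26-neighbours of equal level.
oracle_glszm <- function(bins, mask) {
  dm <- dim(bins)
  seen <- array(FALSE, dm)
  zones <- integer(0)          # level of each zone
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (!mask[i, j, k] || seen[i, j, k]) next
    lev <- bins[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- v[1] + di; jj <- v[2] + dj; kk <- v[3] + dk
        if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
            kk < 1 || kk > dm[3]) next
        if (!mask[ii, jj, kk] || seen[ii, jj, kk]) next
        if (bins[ii, jj, kk] != lev) next
        seen[ii, jj, kk] <- TRUE
        stack[[length(stack) + 1]] <- c(ii, jj, kk)
      }
    }
    zones <- c(zones, lev)
  }
  nz <- length(zones)
  z <- table(zones)
  list(glnu = sum(as.numeric(z)^2) / nz,
       zone_percentage = nz / sum(mask))
}

# Per-voxel neighbourhood-average loop for NGTDM coarseness.
oracle_ngtdm_coarseness <- function(bins, mask) {
  dm <- dim(bins)
  lev_all <- c(); dev_all <- c()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (!mask[i, j, k]) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]) next
      if (mask[ii, jj, kk]) nb <- c(nb, bins[ii, jj, kk])
    }
    if (length(nb) == 0) next
    lev_all <- c(lev_all, bins[i, j, k])
    dev_all <- c(dev_all, abs(bins[i, j, k] - mean(nb)))
  }
  N <- length(lev_all)
  tot <- 0
  for (lv in unique(lev_all)) {
    sel <- lev_all == lv
    tot <- tot + (sum(sel) / N) * sum(dev_all[sel])
  }
  1 / (1e-12 + tot)
}

# Breslow log partial likelihood for a single covariate (no ties assumed
# in the fixtures that use it).
oracle_cox_loglik_1d <- function(beta, times, events, x) {
  ll <- 0
  for (i in seq_along(times)) {
    if (!events[i]) next
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Hand log-rank: observed minus expected over the pooled event times.
oracle_logrank_2g <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
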