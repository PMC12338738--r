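# Independent oracles, coded as literal step-by-step transcriptions so they
# stay independent of the (vectorised) implementation paths they check.

# Five-step MAD-trim modified Z, one element at a time.
oracle_modified_z <- function(x, lo = -10, hi = 10) {
  med <- median(x)
  devs <- numeric(length(x))
  for (i in seq_along(x)) devs[i] <- abs(x[i] - med)
  MAD <- median(devs)
  trimmed <- x[devs <= 2 * MAD]
  med2 <- median(trimmed)
  devs2 <- numeric(length(trimmed))
  for (i in seq_along(trimmed)) devs2[i] <- abs(trimmed[i] - med2)
  MAD2 <- median(devs2)
  z <- numeric(length(x))
  if (MAD2 > 0) {
    for (i in seq_along(x)) z[i] <- 0.6745 * (x[i] - med2) / MAD2
  } else {
    mnad <- mean(devs2)
    if (mnad > 0) {
      for (i in seq_along(x)) z[i] <- (x[i] - med2) / (1.2533 * mnad)
    } # else: all zero already
  }
  for (i in seq_along(z)) {
    if (z[i] < lo) z[i] <- lo
    if (z[i] > hi) z[i] <- hi
  }
  z
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration
# (minimum-likelihood rule) for the table [[a, b], [c, d]].
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, r1 - (n - c1))
  hi <- min(r1, c1)
  k <- lo:hi
  probs <- dhyper(k, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Agglomerative Ward linkage (Lance-Williams update on squared Euclidean
# distances, heights reported on the distance scale) -- a direct
# transcription used to cross-check stats::hclust(method = "ward.D2").
oracle_ward_heights <- function(x) {
  d2 <- as.matrix(dist(x))^2
  n <- nrow(d2)
  size <- rep(1, n)
  active <- rep(TRUE, n)
  cur <- d2
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which(active)
    bi <- bj <- NA_integer_
    bh <- Inf
    for (i in idx) {
      for (j in idx) {
        if (i < j && cur[i, j] < bh) {
          bh <- cur[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    heights[s] <- sqrt(bh)
    for (k in idx) {
      if (k != bi && k != bj) {
        upd <- ((size[bi] + size[k]) * cur[bi, k] +
                  (size[bj] + size[k]) * cur[bj, k] -
                  size[k] * cur[bi, bj]) /
          (size[bi] + size[bj] + size[k])
        cur[bi, k] <- cur[k, bi] <- upd
      }
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
  }
  heights
}
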