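# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Each oracle re-derives the quantity from its
# definition, not from the package implementation.

# Savitzky-Golay by explicit sliding local least-squares fits; edges use the
# terminal window's fit evaluated at the off-centre position.
oracle_sg <- function(y, w, p) {
  n <- length(y)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- if (i <= h) 1:w else if (i > n - h) (n - w + 1L):n else (i - h):(i + h)
    B <- outer(idx - i, 0:p, "^")
    out[i] <- qr.solve(B, y[idx])[1]
  }
  out
}

# Kennard-Stone by exhaustive recomputation: seed pair = max distance (ties
# to smallest (i, j)), then repeatedly the sample maximising its minimum
# distance to everything selected (ties to lowest row index).
oracle_kennard_stone <- function(X, n_train) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  best <- c(NA, NA); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# Exhaustive marker scan: all strict local maxima of |dbm|, topographic
# prominence computed by definition, then the same greedy rule.
oracle_markers <- function(dbm, axis, n_peaks = 7, min_sep = 8, frac = 0.05) {
  a <- abs(dbm)
  n <- length(a)
  peaks <- integer(0)
  for (i in 2:(n - 1)) if (a[i] > a[i - 1] && a[i] > a[i + 1]) {
    peaks <- c(peaks, i)
  }
  prom <- sapply(peaks, function(i) {
    higher_l <- which(a[seq_len(i - 1)] > a[i])
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    left <- min(a[lo:i])
    higher_r <- which(a[(i + 1):n] > a[i]) + i
    hi <- if (length(higher_r)) min(higher_r) - 1L else n
    right <- min(a[i:hi])
    a[i] - max(left, right)
  })
  peaks <- peaks[prom >= frac * max(a)]
  peaks <- peaks[order(-a[peaks], peaks)]
  kept <- integer(0)
  for (i in peaks) {
    if (length(kept) >= n_peaks) break
    if (all(abs(axis[i] - axis[kept]) >= min_sep)) kept <- c(kept, i)
  }
  sort(axis[kept])
}

# small labelled two-class scenario for fast pipeline tests
tiny_preset <- function(name = "case3", seed = 1, rows = 8, cols = 8, ...) {
  case_presets(name, map_rows = rows, map_cols = cols, seed = seed, ...)
}

# deterministic random spectra matrix fixture
random_spectra <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m)
}
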