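# Independently coded brute-force oracles used across the suite.
# Each deliberately avoids the package's own code paths.

oracle_tmm <- function(s, r, trim_m = 0.30, trim_a = 0.05) {
  s <- as.numeric(s); r <- as.numeric(r)
  ns <- sum(s); nr <- sum(r)
  keep <- s > 0 & r > 0
  ys <- s[keep]; yr <- r[keep]
  m <- log2((ys / ns) / (yr / nr))
  a <- 0.5 * log2((ys / ns) * (yr / nr))
  v <- (ns - ys) / (ns * ys) + (nr - yr) / (nr * yr)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  wm <- sum((m / v)[keep2]) / sum((1 / v)[keep2])
  # raw pair factors (2^wm, 1) divided by their geometric mean
  2^(wm / 2)
}

oracle_shrunken_logfc <- function(ys, yr, f, prior = 12) {
  ls <- sum(ys) * f; lr <- sum(yr) / f
  lb <- (ls + lr) / 2
  ps <- prior * ls / lb; pr <- prior * lr / lb
  log2(((ys + ps) / (ls + 2 * ps)) / ((yr + pr) / (lr + 2 * pr)))
}

oracle_quantile_normalize <- function(x) {
  n <- nrow(x)
  sorted <- sapply(seq_len(ncol(x)), function(j) sort(x[, j]))
  target <- rowMeans(matrix(sorted, nrow = n))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    ranked_target <- numeric(n)
    ranked_target[o] <- target
    for (v in unique(x[, j])) {
      idx <- which(x[, j] == v)
      ranked_target[idx] <- mean(ranked_target[idx])
    }
    out[, j] <- ranked_target
  }
  out
}

oracle_q1 <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  h <- 0.25 * (n - 1)
  lo <- floor(h)
  if (lo + 1 >= n) return(xs[n])
  xs[lo + 1] * (1 - (h - lo)) + xs[lo + 2] * (h - lo)
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

oracle_nb_exact_p <- function(y1, y2, lib1, lib2, phi) {
  n <- y1 + y2
  if (n == 0) return(1)
  lam <- n / (lib1 + lib2)
  pr <- vapply(0:n, function(k) {
    dnbinom(k, size = 1 / phi, mu = lam * lib1) *
      dnbinom(n - k, size = 1 / phi, mu = lam * lib2)
  }, numeric(1))
  pr <- pr / sum(pr)
  min(sum(pr[pr <= pr[y1 + 1] * (1 + 1e-12)]), 1)
}

# per-base brute force: mean signal in bins of a TSS window
oracle_tss_profile <- function(cov_contig, tss, strand, window, bin) {
  extent <- max(cov_contig$end)
  base_val <- numeric(extent)
  for (i in seq_len(nrow(cov_contig))) {
    base_val[(cov_contig$start[i] + 1):cov_contig$end[i]] <- cov_contig$value[i]
  }
  pos <- (tss - window):(tss + window - 1)   # 0-based bases in window
  vals <- base_val[pos + 1]
  prof <- colMeans(matrix(vals, nrow = bin))
  if (strand == "-") rev(prof) else prof
}

random_screen_pair <- function(n = 500) {
  mu <- rlnorm(n, log(200), 1)
  list(s = rnbinom(n, mu = mu * runif(1, 0.5, 2), size = 5),
       r = rnbinom(n, mu = mu, size = 5))
}
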