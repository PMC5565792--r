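# Independent brute-force oracles used to check the package's statistics.
# Each oracle is a direct enumeration or closed form, sharing no code with
# the implementation it checks.

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# assignments (requires distinct nonzero |d|).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}

# Exact two-sided Mann-Whitney p by enumerating all group-a rank subsets
# (requires untied pooled values).
oracle_mann_whitney_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)), na + nb <= 14)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx])) -
    na * (na + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Exact two-sided Spearman p over all n! permutations (untied inputs).
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 7)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  rhos <- vapply(perms(seq_len(n)), function(p) cor(rx, ry[p]), numeric(1))
  eps <- 1e-12
  p <- 2 * min(mean(rhos <= rho_obs + eps), mean(rhos >= rho_obs - eps))
  min(p, 1)
}

# Friedman chi-square from hand-computed row ranks with tie correction.
oracle_friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  ties <- apply(m, 1, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  c_corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
  stat / c_corr
}

# Convex-hull area by gift wrapping plus a cross-product triangle fan —
# independent of grDevices::chull and the shoelace formula.
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (j in cand[-1]) {
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_j <- sum((pts[j, ] - pts[cur, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_j > d_nxt)) nxt <- j
    }
    if (nxt == start) break
    hull <- c(hull, nxt)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  if (length(hull) < 3) return(0)
  a <- 0
  p0 <- pts[hull[1], ]
  for (i in 2:(length(hull) - 1)) {
    p1 <- pts[hull[i], ]; p2 <- pts[hull[i + 1], ]
    a <- a + ((p1[1] - p0[1]) * (p2[2] - p0[2]) -
                (p1[2] - p0[2]) * (p2[1] - p0[1])) / 2
  }
  abs(unname(a))
}

# Analytic magnitude response of the digital (bilinear-transform)
# Butterworth low-pass at frequency f.
oracle_butter_gain <- function(f, cutoff, rate, order = 2) {
  1 / sqrt(1 + (tan(pi * f / rate) / tan(pi * cutoff / rate))^(2 * order))
}

# Amplitude of a sampled sinusoid at known frequency via least squares on
# a sin/cos basis (robust to sample phase).
fitted_amplitude <- function(x, f, rate) {
  t <- (seq_along(x) - 1) / rate
  fit <- lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(coef(fit)[2:3]^2))
}
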