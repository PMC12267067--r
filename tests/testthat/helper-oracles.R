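# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles by a different route than the package.

# naive O(N) GSEA running-sum walk
brute_es <- function(ranking, set_genes, weight = 1) {
  ord <- order(ranking, decreasing = TRUE)
  s <- ranking[ord]
  hit <- names(s) %in% set_genes
  nr <- sum(abs(s[hit])^weight)
  inc <- numeric(length(s))
  if (nr == 0) inc[hit] <- 1 / sum(hit) else inc[hit] <- abs(s[hit])^weight / nr
  inc[!hit] <- -1 / sum(!hit)
  run <- cumsum(inc)
  mx <- max(run)
  mn <- min(run)
  if (mx >= -mn - 1e-12) mx else mn  # magnitude tie -> positive peak
}

# product-limit estimator by direct product over distinct event times
brute_km <- function(time, event, at) {
  ev_times <- sort(unique(time[event == 1]))
  vapply(at, function(t0) {
    s <- 1
    for (tt in ev_times[ev_times <= t0]) {
      n_risk <- sum(time >= tt)
      d <- sum(time == tt & event == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }, numeric(1))
}

# two-group log-rank chi-square via hypergeometric moments per event time
brute_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  oe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# PV index recomputed in a straight line
brute_pv <- function(mid, ratio, p1 = 15, p2 = 55, log2scale = FALSE) {
  y <- if (log2scale) log2(ratio) else ratio
  ok <- !is.na(y)
  pre <- mean(y[ok & mid < p1])
  men <- mean(y[ok & mid >= p1 & mid < p2])
  post <- mean(y[ok & mid >= p2])
  men - (pre + post) / 2
}

# polynomial least squares through the explicit normal equations
brute_polyfit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# textbook LOWESS: q-nearest-neighbour tricube weighted lm per grid point
brute_lowess <- function(x, y, span, grid) {
  n <- length(x)
  q <- ceiling(span * n)
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    w <- ifelse(d < h, (1 - (d / h)^3)^3, ifelse(d == h & h > 0, 0, NA))
    w[d >= h] <- 0
    if (h == 0) return(mean(y[d == 0]))
    keep <- w > 0
    fit <- stats::lm(y[keep] ~ I(x[keep] - x0), weights = w[keep])
    unname(stats::coef(fit)[1])
  }, numeric(1))
}

# per-cell TPM formula loop
brute_tpm <- function(counts, len_kb) {
  out <- counts
  for (s in seq_len(ncol(counts))) {
    rate <- counts[, s] / len_kb
    for (g in seq_len(nrow(counts))) {
      out[g, s] <- rate[g] / sum(rate) * 1e6
    }
  }
  out
}

# median-of-ratios loop
brute_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  ref <- apply(counts[keep, , drop = FALSE], 1,
               function(r) exp(mean(log(r))))
  apply(counts[keep, , drop = FALSE], 2,
        function(col) median(col / ref))
}

# exact two-sided Fisher p by enumerating all tables with fixed margins
brute_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  kk <- max(0, c1 - m2):min(m1, c1)
  probs <- stats::dhyper(kk, m1, m2, c1)
  obs <- stats::dhyper(a, m1, m2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# one-sided binomial tail by direct pmf summation
brute_binom_tail <- function(k, n, p0) {
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# tpm-mode toy expression matrix for IO / scoring tests
toy_expr <- function(values, kind = "tpm", genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  if (kind == "tpm") m <- sweep(m, 2, colSums(m), "/") * 1e6
  oncosex::expression_matrix(m, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
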