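#' TPM normalization of a count matrix
#'
#' `tpm[g, s] = (count[g, s] / length_kb[g]) / sum_g(count[g, s] /
#' length_kb[g]) * 1e6`. Every output column sums to 1e6; rescaling a
#' sample's library leaves its TPM column unchanged.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @param lengths_kb Named per-gene transcript lengths in kb (> 0); names
#'   must cover all genes.
#' @return An `expr_matrix` of kind `"tpm"`.
#' @export
tpm_normalize <- function(counts, lengths_kb) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_kind(counts) != "counts") stop("input kind must be 'counts'")
  v <- expr_values(counts)
  missing <- setdiff(rownames(v), names(lengths_kb))
  if (length(missing) > 0) {
    stop("missing gene length for: ", paste(head(missing, 5), collapse = ", "))
  }
  len <- lengths_kb[rownames(v)]
  if (any(len <= 0)) stop("gene lengths must be > 0")
  rate <- v / len
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expression_matrix(tpm, "tpm")
}

#' Convert TPM to log2(TPM + 1)
#'
#' @param expr An `expr_matrix` of kind `"tpm"`.
#' @return An `expr_matrix` of kind `"log2tpm"`.
#' @export
log2_tpm <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_kind(expr) == "log2tpm") return(expr)
  if (expr_kind(expr) != "tpm") stop("input kind must be 'tpm'")
  expression_matrix(log2(expr_values(expr) + 1), "log2tpm")
}

#' Median-of-ratios sample size factors
#'
#' The classic RNA-seq normalization: per gene, the geometric mean across
#' samples forms a pseudo-reference; a sample's size factor is the median
#' over all-nonzero genes of its count divided by the reference.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @return Named positive numeric vector of per-sample factors.
#' @export
median_ratio_size_factors <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (expr_kind(counts) != "counts") stop("input kind must be 'counts'")
  v <- expr_values(counts)
  ok <- rowSums(v == 0) == 0
  if (!any(ok)) {
    stop("no gene with nonzero counts in every sample; ",
         "consider a pseudo-reference variant")
  }
  lg <- log(v[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(exp(lg - ref), 2, median)
}

#' Two-group differential expression (Welch t on log2(TPM + 1))
#'
#' Declared stand-in differential-expression procedure: per gene, the log2
#' fold change is the difference of group means on the log2(TPM + 1) scale
#' and the p-value a two-sided Welch t test on that scale, with
#' Benjamini-Hochberg adjustment across genes. A gene is flagged
#' significant when `|log2fc| > fc_threshold` and `q < alpha`.
#'
#' @param expr An `expr_matrix` of kind `"tpm"` or `"log2tpm"`.
#' @param annotation data.frame with columns `sample` and `group` covering
#'   the expression samples.
#' @param group_a,group_b Group labels to contrast; `log2fc > 0` means
#'   higher in `group_a`.
#' @param fc_threshold Absolute log2FC cut-off for the significance flag
#'   (default 1).
#' @param alpha BH-adjusted p cut-off for the significance flag.
#' @return data.frame (class `de_result`): `gene`, `log2fc`, `p`, `q`,
#'   `significant`.
#' @export
differential_expression <- function(expr, annotation, group_a, group_b,
                                    fc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  lx <- log2_tpm(if (expr_kind(expr) == "counts") {
    stop("differential_expression expects tpm or log2tpm input")
  } else {
    expr
  })
  v <- expr_values(lx)
  for (g in c(group_a, group_b)) {
    if (!g %in% annotation$group) stop("group absent from annotation: ", g)
  }
  sa <- annotation$sample[annotation$group == group_a]
  sb <- annotation$sample[annotation$group == group_b]
  sa <- intersect(sa, colnames(v))
  sb <- intersect(sb, colnames(v))
  if (length(sa) < 2 || length(sb) < 2) {
    stop("need at least 2 samples per group")
  }
  a <- v[, sa, drop = FALSE]
  b <- v[, sb, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate genes: zero variance in both groups
  flat <- se2 == 0
  p[flat & (ma == mb)] <- 1
  p[flat & (ma != mb)] <- 0
  q <- p.adjust(p, method = "BH")
  log2fc <- ma - mb
  out <- data.frame(gene = rownames(v), log2fc = log2fc, p = p, q = q,
                    significant = abs(log2fc) > fc_threshold & q < alpha,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Per-gene Pearson correlation with a sample score
#'
#' Correlates every gene's expression across samples with one continuous
#' per-sample score (for example an invasive-signature score). Genes with
#' zero variance get `NA`, never a coerced 0.
#'
#' @param expr An `expr_matrix` (any kind; typically log2tpm).
#' @param score Numeric per-sample score, either named by sample or in
#'   column order.
#' @return Named numeric vector of Pearson r in `[-1, 1]` (or `NA`).
#' @export
gene_score_correlation <- function(expr, score) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr_values(expr)
  if (ncol(v) < 3) stop("need at least 3 samples")
  if (!is.null(names(score))) {
    missing <- setdiff(colnames(v), names(score))
    if (length(missing) > 0) {
      stop("score undefined for samples: ", paste(missing, collapse = ", "))
    }
    score <- score[colnames(v)]
  }
  if (length(score) != ncol(v)) stop("score length does not match samples")
  r <- suppressWarnings(as.vector(cor(t(v), score)))
  names(r) <- rownames(v)
  r
}

#' Pair differential expression with score correlations
#'
#' Inner join of a DE table and a per-gene correlation vector on the gene
#' label, keeping genes present in both with defined values — the data
#' behind a correlation-versus-fold-change scatter.
#'
#' @param de A [differential_expression()] result.
#' @param corr Named per-gene correlation vector.
#' @return data.frame with columns `gene`, `log2fc`, `p`, `q`, `r`.
#' @export
correlation_fc_scatter <- function(de, corr) {
  stopifnot(is.data.frame(de), !is.null(names(corr)))
  shared <- intersect(de$gene, names(corr))
  out <- de[match(shared, de$gene), c("gene", "log2fc", "p", "q")]
  out$r <- unname(corr[shared])
  out <- out[!is.na(out$r) & !is.na(out$log2fc), , drop = FALSE]
  if (nrow(out) == 0) stop("empty gene intersection between DE and correlation")
  rownames(out) <- NULL
  out
}

#' LOWESS smoothing on an explicit evaluation grid
#'
#' Locally weighted linear regression with tricube weights: at each of
#' `n_points` uniformly spaced grid positions over `[min(x), max(x)]`, the
#' `ceiling(span * n)` nearest data points are fitted by weighted least
#' squares and the local line evaluated at the grid position.
#'
#' @param x,y Numeric data vectors (>= 5 points).
#' @param span Fraction of the data in each local window, in `(0, 1]`.
#' @param n_points Size of the uniform evaluation grid (default 1860).
#' @return data.frame with columns `x` (grid) and `y` (smoothed values).
#' @export
lowess_smooth <- function(x, y, span = 0.3, n_points = 1860) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 data points")
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  q <- ceiling(span * n)
  if (q < 3) stop("span too small: local window has fewer than 3 points")
  grid <- seq(min(x), max(x), length.out = n_points)
  yhat <- vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) {
      return(mean(y[d == 0]))
    }
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    xw <- x[use] - x0
    yw <- y[use]
    ww <- w[use]
    sw <- sum(ww); sx <- sum(ww * xw); sxx <- sum(ww * xw^2)
    sy <- sum(ww * yw); sxy <- sum(ww * xw * yw)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-12 * max(sw * sxx, 1e-300)) {
      sy / sw  # degenerate window: weighted mean
    } else {
      (sxx * sy - sx * sxy) / det  # intercept at x0
    }
  }, numeric(1))
  if (any(!is.finite(yhat))) stop("non-finite smoothed values")
  data.frame(x = grid, y = yhat)
}
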