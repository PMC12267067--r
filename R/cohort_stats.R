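#' Pearson chi-square test on a contingency table
#'
#' Wrapper with the cohort-comparison conventions: no continuity
#' correction by default, integral non-negative counts, and a logged
#' warning when any expected count falls below 5.
#'
#' @param x Matrix of counts (>= 2 rows and columns).
#' @param continuity Apply the Yates correction (2x2 only).
#' @return List: `chi2`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(x, continuity = FALSE) {
  x <- as.matrix(x)
  check_count_matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least a 2x2 table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("zero row or column marginal")
  }
  res <- suppressWarnings(chisq.test(x, correct = continuity))
  if (any(res$expected < 5)) {
    warning("expected count below 5: chi-square approximation is coarse")
  }
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration, with an optional
#' Bonferroni adjustment for a family of `m` comparisons.
#'
#' @param x 2x2 matrix of integral counts.
#' @param m Family size for Bonferroni (default 1 = no adjustment).
#' @return List: `odds_ratio` (conditional MLE), `p`, `p_bonferroni`.
#' @export
fisher_exact <- function(x, m = 1) {
  x <- as.matrix(x)
  check_count_matrix(x)
  if (!all(dim(x) == c(2, 2))) stop("fisher_exact expects a 2x2 table")
  res <- fisher.test(x)
  list(odds_ratio = unname(res$estimate), p = res$p.value,
       p_bonferroni = min(1, m * res$p.value))
}

check_count_matrix <- function(x) {
  if (!is.numeric(x)) stop("counts must be numeric")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integral")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. `U` counts pairs where `x` exceeds
#' `y` (ties count 1/2). For small samples (`n_x + n_y <= 12` by default)
#' the null distribution of U is enumerated exactly over all
#' `choose(n, n_x)` group assignments, which remains valid under ties;
#' larger samples use the tie-corrected normal approximation (no
#' continuity correction).
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction of
#'   `x` relative to `y`).
#' @param exact Force exact enumeration on/off; default `NULL` picks exact
#'   when `length(x) + length(y) <= 12`.
#' @return List: `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less",
                                               "greater"), exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (is.null(exact)) exact <- n <= 12
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx_x) {
    sum(r[idx_x]) - nx * (nx + 1) / 2
  }
  U <- u_of(seq_len(nx))
  if (exact) {
    combos <- utils::combn(n, nx)
    u_null <- apply(combos, 2, u_of)
    p_less <- mean(u_null <= U)
    p_greater <- mean(u_null >= U)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_less, p_greater)),
                less = p_less,
                greater = p_greater)
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    ties <- base::table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) stop("degenerate data: all values tied")
    z <- (U - mu) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(z)),
                less = pnorm(z),
                greater = pnorm(z, lower.tail = FALSE))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = min(1, p), method = method)
}

#' Kruskal-Wallis test with Dunn pairwise follow-up
#'
#' Tie-corrected Kruskal-Wallis H across three or more groups, followed by
#' Dunn's pairwise z comparisons on the pooled ranks, adjusted for
#' multiple comparisons (Dunn's Bonferroni-style adjustment by default,
#' Benjamini-Hochberg selectable). All pairs are compared.
#'
#' @param groups Named list of numeric vectors (>= 3 non-empty groups).
#' @param p_adjust `"bonferroni"` or `"BH"` for the pairwise p-values.
#' @return List: `H`, `df`, `p`, and `pairwise` (data.frame: `group1`,
#'   `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 3) {
    stop("need at least 3 groups; use mann_whitney() for two")
  }
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  kw <- kruskal.test(groups)
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  r <- rank(pooled)
  N <- length(pooled)
  ties <- base::table(pooled)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  nn <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / nn[[pr[1]]] + 1 / nn[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = pw["z", ], p = pw["p", ],
                         p_adj = p.adjust(pw["p", ], method = p_adjust),
                         row.names = NULL)
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       pairwise = pairwise)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1 and order-preserving.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Classify lung lesions into micro- and macro-metastases
#'
#' Macro-metastases are lesions strictly bigger than the cutoff (default
#' 0.1 mm); micro-metastases are at or below it.
#'
#' @param sizes Lesion diameters in mm (>= 0); may be empty.
#' @param cutoff Boundary in mm (default 0.1).
#' @return List: `micro`, `macro` (integer counts).
#' @export
classify_lesions <- function(sizes, cutoff = 0.1) {
  if (any(sizes < 0)) stop("lesion sizes must be >= 0")
  list(micro = sum(sizes <= cutoff), macro = sum(sizes > cutoff))
}

#' Venn intersection of gene lists
#'
#' Computes the count of every non-empty membership region across the
#' lists (after case normalization and de-duplication) and returns the
#' genes common to all lists.
#'
#' @param collection Named list (>= 2) of gene-symbol vectors.
#' @param normalize `"upper"` (human convention), `"capitalize"` (mouse)
#'   or `"none"`.
#' @return List: `regions` (named integer vector keyed by
#'   `"listA&listB"`-style membership patterns), `intersection` (sorted
#'   genes in all lists), `union_size`.
#' @export
intersect_gene_sets <- function(collection,
                                normalize = c("upper", "capitalize",
                                              "none")) {
  normalize <- match.arg(normalize)
  if (length(collection) < 2) stop("need at least 2 gene lists")
  if (is.null(names(collection))) {
    names(collection) <- paste0("list", seq_along(collection))
  }
  norm <- switch(normalize,
                 upper = toupper,
                 capitalize = function(g) {
                   paste0(toupper(substr(g, 1, 1)),
                          tolower(substr(g, 2, nchar(g))))
                 },
                 none = identity)
  lists <- lapply(collection, function(g) unique(norm(as.character(g))))
  universe <- sort(unique(unlist(lists)))
  member <- vapply(lists, function(g) universe %in% g,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row) {
    paste(names(lists)[row], collapse = "&")
  })
  regions <- base::table(pattern)
  regions <- setNames(as.integer(regions), names(regions))
  full <- universe[rowSums(member) == length(lists)]
  list(regions = regions, intersection = full,
       union_size = length(universe))
}
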