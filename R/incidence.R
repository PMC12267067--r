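#' Life-period boundaries for the premenopausal variation index
#'
#' Splits the age axis into prepuberty `[0, p1)`, premenopause `[p1, p2)`
#' and postmenopause `[p2, Inf)`. Bracket membership is decided by bracket
#' midpoint, since published incidence grids rarely align exactly with the
#' period boundaries.
#'
#' @param p1,p2 Boundaries in years; defaults 15 and 55.
#' @return An object of class `age_periods`.
#' @export
age_periods <- function(p1 = 15, p2 = 55) {
  if (!(is.finite(p1) && is.finite(p2) && p1 > 0 && p2 > p1)) {
    stop("need 0 < p1 < p2")
  }
  structure(list(p1 = p1, p2 = p2), class = "age_periods")
}

period_of <- function(mid, periods) {
  cut(mid, c(-Inf, periods$p1, periods$p2, Inf),
      labels = c("prepuberty", "premenopause", "postmenopause"),
      right = FALSE)
}

#' Women/men incidence-ratio curve for one cancer
#'
#' Computes the per-bracket ratio of female to male age-standardized rates,
#' plus its log2. Brackets where either sex has a zero rate are kept on the
#' grid but marked undefined (`NA`), so downstream period means can exclude
#' them explicitly rather than silently dropping grid points.
#'
#' @param table An incidence table: data.frame with columns `cancer`, `sex`
#'   (`"F"`/`"M"`), `age_lo`, `age_hi`, `asr` (rate per 100,000).
#' @param cancer Cancer label to extract.
#' @return A data.frame (class `ratio_curve`) with columns `age_lo`,
#'   `age_hi`, `mid`, `asr_f`, `asr_m`, `ratio`, `log2_ratio`; the cancer
#'   label is stored in attribute `"cancer"`.
#' @export
compute_ratio_curve <- function(table, cancer) {
  stopifnot(is.data.frame(table))
  tab <- table[table$cancer == cancer, , drop = FALSE]
  if (nrow(tab) == 0) stop("cancer not found in incidence table: ", cancer)
  f <- tab[tab$sex == "F", ]
  m <- tab[tab$sex == "M", ]
  if (nrow(f) == 0 || nrow(m) == 0) {
    stop("both sexes must be present for cancer ", cancer)
  }
  f <- f[order(f$age_lo), ]
  m <- m[order(m$age_lo), ]
  if (nrow(f) != nrow(m) || any(f$age_lo != m$age_lo) ||
      any(f$age_hi != m$age_hi)) {
    stop("female and male bracket grids differ for cancer ", cancer)
  }
  if (any(tab$asr < 0)) stop("negative ASR in incidence table")
  ratio <- ifelse(f$asr > 0 & m$asr > 0, f$asr / m$asr, NA_real_)
  if (all(is.na(ratio))) {
    stop("degenerate input: all brackets undefined for cancer ", cancer)
  }
  out <- data.frame(
    age_lo = f$age_lo, age_hi = f$age_hi, mid = (f$age_lo + f$age_hi) / 2,
    asr_f = f$asr, asr_m = m$asr,
    ratio = ratio, log2_ratio = log2(ratio)
  )
  attr(out, "cancer") <- cancer
  class(out) <- c("ratio_curve", "data.frame")
  out
}

#' Premenopausal variation (PV) index and sex-bias classification
#'
#' The PV index contrasts the mean women/men incidence ratio during
#' premenopause against the surrounding life periods:
#' `PV = mu_premenopause - (mu_prepuberty + mu_postmenopause) / 2`,
#' where each `mu` is the unweighted mean of the (raw or log2) ratio over
#' the defined brackets whose midpoint falls in the period. The sign and
#' size of PV classify the cancer via [classify_pv()].
#'
#' @param curve A [compute_ratio_curve()] result.
#' @param periods An [age_periods()] object.
#' @param scale `"raw_ratio"` (default) or `"log2_ratio"`.
#' @return An object of class `pv_result`: list with `cancer`, `pv`,
#'   `period_means` (named length-3), `bias_class`, `scale`.
#' @export
premenopausal_variation_index <- function(curve, periods = age_periods(),
                                          scale = c("raw_ratio",
                                                    "log2_ratio")) {
  scale <- match.arg(scale)
  stopifnot(inherits(curve, "ratio_curve"), inherits(periods, "age_periods"))
  y <- if (scale == "raw_ratio") curve$ratio else curve$log2_ratio
  per <- period_of(curve$mid, periods)
  mu <- vapply(levels(per), function(p) {
    v <- y[per == p & !is.na(y)]
    if (length(v) == 0) {
      stop("degenerate input: no defined bracket in period ", p)
    }
    mean(v)
  }, numeric(1))
  pv <- mu[["premenopause"]] -
    (mu[["prepuberty"]] + mu[["postmenopause"]]) / 2
  structure(list(cancer = attr(curve, "cancer"), pv = pv,
                 period_means = mu, bias_class = classify_pv(pv),
                 scale = scale),
            class = "pv_result")
}

#' @exportS3Method base::print
print.pv_result <- function(x, ...) {
  cat("PV index for", x$cancer %||% "<curve>", "\n")
  cat(sprintf("  scale: %s\n  PV = %.4f  ->  %s\n", x$scale, x$pv,
              x$bias_class))
  cat(sprintf("  period means: prepuberty %.4f, premenopause %.4f, postmenopause %.4f\n",
              x$period_means[["prepuberty"]],
              x$period_means[["premenopause"]],
              x$period_means[["postmenopause"]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-way sex-bias classification from a PV index
#'
#' `pv > 0.2` is female-biased during premenopause, `pv < -0.2` male-biased,
#' anything else (boundaries included) unbiased. Vectorized.
#'
#' @param pv Numeric PV value(s); must be finite.
#' @return Character vector over
#'   `{"female_biased", "male_biased", "unbiased"}`.
#' @export
classify_pv <- function(pv) {
  if (any(!is.finite(pv))) stop("pv must be finite")
  ifelse(pv > 0.2, "female_biased",
         ifelse(pv < -0.2, "male_biased", "unbiased"))
}

#' Polynomial trend fit of the log2 incidence-ratio curve
#'
#' Ordinary least squares fit of `log2_ratio` against bracket midpoint age
#' with a raw polynomial of the given degree (default quartic), the
#' conventional representation of the women/men ratio dynamic.
#'
#' @param curve A [compute_ratio_curve()] result.
#' @param degree Polynomial degree (default 4).
#' @return Object of class `trend_fit`: `cancer`, `degree`, `coefficients`
#'   (ascending powers, length `degree + 1`), `residual_sse`.
#' @export
fit_polynomial_trend <- function(curve, degree = 4) {
  stopifnot(inherits(curve, "ratio_curve"), degree >= 1)
  ok <- !is.na(curve$log2_ratio)
  x <- curve$mid[ok]
  y <- curve$log2_ratio[ok]
  if (length(x) < degree + 1) {
    stop("underdetermined fit: need at least degree + 1 defined brackets")
  }
  X <- outer(x, 0:degree, `^`)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(cancer = attr(curve, "cancer"), degree = degree,
                 coefficients = unname(beta),
                 residual_sse = sum(fit$residuals^2),
                 x_range = range(x)),
            class = "trend_fit")
}

#' Evaluate a polynomial trend fit at given ages
#'
#' @param object A `trend_fit`.
#' @param age Ages (years) at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector of fitted log2 ratios.
#' @export
predict.trend_fit <- function(object, age, ...) {
  drop(outer(age, 0:object$degree, `^`) %*% object$coefficients)
}

#' Concordance between the PV classification and the fitted trend
#'
#' Automated surrogate for a manual curve check: evaluates the fitted
#' polynomial on a fine age grid, averages it over the three life periods
#' (restricted to the fitted age range), forms the same premenopause-minus-
#' flanks contrast, and flags concordance when its sign agrees with the
#' sign of the PV index — or when `|pv| <= 0.2`, where the classification
#' is unbiased and no direction is claimed.
#'
#' @param pv_result A [premenopausal_variation_index()] result.
#' @param fit A [fit_polynomial_trend()] result on the same curve.
#' @param periods An [age_periods()] object.
#' @param grid_n Grid resolution for the curve averages.
#' @return Logical flag: `TRUE` if concordant.
#' @export
concordance_check <- function(pv_result, fit, periods = age_periods(),
                              grid_n = 600) {
  stopifnot(inherits(pv_result, "pv_result"), inherits(fit, "trend_fit"))
  if (!identical(pv_result$cancer, fit$cancer)) {
    stop("pv_result and fit refer to different cancers")
  }
  if (abs(pv_result$pv) <= 0.2) return(TRUE)
  grid <- seq(fit$x_range[1], fit$x_range[2], length.out = grid_n)
  yhat <- predict(fit, grid)
  per <- period_of(grid, periods)
  mu <- tapply(yhat, per, mean)
  if (any(is.na(mu))) {
    stop("fitted age range does not cover all three periods")
  }
  pv_fit <- mu[["premenopause"]] -
    (mu[["prepuberty"]] + mu[["postmenopause"]]) / 2
  sign(pv_fit) == sign(pv_result$pv)
}

#' Exact binomial enrichment test for female-biased classifications
#'
#' One-sided exact binomial tail probability `P(X >= k)` for observing `k`
#' female-biased cancers out of `n` classified, under a null probability
#' `p0` of any single cancer being called female-biased (default 1/3, the
#' uninformative three-class null).
#'
#' @param classes Character vector of bias classes (from [classify_pv()]).
#' @param p0 Null per-cancer probability of the female-biased call.
#' @return List with `count_female_biased`, `n`, `p_value`.
#' @export
bias_enrichment_test <- function(classes, p0 = 1 / 3) {
  if (length(classes) < 1) stop("need at least one classification")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie in (0, 1)")
  k <- sum(classes == "female_biased")
  n <- length(classes)
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(count_female_biased = k, n = n, p_value = p)
}

#' Per-cancer PV table for a whole incidence table
#'
#' Convenience wrapper running [compute_ratio_curve()],
#' [premenopausal_variation_index()] and [fit_polynomial_trend()] for every
#' cancer in the table.
#'
#' @param table An incidence table.
#' @param periods An [age_periods()] object.
#' @param scale Ratio scale passed through.
#' @param degree Polynomial degree (`NA` skips the trend fit).
#' @return data.frame with one row per cancer: `cancer`, `pv`, `bias_class`,
#'   the three period means, and `concordant` when the fit is computed.
#' @export
pv_table <- function(table, periods = age_periods(),
                     scale = c("raw_ratio", "log2_ratio"), degree = 4) {
  scale <- match.arg(scale)
  cancers <- unique(table$cancer)
  rows <- lapply(cancers, function(cn) {
    curve <- compute_ratio_curve(table, cn)
    pv <- premenopausal_variation_index(curve, periods, scale)
    conc <- NA
    if (!is.na(degree) && sum(!is.na(curve$log2_ratio)) >= degree + 1) {
      fit <- fit_polynomial_trend(curve, degree)
      conc <- concordance_check(pv, fit, periods)
    }
    data.frame(cancer = cn, pv = pv$pv, bias_class = pv$bias_class,
               mu_prepuberty = pv$period_means[["prepuberty"]],
               mu_premenopause = pv$period_means[["premenopause"]],
               mu_postmenopause = pv$period_means[["postmenopause"]],
               concordant = conc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
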