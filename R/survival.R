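#' Expression-threshold survival stratification
#'
#' Splits a cohort on one gene's TPM: `low` when expression is at or below
#' `low_max` (default 0.1 TPM, a clearly negative level), `high` when
#' strictly above `high_min` (default 1 TPM, the conventional limit for
#' sufficient protein expression). Samples in the intermediate band
#' `(low_max, high_min]` are explicitly `excluded` and reported, never
#' silently dropped.
#'
#' @param expr An `expr_matrix` of kind `"tpm"`.
#' @param gene Gene whose expression defines the strata.
#' @param low_max,high_min Thresholds in TPM; `low_max < high_min`.
#' @return data.frame (class `strata_assignment`): `sample`, `expression`,
#'   `group` in `{"low", "high", "excluded"}`; thresholds in attributes.
#' @export
stratify_by_expression <- function(expr, gene, low_max = 0.1,
                                   high_min = 1.0) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_kind(expr) != "tpm") stop("stratification expects TPM input")
  if (!(low_max < high_min)) stop("low_max must be below high_min")
  v <- expr_values(expr)
  if (!gene %in% rownames(v)) stop("gene absent from matrix: ", gene)
  e <- v[gene, ]
  group <- ifelse(e <= low_max, "low",
                  ifelse(e > high_min, "high", "excluded"))
  n_ex <- sum(group == "excluded")
  message(sprintf("strata for %s: %d low, %d high, %d excluded in (%g, %g]",
                  gene, sum(group == "low"), sum(group == "high"),
                  n_ex, low_max, high_min))
  out <- data.frame(sample = colnames(v), expression = unname(e),
                    group = unname(group), row.names = NULL)
  attr(out, "threshold_low") <- low_max
  attr(out, "threshold_high") <- high_min
  class(out) <- c("strata_assignment", "data.frame")
  out
}

#' Kaplan-Meier product-limit curve
#'
#' Product-limit estimate of the survival function for one stratum (or the
#' whole table). Censored subjects leave the risk set without a step;
#' censoring tied with events at the same time is counted after the events
#' (standard convention). `S(0) = 1` and the curve is non-increasing.
#'
#' @param table Survival data.frame with columns `time` (> 0) and `event`
#'   (1 = event, 0 = censored), optionally `stratum`.
#' @param stratum Stratum label to subset on (`NULL` = all rows).
#' @return data.frame: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, starting at a `time = 0`, `survival = 1` row.
#' @export
km_estimate <- function(table, stratum = NULL) {
  stopifnot(is.data.frame(table), all(c("time", "event") %in% names(table)))
  if (!is.null(stratum)) {
    table <- table[table$stratum == stratum, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("empty stratum")
  if (any(table$time <= 0)) stop("survival times must be > 0")
  if (!all(table$event %in% c(0, 1))) stop("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(
    time = c(0, fit$time),
    n_risk = c(fit$n, fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv)
  )
}

#' Log-rank comparison of survival strata
#'
#' Standard (unweighted) log-rank test: at each distinct event time the
#' observed events per group are contrasted with their hypergeometric
#' expectation; the statistic is referred to a chi-square with
#' `groups - 1` degrees of freedom.
#'
#' @param table Survival data.frame (`sample`, `time`, `event`, and
#'   `stratum` unless `groups` is given).
#' @param groups Optional [stratify_by_expression()] assignment joined on
#'   `sample`; its `excluded` samples are dropped before testing.
#' @return List (class `logrank_test`): `chi2`, `df`, `p`, `n`,
#'   `n_events`, `groups`.
#' @export
logrank_test <- function(table, groups = NULL) {
  stopifnot(is.data.frame(table))
  if (!is.null(groups)) {
    keep <- groups$group != "excluded"
    g <- groups[keep, c("sample", "group")]
    table <- merge(table, g, by = "sample")
    table$stratum <- table$group
  }
  if (!"stratum" %in% names(table)) stop("no stratum column or assignment")
  tab <- table(table$stratum)
  if (length(tab) < 2) stop("need at least 2 non-empty groups")
  if (any(tab == 0)) stop("empty stratum: ", names(tab)[tab == 0][1])
  if (sum(table$event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                           data = table)
  df <- length(sd$n) - 1
  p <- pchisq(sd$chisq, df, lower.tail = FALSE)
  structure(list(chi2 = unname(sd$chisq), df = df, p = p,
                 n = sum(sd$n), n_events = sum(table$event),
                 groups = names(tab)),
            class = "logrank_test")
}

#' @exportS3Method base::print
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test (%s): chi2 = %.4f, df = %d, p = %.4g\n",
              paste(x$groups, collapse = " vs "), x$chi2, x$df, x$p))
  invisible(x)
}
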