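#' Default GLOBOCAN-like age bracket grid
#'
#' Eighteen ascending, non-overlapping age brackets: seventeen 5-year
#' brackets from 0 to 85 and an open-ended 85+ bracket (closed at 100 so
#' every bracket has a finite midpoint).
#'
#' @return A data.frame with columns `lo` and `hi` (years, `[lo, hi)`).
#' @export
default_age_brackets <- function() {
  lo <- c(seq(0, 80, by = 5), 85)
  hi <- c(seq(5, 85, by = 5), 100)
  data.frame(lo = lo, hi = hi)
}

#' Simulation configuration for the synthetic cohort generators
#'
#' Bundles every planted parameter the four generators
#' ([gen_incidence_table()], [gen_expression_cohort()],
#' [gen_survival_cohort()], [gen_mouse_metastasis_cohort()]) consume.
#' A fixed `seed` makes every generator deterministic; each generator
#' derives its own RNG stream from `(seed, generator name)`, so adding a
#' generator call never perturbs another's output.
#'
#' @param seed Integer master seed.
#' @param n_cancers Number of cancer types in the incidence table.
#' @param age_brackets data.frame with `lo`/`hi` columns (years, ascending,
#'   non-overlapping); must cover the three life periods defined by
#'   `p1`/`p2`.
#' @param p1,p2 Period boundaries in years: prepuberty `[0, p1)`,
#'   premenopause `[p1, p2)`, postmenopause `[p2, Inf)`.
#' @param bias_amplitude Multiplicative premenopausal female effect on the
#'   ASR, scalar or one value per cancer. 1 means no planted sex bias.
#' @param baseline_asr Baseline age-standardized rate scale (per 100,000).
#' @param asr_noise_sd Log-normal noise sdlog applied to every rate
#'   (0 disables noise).
#' @param n_genes Number of genes in the expression cohort (includes the
#'   built-in signature genes and the planted gene).
#' @param n_samples_per_group Samples per genotype-by-sex group.
#' @param groups Group labels; the default crosses genotype (Ecad/dEcad)
#'   with sex (F/M). Labels must end in `_F` or `_M`.
#' @param planted_gene Name of the single activated gene (GRPR-like).
#' @param planted_gene_log2fc Log2 fold change added to `planted_gene` in
#'   `planted_group`.
#' @param planted_gene_base_log2 Baseline log2-TPM of the planted gene in
#'   the unshifted groups. Kept well above 0 so the fold change measured on
#'   log2(TPM + 1) approximates the planted value.
#' @param planted_group Group receiving the planted single-gene effect.
#' @param signature_shifts `NULL` or a data.frame with columns `signature`,
#'   `group`, `shift` (log2 units) adding a shift to all genes of a built-in
#'   signature in one group. Several rows allow archetype cohorts.
#' @param expr_sd Log2-scale standard deviation of expression noise.
#' @param expr_mode `"tpm"` (log-normal TPM, columns sum to 1e6) or
#'   `"counts"` (negative-binomial counts).
#' @param count_dispersion NB dispersion for counts mode and for metastasis
#'   counts (variance = mu + dispersion * mu^2).
#' @param lib_size Expected library size per sample in counts mode.
#' @param hazard_ratio Hazard ratio of the `high` expression stratum
#'   relative to `low`.
#' @param n_per_stratum Subjects per survival stratum.
#' @param base_hazard Event rate (per month) of the `low` stratum.
#' @param censor_max Upper bound of the independent uniform censoring window
#'   in months (0 disables censoring).
#' @param p_metastasis Named per-group metastasis probabilities; groups not
#'   named fall back to `p_metastasis_default`.
#' @param p_metastasis_default Fallback metastasis probability.
#' @param metastasis_mean_count Mean lesion count among metastatic mice.
#' @param lesion_meanlog,lesion_sdlog Log-normal parameters of lesion
#'   diameters (mm); defaults straddle the 0.1 mm micro/macro boundary.
#' @param n_mice_per_group Mice per group in the metastasis cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_cancers = 24L,
                       age_brackets = default_age_brackets(),
                       p1 = 15, p2 = 55,
                       bias_amplitude = 1,
                       baseline_asr = 20,
                       asr_noise_sd = 0.05,
                       n_genes = 2000L,
                       n_samples_per_group = 8L,
                       groups = c("Ecad_F", "Ecad_M", "dEcad_F", "dEcad_M"),
                       planted_gene = "GRPR",
                       planted_gene_log2fc = 0,
                       planted_gene_base_log2 = 6,
                       planted_group = "dEcad_F",
                       signature_shifts = NULL,
                       expr_sd = 0.5,
                       expr_mode = c("tpm", "counts"),
                       count_dispersion = 0.1,
                       lib_size = 1e6,
                       hazard_ratio = 1,
                       n_per_stratum = 100L,
                       base_hazard = 0.05,
                       censor_max = 60,
                       p_metastasis = c(dEcad_F = 0.63, Ecad_F = 0.16),
                       p_metastasis_default = 0.1,
                       metastasis_mean_count = 5,
                       lesion_meanlog = log(0.1),
                       lesion_sdlog = 0.8,
                       n_mice_per_group = 24L) {
  expr_mode <- match.arg(expr_mode)
  cfg <- list(
    seed = as.integer(seed), n_cancers = as.integer(n_cancers),
    age_brackets = age_brackets, p1 = p1, p2 = p2,
    bias_amplitude = bias_amplitude, baseline_asr = baseline_asr,
    asr_noise_sd = asr_noise_sd,
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = groups, planted_gene = planted_gene,
    planted_gene_log2fc = planted_gene_log2fc,
    planted_gene_base_log2 = planted_gene_base_log2,
    planted_group = planted_group, signature_shifts = signature_shifts,
    expr_sd = expr_sd, expr_mode = expr_mode,
    count_dispersion = count_dispersion, lib_size = lib_size,
    hazard_ratio = hazard_ratio, n_per_stratum = as.integer(n_per_stratum),
    base_hazard = base_hazard, censor_max = censor_max,
    p_metastasis = p_metastasis,
    p_metastasis_default = p_metastasis_default,
    metastasis_mean_count = metastasis_mean_count,
    lesion_meanlog = lesion_meanlog, lesion_sdlog = lesion_sdlog,
    n_mice_per_group = as.integer(n_mice_per_group)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ab <- cfg$age_brackets
  if (!is.data.frame(ab) || !all(c("lo", "hi") %in% names(ab))) {
    stop("age_brackets must be a data.frame with columns lo and hi")
  }
  if (any(ab$hi <= ab$lo)) stop("age brackets must satisfy lo < hi")
  if (nrow(ab) > 1) {
    if (is.unsorted(ab$lo, strictly = TRUE)) {
      stop("age brackets must be ascending")
    }
    if (any(ab$lo[-1] < ab$hi[-nrow(ab)])) {
      stop("age brackets must be non-overlapping")
    }
  }
  if (!(cfg$p1 > 0 && cfg$p2 > cfg$p1)) stop("need 0 < p1 < p2")
  mid <- (ab$lo + ab$hi) / 2
  period <- cut(mid, c(-Inf, cfg$p1, cfg$p2, Inf),
                labels = c("prepuberty", "premenopause", "postmenopause"))
  if (nlevels(droplevels(period)) < 3) {
    stop("configuration error: age brackets must cover prepuberty, ",
         "premenopause and postmenopause")
  }
  probs <- c(cfg$p_metastasis, cfg$p_metastasis_default)
  if (any(probs < 0 | probs > 1)) {
    stop("metastasis probabilities must lie in [0, 1]")
  }
  if (any(cfg$bias_amplitude <= 0)) stop("bias_amplitude must be > 0")
  if (!(length(cfg$bias_amplitude) %in% c(1L, cfg$n_cancers))) {
    stop("bias_amplitude must be scalar or one value per cancer")
  }
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (cfg$asr_noise_sd < 0 || cfg$expr_sd < 0) stop("noise sd must be >= 0")
  if (!cfg$planted_group %in% cfg$groups) {
    stop("planted_group must be one of the group labels")
  }
  if (!all(grepl("_(F|M)$", cfg$groups))) {
    stop("group labels must end in _F or _M")
  }
  if (!is.null(cfg$signature_shifts)) {
    ss <- cfg$signature_shifts
    if (!is.data.frame(ss) ||
        !all(c("signature", "group", "shift") %in% names(ss))) {
      stop("signature_shifts needs columns signature, group, shift")
    }
    if (!all(ss$group %in% cfg$groups)) {
      stop("signature_shifts refers to unknown groups")
    }
  }
  invisible(cfg)
}

# Deterministic per-generator RNG stream: a rolling hash of the generator
# name folded into the master seed, kept below 2^31.
sim_stream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483629L)
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

with_sim_stream <- function(cfg, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sim_stream_seed(cfg$seed, name))
  expr
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  x$age_brackets <- as.list(x$age_brackets)
  if (!is.null(x$signature_shifts)) {
    x$signature_shifts <- as.list(x$signature_shifts)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$age_brackets <- as.data.frame(x$age_brackets)
  if (!is.null(x$signature_shifts)) {
    x$signature_shifts <- as.data.frame(x$signature_shifts)
  }
  if (!is.null(x$p_metastasis)) x$p_metastasis <- unlist(x$p_metastasis)
  do.call(sim_config, x)
}
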