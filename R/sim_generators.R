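#' Simulate a sex- and age-bracketed cancer incidence table
#'
#' Produces age-standardized rates (ASR per 100,000 person-years) per
#' cancer, sex and age bracket. Both sexes share an age-increasing baseline
#' rate; female rates in premenopausal brackets (bracket midpoint in
#' `[p1, p2)`) are multiplied by the per-cancer `bias_amplitude`, and
#' log-normal noise with sdlog `asr_noise_sd` is applied to every cell.
#'
#' @param config A [sim_config()].
#' @return A data.frame (class `incidence_table`) with columns `cancer`,
#'   `sex` (`"F"`/`"M"`), `age_lo`, `age_hi`, `asr`.
#' @export
gen_incidence_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_stream(config, "incidence", {
    ab <- config$age_brackets
    mid <- (ab$lo + ab$hi) / 2
    premeno <- mid >= config$p1 & mid < config$p2
    amp <- rep_len(config$bias_amplitude, config$n_cancers)
    cancers <- sprintf("cancer_%02d", seq_len(config$n_cancers))
    # shared age profile: incidence rising with age, as for most carcinomas
    base_by_age <- config$baseline_asr * (0.2 + (mid / 50)^2)
    rows <- vector("list", config$n_cancers)
    for (i in seq_len(config$n_cancers)) {
      base <- base_by_age
      f <- base * ifelse(premeno, amp[i], 1)
      m <- base
      if (config$asr_noise_sd > 0) {
        f <- f * exp(rnorm(length(f), 0, config$asr_noise_sd))
        m <- m * exp(rnorm(length(m), 0, config$asr_noise_sd))
      }
      rows[[i]] <- data.frame(
        cancer = cancers[i],
        sex = rep(c("F", "M"), each = nrow(ab)),
        age_lo = rep(ab$lo, 2), age_hi = rep(ab$hi, 2),
        asr = c(f, m)
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("incidence_table", "data.frame")
    out
  })
}

#' Simulate a 2x2 (genotype x sex) expression cohort with planted effects
#'
#' Generates a gene-by-sample expression matrix plus a sample annotation
#' table. Genes comprise the built-in signature genes, the planted
#' (GRPR-like) gene and filler genes up to `n_genes`. Expression is
#' log-normal on the log2 scale (sd `expr_sd`); the planted gene gains
#' `planted_gene_log2fc` log2 units in `planted_group` only, and each
#' `signature_shifts` row adds its shift to one signature's genes in one
#' group. In `"tpm"` mode columns are rescaled to sum to 1e6; in
#' `"counts"` mode negative-binomial counts are drawn around the scaled
#' means with dispersion `count_dispersion`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expr` (an [expression_matrix()]) and
#'   `annotation` (data.frame: `sample`, `sex`, `genotype`, `group`).
#' @export
gen_expression_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_stream(config, "expression", {
    sig_genes <- unique(unlist(lapply(builtin_signatures(), `[[`, "genes")))
    core <- unique(c(sig_genes, config$planted_gene))
    if (config$n_genes < length(core)) {
      stop("n_genes too small to hold the signature and planted genes")
    }
    filler <- sprintf("GENE%04d", seq_len(config$n_genes - length(core)))
    genes <- c(core, filler)
    if (!config$planted_gene %in% genes) {
      stop("planted gene not in gene universe")
    }

    n_g <- config$n_samples_per_group
    samples <- unlist(lapply(config$groups, function(g) {
      sprintf("%s_s%02d", g, seq_len(n_g))
    }))
    group_of <- rep(config$groups, each = n_g)
    ann <- data.frame(
      sample = samples,
      sex = sub("^.*_(F|M)$", "\\1", group_of),
      genotype = sub("_(F|M)$", "", group_of),
      group = group_of
    )

    base <- rnorm(length(genes), mean = 5, sd = 1.5)
    names(base) <- genes
    base[config$planted_gene] <- config$planted_gene_base_log2

    log2mu <- matrix(base, nrow = length(genes), ncol = length(samples),
                     dimnames = list(genes, samples))
    planted_cols <- group_of == config$planted_group
    log2mu[config$planted_gene, planted_cols] <-
      log2mu[config$planted_gene, planted_cols] + config$planted_gene_log2fc
    if (!is.null(config$signature_shifts)) {
      sigs <- builtin_signatures()
      for (i in seq_len(nrow(config$signature_shifts))) {
        row <- config$signature_shifts[i, ]
        sig <- sigs[[as.character(row$signature)]]
        if (is.null(sig)) {
          stop("unknown signature in signature_shifts: ", row$signature)
        }
        g_in <- intersect(sig$genes, genes)
        cols <- group_of == row$group
        log2mu[g_in, cols] <- log2mu[g_in, cols] + row$shift
      }
    }

    log2v <- log2mu
    if (config$expr_sd > 0) {
      log2v <- log2v + matrix(rnorm(length(log2v), 0, config$expr_sd),
                              nrow = nrow(log2v))
    }
    lin <- 2^log2v
    if (config$expr_mode == "tpm") {
      vals <- sweep(lin, 2, colSums(lin), "/") * 1e6
      expr <- expression_matrix(vals, kind = "tpm")
    } else {
      mu <- sweep(lin, 2, colSums(lin), "/") * config$lib_size
      size <- 1 / config$count_dispersion
      vals <- matrix(rnbinom(length(mu), mu = mu, size = size),
                     nrow = nrow(mu), dimnames = dimnames(mu))
      expr <- expression_matrix(vals, kind = "counts")
    }
    list(expr = expr, annotation = ann)
  })
}

#' Simulate a two-stratum survival cohort with a planted hazard ratio
#'
#' Event times are exponential with rate `base_hazard` in the `low` stratum
#' and `base_hazard * hazard_ratio` in the `high` stratum; censoring is
#' uniform on `[0, censor_max]`, independent of the event time.
#'
#' @param config A [sim_config()].
#' @return A data.frame (class `survival_table`): `sample`, `time` (months),
#'   `event` (1 = event, 0 = censored), `stratum` (`"low"`/`"high"`).
#' @export
gen_survival_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_stream(config, "survival", {
    n <- config$n_per_stratum
    stratum <- rep(c("low", "high"), each = n)
    rate <- ifelse(stratum == "high",
                   config$base_hazard * config$hazard_ratio,
                   config$base_hazard)
    t_event <- rexp(2 * n, rate = rate)
    t_cens <- if (config$censor_max > 0) {
      runif(2 * n, 0, config$censor_max)
    } else {
      rep(Inf, 2 * n)
    }
    time <- pmin(t_event, t_cens)
    time <- pmax(time, .Machine$double.eps)
    out <- data.frame(
      sample = sprintf("s%04d", seq_len(2 * n)),
      time = time,
      event = as.integer(t_event <= t_cens),
      stratum = stratum
    )
    class(out) <- c("survival_table", "data.frame")
    out
  })
}

#' Simulate a mouse lung-metastasis cohort
#'
#' Each mouse develops metastasis with its group's Bernoulli probability;
#' metastatic mice receive a negative-binomial lesion count (>= 1) and
#' log-normal lesion diameters in mm, so the 0.1 mm micro/macro
#' classification boundary is exercised.
#'
#' @param config A [sim_config()].
#' @return A data.frame (class `metastasis_table`): `mouse`, `group`, `sex`,
#'   `metastasis` (0/1), `n_lesions`, `micro_count`, `macro_count`, and a
#'   list column `sizes` of lesion diameters (mm).
#' @export
gen_mouse_metastasis_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_stream(config, "metastasis", {
    n <- config$n_mice_per_group
    group <- rep(config$groups, each = n)
    p <- vapply(group, function(g) {
      if (!is.null(config$p_metastasis) && g %in% names(config$p_metastasis)) {
        config$p_metastasis[[g]]
      } else {
        config$p_metastasis_default
      }
    }, numeric(1))
    met <- rbinom(length(group), 1, p)
    size_nb <- 1 / config$count_dispersion
    mu <- max(config$metastasis_mean_count - 1, 0)
    counts <- ifelse(met == 1,
                     1 + rnbinom(length(group), mu = mu, size = size_nb),
                     0L)
    sizes <- lapply(counts, function(k) {
      if (k == 0) numeric(0) else {
        rlnorm(k, config$lesion_meanlog, config$lesion_sdlog)
      }
    })
    cls <- lapply(sizes, classify_lesions)
    out <- data.frame(
      mouse = sprintf("m%04d", seq_along(group)),
      group = group,
      sex = sub("^.*_(F|M)$", "\\1", group),
      metastasis = met,
      n_lesions = as.integer(counts),
      micro_count = vapply(cls, `[[`, integer(1), "micro"),
      macro_count = vapply(cls, `[[`, integer(1), "macro")
    )
    out$sizes <- sizes
    class(out) <- c("metastasis_table", "data.frame")
    out
  })
}

#' Write simulated tables as TSV
#'
#' Plain tab-separated serialization for the simulated tables. The
#' metastasis table's lesion-size list column is flattened to a
#' comma-separated `sizes_mm` string.
#'
#' @param x A data.frame from one of the generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(x, path) {
  if (!is.null(x$sizes)) {
    x$sizes_mm <- vapply(x$sizes, function(s) {
      paste(formatC(s, format = "g"), collapse = ",")
    }, character(1))
    x$sizes <- NULL
  }
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
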