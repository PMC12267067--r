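#' Weighted running-sum enrichment score
#'
#' Classic GSEA statistic: genes are ordered by a ranking metric; walking
#' down the list, hits (set members) increment the running sum
#' proportionally to `|metric|^weight` (normalized to 1 in total) and
#' misses decrement it by `1 / (N - n_hits)`. The enrichment score is the
#' signed extremum of the running sum, always in `[-1, 1]`.
#'
#' A set covering the whole ranked list admits no misses; the score is
#' then the degenerate value 1 and is flagged.
#'
#' @param ranking Named numeric vector (gene-level metric); no duplicate
#'   names. Internally sorted in decreasing order.
#' @param set_genes Character vector of set members.
#' @param weight Exponent on `|metric|` for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov walk).
#' @return List: `es`, `n_hits`, `degenerate`.
#' @export
gsea_es <- function(ranking, set_genes, weight = 1) {
  if (anyDuplicated(names(ranking))) stop("duplicate genes in ranking")
  ord <- order(ranking, decreasing = TRUE)
  stat <- ranking[ord]
  pos <- sort(match(intersect(set_genes, names(stat)), names(stat)))
  if (length(pos) == 0) stop("empty overlap between gene set and ranking")
  N <- length(stat)
  k <- length(pos)
  if (k == N) {
    return(list(es = 1, n_hits = k, degenerate = TRUE))
  }
  list(es = es_from_positions(abs(stat)^weight, pos, N),
       n_hits = k, degenerate = FALSE)
}

# Core O(k log k) extremum of the running sum given sorted hit positions.
# absw: |metric|^weight over the full ranked list (decreasing metric order).
es_from_positions <- function(absw, pos, N) {
  k <- length(pos)
  w <- absw[pos]
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / k else w <- w / nr
  cumhit <- cumsum(w)
  step <- 1 / (N - k)
  i <- seq_len(k)
  after <- cumhit - (pos - i) * step          # running sum just after hit i
  before <- c(0, cumhit[-k]) - (pos - i) * step  # just before hit i
  maxp <- max(after)
  minn <- min(c(before, 0))
  if (maxp >= -minn - 1e-12) maxp else minn  # magnitude tie -> positive
}

rank_metric <- function(v, ia, ib, metric) {
  a <- v[, ia, drop = FALSE]
  b <- v[, ib, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  if (metric == "log2fc") {
    ma - mb
  } else {
    sda <- apply(a, 1, sd)
    sdb <- apply(b, 1, sd)
    # classic signal-to-noise with the usual sd floor
    sda <- pmax(sda, 0.2 * abs(ma), 0.2)
    sdb <- pmax(sdb, 0.2 * abs(mb), 0.2)
    (ma - mb) / (sda + sdb)
  }
}

#' Permutation GSEA over a gene-set collection
#'
#' Computes the weighted running-sum enrichment score per gene set and
#' calibrates it against a seeded permutation null (default 1,000
#' permutations per set). Two standard null models are exposed:
#' `"gene"` permutes gene tags (random sets of matched size on the fixed
#' ranking); `"phenotype"` permutes sample labels between two groups and
#' recomputes the ranking metric for every permutation (requires `expr`,
#' `annotation`, `group_a`, `group_b`).
#'
#' NES is the ES divided by the mean of same-sign null ES values; the
#' permutation p-value is the same-sign tail frequency with add-one
#' continuity; FDR is the standard collection-level ratio of pooled
#' normalized null NES exceedances to observed NES exceedances. A result
#' passes the default reporting filter when NES > 1.7 and FDR < 0.05.
#'
#' @param ranking Named numeric gene-level metric (required for
#'   `method = "gene"`; derived from the data for `"phenotype"`).
#' @param gene_sets Named list of character vectors (or
#'   [gene_signature()]s).
#' @param n_perm Permutations per gene set (default 1000; < 100 warns).
#' @param weight Hit-increment exponent (default 1).
#' @param seed Integer seed for the permutation stream.
#' @param method `"gene"` or `"phenotype"` null model.
#' @param expr,annotation,group_a,group_b Two-group design for the
#'   phenotype null; `expr` must be kind `"tpm"` or `"log2tpm"`.
#' @param metric Ranking metric for the phenotype null: `"log2fc"`
#'   (difference of log2(TPM+1) group means) or `"s2n"` (signal-to-noise).
#' @param nes_min,fdr_max Reporting filter thresholds (strict
#'   inequalities).
#' @return data.frame of class `gsea_result`: `gene_set`, `size`, `es`,
#'   `nes`, `p_perm`, `fdr`, `n_perm`, `degenerate`, `passes_filter`.
#' @export
gsea <- function(ranking = NULL, gene_sets, n_perm = 1000, weight = 1,
                 seed = 1, method = c("gene", "phenotype"),
                 expr = NULL, annotation = NULL,
                 group_a = NULL, group_b = NULL,
                 metric = c("log2fc", "s2n"),
                 nes_min = 1.7, fdr_max = 0.05) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  if (inherits(gene_sets, "gene_signature")) gene_sets <- list(gene_sets)
  gene_sets <- lapply(gene_sets, function(s) {
    if (inherits(s, "gene_signature")) s$genes else as.character(s)
  })
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- paste0("set_", seq_along(gene_sets))
  }
  if (n_perm < 100) warning("n_perm < 100: permutation p/FDR are coarse")

  if (method == "phenotype") {
    stopifnot(inherits(expr, "expr_matrix"))
    v <- expr_values(log2_tpm(expr))
    ia <- which(colnames(v) %in%
                  annotation$sample[annotation$group == group_a])
    ib <- which(colnames(v) %in%
                  annotation$sample[annotation$group == group_b])
    if (length(ia) < 2 || length(ib) < 2) {
      stop("need at least 2 samples per group for phenotype permutation")
    }
    ranking <- setNames(rank_metric(v, ia, ib, metric), rownames(v))
  }
  if (is.null(ranking)) stop("a ranking is required for method = 'gene'")
  if (anyDuplicated(names(ranking))) stop("duplicate genes in ranking")

  ord <- order(ranking, decreasing = TRUE)
  stat <- ranking[ord]
  N <- length(stat)
  absw <- abs(stat)^weight

  obs <- lapply(gene_sets, function(gs) gsea_es(ranking, gs, weight))
  sizes <- vapply(gene_sets, function(gs) {
    length(intersect(gs, names(ranking)))
  }, integer(1))
  if (any(sizes == 0)) {
    stop("empty overlap for set(s): ",
         paste(names(gene_sets)[sizes == 0], collapse = ", "))
  }

  set.seed(as.integer(seed %% 2147483647))
  null_es <- vector("list", length(gene_sets))
  if (method == "gene") {
    for (s in seq_along(gene_sets)) {
      k <- sizes[s]
      if (k == N) { null_es[[s]] <- rep(NA_real_, n_perm); next }
      null_es[[s]] <- vapply(seq_len(n_perm), function(j) {
        es_from_positions(absw, sort(sample.int(N, k)), N)
      }, numeric(1))
    }
  } else {
    pool <- c(ia, ib)
    na <- length(ia)
    null_mat <- matrix(NA_real_, n_perm, length(gene_sets))
    for (j in seq_len(n_perm)) {
      sh <- sample(pool)
      rk <- rank_metric(v, sh[seq_len(na)], sh[-seq_len(na)], metric)
      ordj <- order(rk, decreasing = TRUE)
      abswj <- abs(rk[ordj])^weight
      nmj <- rownames(v)[ordj]
      for (s in seq_along(gene_sets)) {
        if (sizes[s] == N) next
        posj <- sort(match(intersect(gene_sets[[s]], nmj), nmj))
        null_mat[j, s] <- es_from_positions(abswj, posj, N)
      }
    }
    null_es <- lapply(seq_along(gene_sets), function(s) null_mat[, s])
  }

  es <- vapply(obs, `[[`, numeric(1), "es")
  degen <- vapply(obs, `[[`, logical(1), "degenerate")
  nes <- p_perm <- rep(NA_real_, length(es))
  null_nes <- vector("list", length(es))
  for (s in seq_along(es)) {
    if (degen[s]) { null_nes[[s]] <- numeric(0); next }
    nl <- null_es[[s]]
    mp <- mean(nl[nl >= 0])
    mn <- mean(abs(nl[nl < 0]))
    norm <- ifelse(nl >= 0,
                   if (is.finite(mp) && mp > 0) nl / mp else NA_real_,
                   if (is.finite(mn) && mn > 0) nl / mn else NA_real_)
    null_nes[[s]] <- norm[is.finite(norm)]
    if (es[s] >= 0) {
      nes[s] <- if (is.finite(mp) && mp > 0) es[s] / mp else NA_real_
      same <- nl[nl >= 0]
      p_perm[s] <- (1 + sum(same >= es[s])) / (1 + length(same))
    } else {
      nes[s] <- if (is.finite(mn) && mn > 0) es[s] / mn else NA_real_
      same <- nl[nl < 0]
      p_perm[s] <- (1 + sum(same <= es[s])) / (1 + length(same))
    }
  }

  pooled <- unlist(null_nes)
  fdr <- rep(NA_real_, length(es))
  for (s in seq_along(es)) {
    if (degen[s] || !is.finite(nes[s])) next
    if (nes[s] >= 0) {
      num <- mean(pooled >= nes[s])
      den <- mean(nes[is.finite(nes)] >= nes[s])
    } else {
      num <- mean(pooled <= nes[s])
      den <- mean(nes[is.finite(nes)] <= nes[s])
    }
    fdr[s] <- min(1, num / max(den, .Machine$double.eps))
  }

  out <- data.frame(
    gene_set = names(gene_sets), size = sizes, es = es, nes = nes,
    p_perm = p_perm, fdr = fdr, n_perm = as.integer(n_perm),
    degenerate = degen,
    passes_filter = !degen & is.finite(nes) & is.finite(fdr) &
      nes > nes_min & fdr < fdr_max,
    row.names = NULL
  )
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Filter enrichment results on NES and FDR
#'
#' Keeps gene sets with `nes > nes_min` and `fdr < fdr_max` (strict
#' inequalities; the conventional reporting thresholds are NES above 1.7
#' at FDR below 0.05).
#'
#' @param results A [gsea()] result.
#' @param nes_min,fdr_max Thresholds.
#' @return The filtered rows.
#' @export
gsea_filter <- function(results, nes_min = 1.7, fdr_max = 0.05) {
  stopifnot(is.data.frame(results))
  keep <- !is.na(results$nes) & !is.na(results$fdr) &
    results$nes > nes_min & results$fdr < fdr_max
  results[keep, , drop = FALSE]
}
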