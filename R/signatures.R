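#' Construct a gene signature
#'
#' @param name Signature label.
#' @param genes Character vector of gene symbols (non-empty; duplicates
#'   removed, order preserved).
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("signature must contain at least one gene")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Built-in melanoma signature registry
#'
#' The marker-gene lists used throughout the pipeline (human symbols):
#' the four melanoma cell-state signatures — `pigmentation`, `SMC`
#' (starved-like melanoma cells), `invasive` and `NCSC` (neural crest
#' cell-like) — plus `yap1_activation`, `anoikis_resistance` and
#' `er_activation`.
#'
#' @return Named list of [gene_signature()] objects.
#' @export
builtin_signatures <- function() {
  defs <- list(
    pigmentation = c("MITF", "MLANA", "TRPM1", "DCT", "TYR"),
    SMC = c("CD36", "DLX5", "IP6K3", "PAX3", "TRIM67"),
    invasive = c("AXL", "CYR61", "TCF4", "LOXL2", "TNC", "WNT5A"),
    NCSC = c("AQP1", "GFRA2", "L1CAM", "NGFR", "SLC22A17", "TMEM176B"),
    yap1_activation = c("CYR61", "CTGF", "TEAD4", "LATS2", "CRIM1"),
    anoikis_resistance = c("S100A7A", "MTPN", "ATP10B", "S100A8", "RSAD2",
                           "RENBP", "CDHR1", "CD36"),
    er_activation = c("GATA4", "SDK2", "EGR3", "IL19", "GSG1L", "RSPO1",
                      "PGR", "IL24", "PDZK1")
  )
  out <- lapply(names(defs), function(n) gene_signature(n, defs[[n]]))
  names(out) <- names(defs)
  out
}

#' The four melanoma cell-state signature names, in tie-break order
#' @return Character vector.
#' @export
melanoma_state_signatures <- function() {
  c("pigmentation", "SMC", "invasive", "NCSC")
}

#' Map a human signature to murine orthologue symbols
#'
#' Uses a two-column alias table (columns `human`, `mouse`); symbols
#' without an entry fall back to the conventional case transformation
#' (first letter upper, rest lower). The packaged table
#' `mouse_human_orthologues.tsv` covers the built-in signatures.
#'
#' @param sig A [gene_signature()].
#' @param alias_table data.frame with columns `human` and `mouse`, or
#'   `NULL` to use the packaged table.
#' @return A `gene_signature` with mouse symbols.
#' @export
map_to_mouse <- function(sig, alias_table = NULL) {
  stopifnot(inherits(sig, "gene_signature"))
  if (is.null(alias_table)) {
    path <- system.file("extdata", "mouse_human_orthologues.tsv",
                        package = "oncosex")
    alias_table <- read.delim(path, stringsAsFactors = FALSE)
  }
  idx <- match(toupper(sig$genes), toupper(alias_table$human))
  mouse <- alias_table$mouse[idx]
  fallback <- is.na(mouse)
  mouse[fallback] <- paste0(
    toupper(substr(sig$genes[fallback], 1, 1)),
    tolower(substr(sig$genes[fallback], 2, nchar(sig$genes[fallback])))
  )
  gene_signature(sig$name, mouse)
}

#' Read and write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated — name, description, then genes.
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors or of [gene_signature()]s.
#' @param description Description field written for every set.
#' @return `read_gmt()` returns a named list of character vectors;
#'   `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(out) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(n) {
    genes <- sets[[n]]
    if (inherits(genes, "gene_signature")) genes <- genes$genes
    paste(c(n, description, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample signature score
#'
#' Scores each sample as the mean expression (log2 scale) of the signature
#' genes present in the matrix. With `standardize = TRUE` every gene is
#' z-scored across samples first, which puts signatures of different sizes
#' and expression levels on a comparable scale (required for predominant-
#' state calls). Missing signature genes are reported via a message, never
#' imputed; constant genes contribute z = 0 under standardization.
#'
#' @param expr An `expr_matrix` of kind `"log2tpm"` (use [log2_tpm()]).
#' @param sig A [gene_signature()].
#' @param standardize Z-score genes across samples before averaging.
#' @return Named numeric per-sample score vector.
#' @export
score_signature <- function(expr, sig, standardize = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sig, "gene_signature"))
  if (expr_kind(expr) != "log2tpm") {
    stop("score_signature expects log2-scale expression (kind 'log2tpm')")
  }
  v <- expr_values(expr)
  present <- intersect(sig$genes, rownames(v))
  if (length(present) == 0) {
    stop("no signature gene present in the matrix; requested: ",
         paste(sig$genes, collapse = ", "))
  }
  absent <- setdiff(sig$genes, present)
  if (length(absent) > 0) {
    message("signature ", sig$name, ": ", length(absent),
            " gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  }
  m <- v[present, , drop = FALSE]
  if (standardize) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- Inf  # constant gene -> z = 0
    m <- (m - mu) / s
  }
  colMeans(m)
}

#' Score a collection of signatures
#'
#' @param expr An `expr_matrix` of kind `"log2tpm"`.
#' @param sigs Named list of [gene_signature()]s (default: built-ins).
#' @param standardize Passed to [score_signature()].
#' @return A samples-by-signatures numeric matrix (class `score_matrix`)
#'   with attribute `"standardized"`.
#' @export
score_signatures <- function(expr, sigs = builtin_signatures(),
                             standardize = FALSE) {
  scores <- vapply(sigs, function(s) score_signature(expr, s, standardize),
                   numeric(ncol(expr)))
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1,
                     dimnames = list(colnames(expr), names(sigs)))
  }
  structure(scores, standardized = standardize,
            class = c("score_matrix", "matrix", "array"))
}

#' YAP activation score by mean target fold change
#'
#' Mean over the YAP1 target genes of the ratio of mean case TPM to mean
#' reference TPM, with an epsilon pseudo-rate guarding zero denominators.
#'
#' @param expr_case,expr_ref `expr_matrix` objects of kind `"tpm"` for the
#'   case and reference conditions.
#' @param targets A [gene_signature()] (default: built-in
#'   `yap1_activation`).
#' @param eps Pseudo-TPM added to both means (default 0.01).
#' @param log Return the mean of log2 fold changes instead of raw ratios.
#' @return Single numeric score.
#' @export
yap_fold_change_score <- function(expr_case, expr_ref,
                                  targets = builtin_signatures()$yap1_activation,
                                  eps = 0.01, log = FALSE) {
  stopifnot(inherits(expr_case, "expr_matrix"),
            inherits(expr_ref, "expr_matrix"))
  if (expr_kind(expr_case) != "tpm" || expr_kind(expr_ref) != "tpm") {
    stop("fold-change scoring expects TPM matrices")
  }
  vc <- expr_values(expr_case)
  vr <- expr_values(expr_ref)
  present <- intersect(targets$genes, intersect(rownames(vc), rownames(vr)))
  if (length(present) == 0) stop("no target gene present in both conditions")
  fc <- (rowMeans(vc[present, , drop = FALSE]) + eps) /
    (rowMeans(vr[present, , drop = FALSE]) + eps)
  if (log) mean(log2(fc)) else mean(fc)
}

#' Predominant melanoma-state assignment
#'
#' Assigns each sample the cell-state signature with the highest
#' standardized score among the four melanoma states. Exact ties are
#' broken by the fixed order pigmentation < SMC < invasive < NCSC and
#' flagged.
#'
#' @param scores A [score_signatures()] result computed with
#'   `standardize = TRUE`, containing all four state signatures.
#' @return data.frame: `sample`, `state`, `tie` (logical).
#' @export
assign_predominant_state <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  states <- melanoma_state_signatures()
  missing <- setdiff(states, colnames(scores))
  if (length(missing) > 0) {
    stop("state signature(s) not scored: ", paste(missing, collapse = ", "))
  }
  if (!isTRUE(attr(scores, "standardized"))) {
    stop("predominant-state calls require standardized scores ",
         "(score_signatures(..., standardize = TRUE))")
  }
  m <- scores[, states, drop = FALSE]
  idx <- apply(m, 1, which.max)
  tie <- apply(m, 1, function(r) sum(r == max(r)) > 1)
  data.frame(sample = rownames(m), state = states[idx], tie = tie,
             row.names = NULL)
}
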