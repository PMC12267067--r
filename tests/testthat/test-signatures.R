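test_that("the built-in registry carries the expected marker lists", {
  sigs <- builtin_signatures()
  expect_setequal(names(sigs),
                  c("pigmentation", "SMC", "invasive", "NCSC",
                    "yap1_activation", "anoikis_resistance",
                    "er_activation"))
  expect_equal(sigs$pigmentation$genes,
               c("MITF", "MLANA", "TRPM1", "DCT", "TYR"))
  expect_equal(sigs$invasive$genes,
               c("AXL", "CYR61", "TCF4", "LOXL2", "TNC", "WNT5A"))
  expect_equal(length(sigs$er_activation$genes), 9)
  # the shipped GMT mirrors the registry
  gmt <- read_gmt(system.file("extdata", "melanoma_signatures.gmt",
                              package = "oncosex"))
  for (n in names(sigs)) expect_setequal(gmt[[n]], sigs[[n]]$genes)
})

test_that("GMT write/read round trips a collection", {
  sets <- list(one = c("A", "B", "C"), two = c("D", "E"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})

test_that("mouse orthologue mapping uses the alias table", {
  sig <- map_to_mouse(builtin_signatures()$pigmentation)
  expect_equal(sig$genes, c("Mitf", "Mlana", "Trpm1", "Dct", "Tyr"))
  custom <- map_to_mouse(gene_signature("x", c("MITF", "NOVEL1")),
                         data.frame(human = "MITF", mouse = "Mitf"))
  expect_equal(custom$genes, c("Mitf", "Novel1"))
})

test_that("signature scoring reduces to the right means", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                2, 4, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("MITF", "MLANA", "other"),
                              c("s1", "s2", "s3")))
  expr <- expression_matrix(m, "log2tpm")
  single <- suppressMessages(
    score_signature(expr, gene_signature("one", "MITF")))
  expect_equal(unname(single), c(1, 2, 3))
  # all present genes equal v in a sample -> score v
  pair <- suppressMessages(
    score_signature(expr, gene_signature("pair", c("MITF", "MLANA"))))
  expect_equal(unname(pair), c(3, 3.5, 4))
  expect_error(score_signature(expr, gene_signature("none", "ZZZ")),
               "ZZZ")
  expect_error(score_signature(expression_matrix(m, "counts"),
                               gene_signature("one", "MITF")),
               "log2")
})

test_that("scores are invariant to gene and sample order", {
  set.seed(9)
  genes <- c(builtin_signatures()$invasive$genes, paste0("f", 1:20))
  m <- matrix(abs(rnorm(length(genes) * 6, 5)), length(genes), 6,
              dimnames = list(genes, paste0("s", 1:6)))
  expr <- expression_matrix(m, "log2tpm")
  shuf <- expression_matrix(m[sample(nrow(m)), sample(ncol(m))], "log2tpm")
  s1 <- score_signature(expr, builtin_signatures()$invasive)
  s2 <- score_signature(shuf, builtin_signatures()$invasive)
  expect_equal(s1[sort(names(s1))], s2[sort(names(s2))], tolerance = 1e-12)
})

test_that("YAP fold-change scoring averages per-target ratios", {
  genes <- c(builtin_signatures()$yap1_activation$genes, "x")
  base <- matrix(50, length(genes), 4, dimnames = list(genes,
                                                       paste0("s", 1:4)))
  ref <- toy_expr(base, genes = genes)
  expect_equal(yap_fold_change_score(ref, ref), 1, tolerance = 1e-12)

  # doubling every target, compensated by the filler gene so both
  # matrices stay valid TPM with identical totals
  vr <- base; vr["x", ] <- 1e6 - 5 * 50
  vc0 <- base; vc0[1:5, ] <- 100; vc0["x", ] <- 1e6 - 5 * 100
  case <- expression_matrix(vc0, "tpm")
  refm <- expression_matrix(vr, "tpm")
  expect_equal(yap_fold_change_score(case, refm), 2, tolerance = 1e-3)

  set.seed(10)
  rc <- matrix(runif(length(genes) * 3, 1, 100), length(genes), 3,
               dimnames = list(genes, paste0("c", 1:3)))
  rr <- matrix(runif(length(genes) * 5, 1, 100), length(genes), 5,
               dimnames = list(genes, paste0("r", 1:5)))
  ec <- toy_expr(rc, genes = genes)
  er <- toy_expr(rr, genes = genes)
  targets <- builtin_signatures()$yap1_activation$genes
  vc <- unclass(ec); vrm <- unclass(er)
  oracle <- mean(vapply(targets, function(g) {
    (mean(vc[g, ]) + 0.01) / (mean(vrm[g, ]) + 0.01)
  }, numeric(1)))
  expect_equal(yap_fold_change_score(ec, er), oracle, tolerance = 1e-12)
})

test_that("predominant-state calls need standardized scores of all four
           states", {
  cfg <- sim_config(seed = 15, n_genes = 300, n_samples_per_group = 4)
  co <- gen_expression_cohort(cfg)
  lx <- log2_tpm(co$expr)
  raw <- score_signatures(lx, standardize = FALSE)
  expect_error(assign_predominant_state(raw), "standardized")
  partial <- score_signatures(lx, builtin_signatures()["pigmentation"],
                              standardize = TRUE)
  expect_error(assign_predominant_state(partial), "not scored")
})

test_that("state assignment picks the maximal z-score with ordered
           tie-breaks", {
  sc <- matrix(c(2, 0, -1, 0,
                 1, 1, 0, -1), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), melanoma_state_signatures()))
  sm <- structure(sc, standardized = TRUE,
                  class = c("score_matrix", "matrix", "array"))
  st <- assign_predominant_state(sm)
  expect_equal(st$state, c("pigmentation", "pigmentation"))
  expect_equal(st$tie, c(FALSE, TRUE))
})

test_that("state assignment is invariant to per-gene affine rescaling", {
  cfg <- sim_config(
    seed = 16, n_genes = 300, n_samples_per_group = 6,
    groups = paste0(melanoma_state_signatures(), "_F"),
    planted_group = "pigmentation_F",
    signature_shifts = data.frame(
      signature = melanoma_state_signatures(),
      group = paste0(melanoma_state_signatures(), "_F"),
      shift = 2))
  co <- gen_expression_cohort(cfg)
  v <- log2(unclass(co$expr) + 1)
  st1 <- assign_predominant_state(
    score_signatures(expression_matrix(v, "log2tpm"), standardize = TRUE))
  set.seed(1)
  v2 <- v * runif(nrow(v), 0.5, 3) + rnorm(nrow(v))
  st2 <- assign_predominant_state(
    score_signatures(expression_matrix(v2, "log2tpm"), standardize = TRUE))
  expect_equal(st1$state, st2$state)
})

test_that("archetype cohorts are recovered almost perfectly", {
  states <- melanoma_state_signatures()
  cfg <- sim_config(
    seed = 17, n_genes = 400, n_samples_per_group = 12,
    groups = paste0(states, "_F"), planted_group = "pigmentation_F",
    signature_shifts = data.frame(signature = states,
                                  group = paste0(states, "_F"),
                                  shift = 2),
    expr_sd = 0.5)
  co <- gen_expression_cohort(cfg)
  st <- assign_predominant_state(
    score_signatures(log2_tpm(co$expr), standardize = TRUE))
  truth <- sub("_F.*$", "", co$annotation$group)
  expect_gte(mean(st$state == truth), 0.95)
})

test_that("planted signature shifts move the unstandardized score", {
  cfg <- sim_config(
    seed = 18, n_genes = 500, n_samples_per_group = 25,
    signature_shifts = data.frame(signature = "invasive",
                                  group = "dEcad_F", shift = 2))
  co <- gen_expression_cohort(cfg)
  sc <- score_signature(log2_tpm(co$expr), builtin_signatures()$invasive)
  in_grp <- co$annotation$group == "dEcad_F"
  expect_equal(mean(sc[in_grp]) - mean(sc[!in_grp]), 2, tolerance = 0.25)
})
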