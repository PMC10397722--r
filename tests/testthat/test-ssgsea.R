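rand_expr <- function(genes, samples, seed = 1) {
  set.seed(seed)
  matrix(rexp(genes * samples, 1 / 50), genes, samples,
         dimnames = list(sprintf("g%03d", seq_len(genes)),
                         sprintf("s%02d", seq_len(samples))))
}

test_that("top-ranked sets score positive, bottom-ranked negative", {
  v <- matrix(20:1, 20, 1, dimnames = list(sprintf("g%03d", 1:20), "s1"))
  top <- list(TOP = c("g001", "g002"))
  bottom <- list(BOT = c("g019", "g020"))
  s_top <- ssgsea_score(v, top)[1, 1]
  s_bot <- ssgsea_score(v, bottom)[1, 1]
  expect_gt(s_top, 0)
  expect_lt(s_bot, 0)
})

test_that("scores are invariant to strictly monotone transforms", {
  for (seed in 1:5) {
    v <- rand_expr(40, 3, seed)
    sets <- list(S1 = rownames(v)[c(3, 9, 17, 30)],
                 S2 = rownames(v)[c(1, 2, 35:40)])
    base <- ssgsea_score(v, sets)
    expect_equal(ssgsea_score(log10(v + 1), sets), base, tolerance = 1e-12)
    expect_equal(ssgsea_score(v^3, sets), base, tolerance = 1e-12)
    # and therefore tpm vs log10_tpm inputs give identical scores
    tpmv <- sweep(v, 2, colSums(v), "/") * 1e6
    x <- expr_matrix(tpmv, "tpm", "human", check_tpm = FALSE)
    expect_equal(ssgsea_score(log10_transform(x), sets),
                 ssgsea_score(x, sets), tolerance = 1e-12)
  }
})

test_that("scores match the brute-force oracle, exhaustively at n = 6", {
  ids <- paste0("g", 1:6)
  sets <- list(A = c("g1", "g4"), B = c("g2", "g3", "g6"))
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) all(sort(r) == 1:6)), ]
  for (alpha in c(0.25, 0)) {
    cfgA <- ssgsea_config(alpha = alpha)
    for (i in seq_len(nrow(perms))) {
      v <- matrix(as.numeric(perms[i, ]), 6, 1,
                  dimnames = list(ids, "s1"))
      got <- ssgsea_score(v, sets, cfgA)
      expect_equal(got[1, "A"], oracle_ssgsea(v[, 1], ids, sets$A, alpha),
                   tolerance = 1e-12)
      expect_equal(got[1, "B"], oracle_ssgsea(v[, 1], ids, sets$B, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("scores match the oracle on tied instances up to 8 genes", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    ids <- paste0("g", seq_len(n))
    v <- matrix(sample(1:4, n, replace = TRUE) * 10, n, 1,  # heavy ties
                dimnames = list(ids, "s1"))
    set_ids <- sample(ids, sample(2:(n - 1), 1))
    got <- ssgsea_score(v, list(S = set_ids))[1, 1]
    expect_equal(got, oracle_ssgsea(v[, 1], ids, set_ids, 0.25),
                 tolerance = 1e-12)
  }
})

test_that("degenerate sets are skipped or rejected", {
  v <- rand_expr(10, 2)
  expect_warning(s <- ssgsea_score(v, list(ok = rownames(v)[1:3],
                                           tiny = c("g001", "nope"))),
                 "tiny")
  expect_identical(colnames(s), "ok")
  expect_error(ssgsea_score(v, list(all = rownames(v))), "covers all genes")
  expect_error(suppressWarnings(ssgsea_score(v, list(tiny = "g001"))),
               "no scorable")
})

test_that("permutation significance is calibrated, positive and seeded", {
  v <- rand_expr(120, 10, seed = 5)          # pure noise: the global null
  sets <- lapply(1:8, function(i) {
    set.seed(100 + i); sample(rownames(v), 8)
  })
  names(sets) <- paste0("N", 1:8)
  cfg <- ssgsea_config(n_permutations = 200, seed = 3)
  res <- ssgsea_significance(v, sets, cfg)
  expect_true(all(res$p_value > 0))
  expect_true(all(res$fdr >= res$p_value))
  frac <- mean(res$p_value < 0.05)
  m <- length(res$p_value)
  band <- 2.576 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(frac - 0.05), band + 2 / m)

  res2 <- ssgsea_significance(v, sets, cfg)
  expect_identical(res$fdr, res2$fdr)
  expect_error(ssgsea_significance(v, sets,
                                   ssgsea_config(n_permutations = 50)),
               ">= 100")
})

test_that("the enriched-set selection rule counts samples, not averages", {
  res <- structure(list(fdr = matrix(
    c(rep(0.01, 6), rep(0.5, 3),    # set1: significant in 6 of 9
      rep(0.01, 5), rep(0.5, 4)),   # set2: significant in 5 of 9
    nrow = 9, ncol = 2,
    dimnames = list(paste0("s", 1:9), c("set1", "set2")))),
    class = "ssgsea_result")
  sel <- select_enriched(res, fdr_threshold = 0.05, sample_fraction = 2 / 3,
                         group = paste0("s", 1:9))
  expect_identical(sel, "set1")         # 6 >= ceil(6), 5 < 6
  expect_error(select_enriched(res, group = character(0)), "empty")
})

test_that("class-signature sets are called in their class and not elsewhere", {
  cfg <- small_sim_config(
    samples_per_class = list(A = c(BLCA = 9, LGG = 3, HGG = 9, normal = 9),
                             B = c(BLCA = 3, LGG = 3, HGG = 3, normal = 3)),
    signature_log2fc = 2.0, seed = 41)
  orth <- generate_ortholog_table(cfg)
  coh <- generate_cohort(cfg, "A")
  tpm <- counts_to_tpm(coh$counts, orth$annotation$A)
  # directional (up-regulated) halves of the class signatures: a mixed
  # up/down set has near-zero integrated enrichment by construction
  up <- function(cl) names(which(coh$ground_truth$signature_lfc$A[[cl]] > 0))
  sets <- list(BLCA_sig = up("BLCA"), HGG_sig = up("HGG"))
  res <- ssgsea_significance(tpm, sets,
                             ssgsea_config(n_permutations = 200, seed = 41))
  blca <- names(coh$labels)[coh$labels == "BLCA"]
  norm <- names(coh$labels)[coh$labels == "normal"]
  expect_true("BLCA_sig" %in% select_enriched(res, group = blca))
  expect_false("BLCA_sig" %in% select_enriched(res, group = norm))
})

test_that("group subsampling is balanced, seeded and guarded", {
  labs <- setNames(rep(c("x", "y"), times = c(30, 9)),
                   paste0("s", 1:39))
  keep <- subsample_groups(labs, 9, seed = 2)
  expect_length(keep, 18)
  expect_equal(unname(table(labs[keep])), c(9L, 9L), ignore_attr = TRUE)
  expect_identical(keep, subsample_groups(labs, 9, seed = 2))
  expect_error(subsample_groups(labs, 10), "'y' has 9")
})
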