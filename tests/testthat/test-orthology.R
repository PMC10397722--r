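write_ortholog_tsv <- function(df) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

ortholog_df <- function(h, c, type = "ortholog_one2one",
                        biotype = "protein_coding") {
  data.frame(human_gene_id = h, human_gene_name = paste0(h, "n"),
             canine_gene_id = c, canine_gene_name = paste0(c, "n"),
             homology_type = rep_len(type, length(h)),
             pct_identity_h2c = 90, pct_identity_c2h = 88,
             gene_order_conservation_score = 100,
             human_biotype = rep_len(biotype, length(h)),
             stringsAsFactors = FALSE)
}

test_that("ortholog export parsing strips versions and checks columns", {
  df <- ortholog_df(c("ENSG00000141510.17", "ENSG00000000003.1",
                      "ENSG00000000005"),
                    c("ENSCAFG001.2", "ENSCAFG002", "ENSCAFG003"),
                    type = c("ortholog_one2one", "ortholog_one2one",
                             "ortholog_one2many"))
  tab <- read_ortholog_table(write_ortholog_tsv(df))
  expect_s3_class(tab, "ortholog_table")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$human_gene_id[1], "ENSG00000141510")
  expect_identical(tab$canine_gene_id[1], "ENSCAFG001")

  expect_error(read_ortholog_table(
    write_ortholog_tsv(df[setdiff(names(df), "homology_type")])),
    "missing required column: homology_type")

  # empty data section is an empty table, not an error
  empty <- read_ortholog_table(write_ortholog_tsv(df[0, ]))
  expect_equal(nrow(empty), 0)

  # header names remappable for foreign exports
  df2 <- df
  names(df2)[names(df2) == "human_gene_id"] <- "Gene stable ID"
  tab2 <- read_ortholog_table(write_ortholog_tsv(df2),
                              col_map = c(human_gene_id = "Gene stable ID"))
  expect_identical(tab2$human_gene_id, tab$human_gene_id)
})

test_that("one-to-one filtering re-checks uniqueness", {
  # a human gene paired with two canine genes under one2one labels: both drop
  amb <- read_ortholog_table(write_ortholog_tsv(
    ortholog_df(c("h1", "h1", "h2"), c("c1", "c2", "c3"))))
  kept <- filter_one_to_one(amb)
  expect_identical(kept$human_gene_id, "h2")

  disjoint <- read_ortholog_table(write_ortholog_tsv(
    ortholog_df(c("h1", "h2", "h3"), c("c1", "c2", "c3"))))
  expect_equal(nrow(filter_one_to_one(disjoint)), 3)
  # idempotent
  expect_identical(filter_one_to_one(filter_one_to_one(amb)), kept)
})

test_that("protein-coding filter prefers the annotation over the table", {
  tab <- read_ortholog_table(write_ortholog_tsv(
    ortholog_df(paste0("h", 1:10), paste0("c", 1:10),
                biotype = c(rep("protein_coding", 7), rep("lncRNA", 3)))))
  expect_equal(nrow(filter_protein_coding(tab)), 7)

  ann <- data.frame(gene_id = paste0("h", 1:10),
                    biotype = c(rep("protein_coding", 4), rep("lncRNA", 6)))
  expect_equal(nrow(filter_protein_coding(tab, ann)), 4)

  # genes absent from the annotation drop with a warning, not an error
  expect_warning(out <- filter_protein_coding(tab, ann[1:5, ]), "absent")
  expect_equal(nrow(out), 4)

  # all non-coding: empty table, and the feature-space build then errors
  none <- filter_protein_coding(tab, transform(ann, biotype = "lncRNA"))
  expect_equal(nrow(none), 0)
  expect_error(build_feature_space(none), "empty")
})

test_that("feature space is lexicographic and bijective", {
  tab <- read_ortholog_table(write_ortholog_tsv(
    ortholog_df(c("hB", "hA"), c("cX", "cY"))))
  fs <- build_feature_space(tab)
  expect_identical(fs$human_ids, c("hA", "hB"))
  expect_identical(fs$canine_ids, c("cY", "cX"))
  expect_length(fs$human_ids, nrow(tab))
  # canine -> index -> canine round trip
  expect_identical(fs$canine_ids[match(fs$canine_ids, fs$canine_ids)],
                   fs$canine_ids)
  expect_match(fs$fingerprint, "^2:")
})

test_that("projection is strict, order-preserving and bit-exact", {
  cfg <- small_sim_config()
  orth <- generate_ortholog_table(cfg)
  fs <- build_feature_space(
    filter_protein_coding(filter_one_to_one(orth$table), orth$annotation$A))
  coh <- generate_cohort(cfg, "B")
  lg <- log10_transform(counts_to_tpm(coh$counts, orth$annotation$B))
  proj <- project_to_feature_space(lg, fs)
  expect_identical(gene_ids(proj), fs$human_ids)       # renamed to human ids
  expect_identical(sample_ids(proj), sample_ids(lg))   # sample order kept
  expect_identical(proj$values[5, ], lg$values[fs$canine_ids[5], ])

  # dropping one mapped gene makes projection fail, naming the gene
  miss <- expr_matrix(lg$values[-match(fs$canine_ids[3], gene_ids(lg)), ,
                                drop = FALSE],
                      unit = "log10_tpm", species = lg$species)
  expect_error(project_to_feature_space(miss, fs), fs$canine_ids[3])

  expect_error(project_to_feature_space(coh$counts, fs), "tpm")
})

test_that("simulator ground truth pins down the filter arithmetic", {
  for (seed in c(2, 31)) {
    cfg <- small_sim_config(seed = seed)
    orth <- generate_ortholog_table(cfg)
    one <- filter_one_to_one(orth$table)
    expect_equal(nrow(one), cfg$n_genes_one_to_one)
    pc <- filter_protein_coding(one, orth$annotation$A)
    expect_equal(nrow(pc),
                 round(cfg$n_genes_one_to_one * cfg$fraction_protein_coding))
    # the two filters commute on simulator tables and are jointly idempotent
    other <- filter_one_to_one(
      filter_protein_coding(orth$table, orth$annotation$A))
    expect_identical(sort(other$human_gene_id), sort(pc$human_gene_id))
    expect_identical(filter_protein_coding(pc, orth$annotation$A), pc)
  }
})
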