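#' Configuration for the two-species synthetic cohort generator
#'
#' The simulator emulates the structure of a paired human/canine tumor
#' RNA-seq resource: two species sharing class-specific expression
#' signatures on a configurable fraction of their one-to-one protein-coding
#' orthologs, a per-gene species batch shift, negative-binomial count noise,
#' an ortholog table mixing one-to-one / one-to-many / species-specific /
#' non-coding genes, and (optionally) a pair of "grade" classes separated
#' only by a small effect on a few genes — the regime in which grade-level
#' transfer is expected to fail.
#'
#' Defaults state the simulated world once: species A carries balanced
#' tumor cohorts plus a small normal class, species B mirrors a canine
#' resource (56 bladder tumors, 30 high-grade and 9 low-grade gliomas, a
#' handful of normals) so that species B covers only a subset of the
#' classes the species-A model knows.
#'
#' @param class_names class labels; `"normal"` (if present) is the
#'   signature-free baseline class used as the differential-expression
#'   reference.
#' @param samples_per_class named list with elements `A` and `B`, each a
#'   named integer vector over `class_names` (0 = class absent in that
#'   species).
#' @param n_genes_one_to_one,n_genes_one_to_many,n_genes_species_specific
#'   ortholog-table composition; `n_genes_species_specific` is a named
#'   vector `c(A=, B=)`.
#' @param fraction_protein_coding fraction of one-to-one pairs flagged
#'   protein-coding on the species-A side (the feature-space fraction).
#' @param n_signature_genes_per_class,signature_log2fc size and log2 effect
#'   of each tumor class's signature (signs alternate up/down per gene).
#' @param conserved_fraction fraction of signature genes whose effect is
#'   shared across species; the remainder act in species A only, with a
#'   disjoint species-B-private set taking their place in B.
#' @param species_batch_log2fc standard deviation of the per-gene additive
#'   log2 batch shift applied to species B.
#' @param nb_dispersion negative-binomial dispersion (1/size); must be > 0.
#' @param gene_length_range union-exon length range in bp.
#' @param grade_pair optional two class names sharing one signature except
#'   for `n_grade_genes` genes shifted by `grade_delta_log2fc` in the first
#'   of the pair.
#' @param grade_delta_log2fc,n_grade_genes the grade-level perturbation.
#' @param xor_pair optional two class names distinguished only by an
#'   XOR-style interaction between two contiguous `n_xor_genes`-gene blocks
#'   at `xor_log2fc`; class means coincide, so no linear readout separates
#'   them while a nonlinear model can.
#' @param n_xor_genes,xor_log2fc the XOR block size and effect.
#' @param library_size_mean,library_size_log_sd per-sample sequencing depth
#'   drawn log-normal; the spread forces depth normalisation to matter.
#' @param seed integer master seed; every generator derives from it.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(
    class_names = c("BLCA", "LGG", "HGG", "normal"),
    samples_per_class = list(
      A = c(BLCA = 60, LGG = 60, HGG = 60, normal = 20),
      B = c(BLCA = 56, LGG = 9, HGG = 30, normal = 7)),
    n_genes_one_to_one = 1000,
    n_genes_one_to_many = 50,
    n_genes_species_specific = c(A = 100, B = 100),
    fraction_protein_coding = 0.9,
    n_signature_genes_per_class = 30,
    signature_log2fc = 2.0,
    conserved_fraction = 1.0,
    species_batch_log2fc = 0.5,
    nb_dispersion = 0.1,
    gene_length_range = c(300, 20000),
    grade_pair = c("HGG", "LGG"),
    grade_delta_log2fc = 0.25,
    n_grade_genes = 10,
    xor_pair = NULL,
    n_xor_genes = 20,
    xor_log2fc = 3.0,
    library_size_mean = 1e6,
    library_size_log_sd = 0.3,
    seed = 1L) {
  cfg <- as.list(environment())
  if (anyDuplicated(class_names)) stop("class names must be unique")
  if (n_genes_one_to_one < 1)
    stop("zero one-to-one genes: the pipeline requires a nonempty feature space")
  if (!is.null(grade_pair) && !all(grade_pair %in% class_names))
    stop("grade_pair must be a subset of class_names")
  if (!is.null(cfg$xor_pair) && !all(cfg$xor_pair %in% class_names))
    stop("xor_pair must be a subset of class_names")
  if (fraction_protein_coding <= 0 || fraction_protein_coding > 1)
    stop("fraction_protein_coding must be in (0, 1]")
  if (conserved_fraction < 0 || conserved_fraction > 1)
    stop("conserved_fraction must be in [0, 1]")
  for (sp in c("A", "B")) {
    n <- samples_per_class[[sp]]
    if (is.null(n) || is.null(names(n)) || !all(names(n) %in% class_names) ||
        any(n < 0))
      stop("samples_per_class$", sp,
           " must be a non-negative vector named by class_names")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic "design" shared by the table and both cohorts: gene ids,
# lengths, biotypes, homology structure and per-class log2 effect matrices.
# All randomness here is a pure function of cfg$seed.
simulate_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n11 <- cfg$n_genes_one_to_one
  n1m <- cfg$n_genes_one_to_many
  nsp <- cfg$n_genes_species_specific
  idA <- sprintf("GA%06d", seq_len(n11 + n1m + nsp[["A"]]))
  nB_total <- n11 + 2 * n1m + nsp[["B"]]
  idB <- sprintf("GB%06d", seq_len(nB_total))

  a11 <- idA[seq_len(n11)]
  b11 <- idB[seq_len(n11)]
  a1m <- idA[n11 + seq_len(n1m)]
  b1m <- if (n1m > 0) matrix(idB[n11 + seq_len(2 * n1m)], ncol = 2) else
    matrix(character(0), ncol = 2)
  n_pc <- round(n11 * cfg$fraction_protein_coding)
  pc11 <- sort(sample.int(n11, n_pc))         # protein-coding one2one pairs
  biotypeA <- rep("lncRNA", length(idA))
  biotypeA[pc11] <- "protein_coding"
  if (n1m > 0)
    biotypeA[n11 + seq_len(n1m)] <-
      sample(c("protein_coding", "lncRNA"), n1m, replace = TRUE)
  if (nsp[["A"]] > 0)
    biotypeA[n11 + n1m + seq_len(nsp[["A"]])] <-
      sample(c("protein_coding", "lncRNA"), nsp[["A"]], replace = TRUE)
  biotypeB <- rep("lncRNA", length(idB))
  biotypeB[seq_len(n11)][pc11] <- "protein_coding"
  if (nB_total > n11)
    biotypeB[(n11 + 1):nB_total] <-
      sample(c("protein_coding", "lncRNA"), nB_total - n11, replace = TRUE)

  lenA <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 length(idA), replace = TRUE)
  lenB <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 length(idB), replace = TRUE)

  # baseline log2 abundance and species-B batch shift, per gene
  base_A <- stats::rnorm(length(idA), mean = 3, sd = 1.5)
  base_11 <- base_A[seq_len(n11)]
  base_B <- stats::rnorm(length(idB), mean = 3, sd = 1.5)
  base_B[seq_len(n11)] <- base_11       # orthologs share a baseline ...
  batch_B <- stats::rnorm(length(idB), 0, cfg$species_batch_log2fc)  # ... plus a shift

  classes <- cfg$class_names
  tumor_classes <- setdiff(classes, "normal")
  # signature genes live among protein-coding one2one pairs so they survive
  # the feature filter and can carry cross-species signal
  eligible <- pc11
  if (!is.null(cfg$xor_pair)) {
    # reserve two contiguous blocks (contiguous in id order = feature order)
    xorU <- eligible[seq_len(cfg$n_xor_genes)]
    xorV <- eligible[cfg$n_xor_genes + seq_len(cfg$n_xor_genes)]
    eligible <- setdiff(eligible, c(xorU, xorV))
  } else xorU <- xorV <- integer(0)

  beta_A <- matrix(0, length(idA), length(classes),
                   dimnames = list(idA, classes))
  beta_B <- matrix(0, length(idB), length(classes),
                   dimnames = list(idB, classes))
  sig <- list(A = list(), B = list())
  sig_lfc <- list(A = list(), B = list())
  base_classes <- setdiff(tumor_classes, c(
    if (!is.null(cfg$grade_pair)) cfg$grade_pair[2] else character(0),
    cfg$xor_pair))
  for (k in base_classes) {
    if (length(eligible) < cfg$n_signature_genes_per_class)
      stop("not enough protein-coding one2one genes for the signatures")
    g <- sample(eligible, cfg$n_signature_genes_per_class)
    eligible <- setdiff(eligible, g)
    sgn <- rep_len(c(1, -1), length(g))
    lfc <- sgn * cfg$signature_log2fc
    conserved <- stats::runif(length(g)) < cfg$conserved_fraction
    beta_A[g, k] <- lfc
    beta_B[g[conserved], k] <- lfc[conserved]
    gB_ids <- idB[g]
    sig$A[[k]] <- idA[g]
    sig_lfc$A[[k]] <- stats::setNames(lfc, idA[g])
    # species-B-private replacement genes for the non-conserved part
    n_priv <- sum(!conserved)
    if (n_priv > 0) {
      gp <- sample(eligible, n_priv)
      eligible <- setdiff(eligible, gp)
      beta_B[gp, k] <- lfc[!conserved]
      gB_ids <- c(idB[g[conserved]], idB[gp])
      sig$B[[k]] <- gB_ids
      sig_lfc$B[[k]] <- stats::setNames(c(lfc[conserved], lfc[!conserved]), gB_ids)
    } else {
      sig$B[[k]] <- idB[g]
      sig_lfc$B[[k]] <- stats::setNames(lfc, idB[g])
    }
  }
  grade_genes <- integer(0)
  if (!is.null(cfg$grade_pair)) {
    hi <- cfg$grade_pair[1]; lo <- cfg$grade_pair[2]
    beta_A[, lo] <- beta_A[, hi]
    beta_B[, lo] <- beta_B[, hi]
    grade_genes <- sample(eligible, cfg$n_grade_genes)
    eligible <- setdiff(eligible, grade_genes)
    beta_A[grade_genes, hi] <- beta_A[grade_genes, hi] + cfg$grade_delta_log2fc
    beta_B[grade_genes, hi] <- beta_B[grade_genes, hi] + cfg$grade_delta_log2fc
    sig$A[[lo]] <- sig$A[[hi]]; sig$B[[lo]] <- sig$B[[hi]]
    sig_lfc$A[[lo]] <- sig_lfc$A[[hi]]; sig_lfc$B[[lo]] <- sig_lfc$B[[hi]]
  }

  list(idA = idA, idB = idB, a11 = a11, b11 = b11, a1m = a1m, b1m = b1m,
       pc11 = pc11, biotypeA = biotypeA, biotypeB = biotypeB,
       lenA = lenA, lenB = lenB, base_A = base_A, base_B = base_B,
       batch_B = batch_B, beta_A = beta_A, beta_B = beta_B,
       signature = sig, signature_lfc = sig_lfc,
       grade_genes = idA[grade_genes],
       xor_blocks = list(U = idA[xorU], V = idA[xorV]))
}

#' Generate the synthetic ortholog table and per-species annotations
#'
#' Produces a homology export with exactly the configured numbers of
#' one-to-one pairs, one-to-many groups (one species-A gene paired with two
#' species-B genes, flagged `ortholog_one2many`) and species-specific genes
#' (present in the annotations, absent from the table), with
#' `fraction_protein_coding` of the one-to-one pairs flagged protein-coding
#' on the species-A side. Byte-identical under the same seed.
#'
#' @param config a [simulation_config()].
#' @return list with `table` (an `ortholog_table`), `annotation` (list of
#'   species-A and species-B annotation data.frames) and `ground_truth`
#'   (design-level truth: signature sets with signed log2 effects per
#'   species and class, ortholog pairs by homology type, grade genes, XOR
#'   blocks).
#' @export
generate_ortholog_table <- function(config) {
  d <- simulate_design(config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  one2one <- data.frame(
    human_gene_id = d$a11, human_gene_name = paste0(d$a11, "_nm"),
    canine_gene_id = d$b11, canine_gene_name = paste0(d$b11, "_nm"),
    homology_type = "ortholog_one2one",
    pct_identity_h2c = round(stats::runif(length(d$a11), 80, 100), 2),
    pct_identity_c2h = round(stats::runif(length(d$a11), 80, 100), 2),
    gene_order_conservation_score = sample(c(25, 50, 75, 100),
                                           length(d$a11), replace = TRUE),
    human_biotype = d$biotypeA[seq_along(d$a11)],
    stringsAsFactors = FALSE)
  tab <- one2one
  if (length(d$a1m)) {
    a <- rep(d$a1m, each = 2)
    b <- as.vector(t(d$b1m))
    one2many <- data.frame(
      human_gene_id = a, human_gene_name = paste0(a, "_nm"),
      canine_gene_id = b, canine_gene_name = paste0(b, "_nm"),
      homology_type = "ortholog_one2many",
      pct_identity_h2c = round(stats::runif(length(a), 50, 95), 2),
      pct_identity_c2h = round(stats::runif(length(a), 50, 95), 2),
      gene_order_conservation_score = sample(c(0, 25, 50, 75),
                                             length(a), replace = TRUE),
      human_biotype = d$biotypeA[match(a, d$idA)],
      stringsAsFactors = FALSE)
    tab <- rbind(tab, one2many)
  }
  class(tab) <- c("ortholog_table", "data.frame")
  annotation <- list(
    A = data.frame(gene_id = d$idA, length_bp = d$lenA, biotype = d$biotypeA,
                   stringsAsFactors = FALSE),
    B = data.frame(gene_id = d$idB, length_bp = d$lenB, biotype = d$biotypeB,
                   stringsAsFactors = FALSE))
  gt <- list(signature = d$signature, signature_lfc = d$signature_lfc,
             pairs_one2one = data.frame(A = d$a11, B = d$b11,
                                        stringsAsFactors = FALSE),
             pairs_one2many = data.frame(A = rep(d$a1m, each = 2),
                                         B = as.vector(t(d$b1m)),
                                         stringsAsFactors = FALSE),
             grade_genes = d$grade_genes, xor_blocks = d$xor_blocks)
  class(gt) <- "sim_ground_truth"
  list(table = tab, annotation = annotation, ground_truth = gt)
}

#' Generate one species' cohort of negative-binomial counts
#'
#' Counts are drawn from a negative-binomial model whose per-sample mean is
#' `mu_gs = libsize_s * p_gs`, with `p_gs` proportional to
#' `L_g * 2^(base_g + batch_g + beta_class(g, s))`: length-weighted
#' abundance with the class signature (and, for species B, the per-gene
#' batch shift) acting additively in log2. Library sizes are log-normal
#' around `library_size_mean`. XOR classes draw a per-sample arm so that the
#' two blocks are anti- or co-activated with equal probability.
#'
#' @param config a [simulation_config()].
#' @param species `"A"` or `"B"`.
#' @return list with `counts` (an [expr_matrix()] of unit `counts`),
#'   `labels` (named character vector) and `ground_truth`.
#' @export
generate_cohort <- function(config, species = c("A", "B")) {
  species <- match.arg(species)
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  d <- simulate_design(config)
  npc <- config$samples_per_class[[species]]
  npc <- npc[npc > 0]
  if (!length(npc)) stop("species ", species, " has no class with samples")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + if (species == "A") 101L else 202L)

  ids <- if (species == "A") d$idA else d$idB
  len_kb <- (if (species == "A") d$lenA else d$lenB) / 1000
  base <- if (species == "A") d$base_A else d$base_B + d$batch_B
  beta <- if (species == "A") d$beta_A else d$beta_B

  labels <- rep(names(npc), times = npc)
  sample_id <- sprintf("%s_%s_%02d", species, labels,
                       unlist(lapply(npc, seq_len)))
  n <- length(labels)
  counts <- matrix(0, length(ids), n, dimnames = list(ids, sample_id))
  lib <- stats::rlnorm(n, meanlog = log(config$library_size_mean),
                       sdlog = config$library_size_log_sd)
  xorU <- match(d$xor_blocks$U, d$idA)
  xorV <- match(d$xor_blocks$V, d$idA)  # one2one => same index in both species
  for (s in seq_len(n)) {
    lmu <- base + beta[, labels[s]]
    if (!is.null(config$xor_pair) && labels[s] %in% config$xor_pair) {
      arm <- stats::runif(1) < 0.5
      eff <- config$xor_log2fc
      if (labels[s] == config$xor_pair[1]) {      # anti-activated blocks
        lmu[xorU] <- lmu[xorU] + if (arm) eff else -eff
        lmu[xorV] <- lmu[xorV] + if (arm) -eff else eff
      } else {                                    # co-activated blocks
        lmu[xorU] <- lmu[xorU] + if (arm) eff else -eff
        lmu[xorV] <- lmu[xorV] + if (arm) eff else -eff
      }
    }
    rate <- len_kb * 2^lmu
    mu <- lib[s] * rate / sum(rate)
    counts[, s] <- stats::rnbinom(length(ids), mu = mu,
                                  size = 1 / config$nb_dispersion)
  }
  gt <- list(signature = d$signature, signature_lfc = d$signature_lfc,
             grade_genes = d$grade_genes, xor_blocks = d$xor_blocks,
             labels = stats::setNames(labels, sample_id))
  class(gt) <- "sim_ground_truth"
  list(counts = expr_matrix(counts,
                            unit = "counts",
                            species = paste0("synthetic-", species)),
       labels = stats::setNames(labels, sample_id),
       ground_truth = gt)
}
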