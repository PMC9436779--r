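#' Synthetic cohorts with planted ground truth
#'
#' Generates every input the pipeline consumes -- toy gene annotation,
#' breakpoint pairs, copy-number segments and panel targets, small
#' variants, junction tables, expression matrices and driver alteration
#' matrices -- with per-sample planted truth, so that every stage of
#' the classification pipeline is testable without access-restricted
#' cohort data. Simulation is at the call/count level: no reads.
#'
#' @name synthetic_cohort
NULL

# deterministic sub-seed per generator block so that adding a new
# generator never perturbs the streams of existing ones
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 7919) %% 2147483629)
}

build_plus_gene <- function(gene_id, chrom, start, exon_lens,
                            intron_lens, coding = TRUE) {
  k <- length(exon_lens)
  if (length(intron_lens) == 1) intron_lens <- rep(intron_lens, k - 1)
  s <- numeric(k); e <- numeric(k)
  pos <- start
  for (i in seq_len(k)) {
    s[i] <- pos; e[i] <- pos + exon_lens[i]
    pos <- e[i] + if (i < k) intron_lens[i] else 0
  }
  exons <- data.frame(start = s, end = e)
  cds <- if (coding)
    data.frame(exon_index = seq_len(k), start = s, end = e) else NULL
  gene_model(gene_id, chrom, "+", exons, cds)
}

build_minus_gene <- function(gene_id, chrom, start, exon_lens,
                             intron_lens, coding = TRUE) {
  k <- length(exon_lens)
  if (length(intron_lens) == 1) intron_lens <- rep(intron_lens, k - 1)
  # genomic layout left-to-right is reverse transcript order
  glens <- rev(exon_lens)
  ilens <- rev(intron_lens)
  s <- numeric(k); e <- numeric(k)
  pos <- start
  for (i in seq_len(k)) {
    s[i] <- pos; e[i] <- pos + glens[i]
    pos <- e[i] + if (i < k) ilens[i] else 0
  }
  ord <- rev(seq_len(k))  # transcript order = descending coordinates
  exons <- data.frame(start = s[ord], end = e[ord])
  cds <- if (coding)
    data.frame(exon_index = seq_len(k), start = s[ord], end = e[ord])
  else NULL
  gene_model(gene_id, chrom, "-", exons, cds)
}

#' Toy gene fixtures: an 18-exon FGFR2-like gene and fusion partners
#'
#' Builds a deterministic annotation bundle: `FGFR2` with 18 fully
#' coding exons (821-aa protein; exon 17 ends at phase 1, intron 17 is
#' the breakpoint hotspot), a long partner `BICC1` whose first intron
#' is phase-compatible with intron 17, a short phase-incompatible
#' partner `TACC2`, a minus-strand partner `ATE1`, and a non-coding
#' gene `LINC1`. Alternative terminal-exon acceptor positions
#' (E18-C1..C4) and an intergenic acceptor are returned for junction
#' labelling.
#'
#' @param seed Unused for construction (the bundle is fully
#'   deterministic); kept so that callers can treat fixture generation
#'   like any other seeded generator.
#' @param gtf_path Optional path; when given the bundle is also written
#'   as GTF.
#' @return List with `models` (named list of `GeneModel`), `acceptors`
#'   (`data.frame` label/chrom/pos), and `intergenic_region`
#'   (`c(start, end)` guaranteed gene-free on chr10).
#' @export
make_toy_gene_fixtures <- function(seed = 1, gtf_path = NULL) {
  fgfr2 <- build_plus_gene("FGFR2", "chr10", 1e6,
                           c(rep(140, 16), 101, 125),
                           c(rep(2000, 16), 5000))
  bicc1 <- build_plus_gene("BICC1", "chr10", 2e6,
                           c(100, 200, 300, 2193), 1500)
  tacc2 <- build_plus_gene("TACC2", "chr11", 5e5,
                           c(150, 300, 450), 1000)
  ate1 <- build_minus_gene("ATE1", "chr11", 8e5,
                           c(220, 200, 180), 1200)
  linc1 <- build_plus_gene("LINC1", "chr10", 3e6, c(400, 600), 2500,
                           coding = FALSE)
  models <- list(FGFR2 = fgfr2, BICC1 = bicc1, TACC2 = tacc2,
                 ATE1 = ate1, LINC1 = linc1)
  i17 <- intron_interval(fgfr2, 17)
  e18 <- fgfr2$exons[18, ]
  acceptors <- data.frame(
    label = c("E18-C1", "E18-C2", "E18-C3", "E18-C4", "BICC1", "IGR1"),
    chrom = c(rep("chr10", 6)),
    pos = c(e18$start,
            i17[1] + 3500, i17[1] + 1500, i17[1] + 2500,
            bicc1$exons$start[2],
            5e6 + 500))
  out <- list(models = models, acceptors = acceptors,
              intergenic_region = c(5e6, 5.1e6))
  if (!is.null(gtf_path)) write_gene_models_gtf(models, gtf_path)
  out
}

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of the diagnostic-panel
#' cohort: the relative sizes of the three altered categories follow
#' the printed pan-cancer class counts (1367 E18-truncating : 838
#' full-length amplified : 978 hotspot), scaled so that half the
#' cohort is altered; the mechanism mixture within the E18-truncating
#' class follows the printed subgroup counts (757 in-frame fusions, 82
#' frame-unknown, 291 intergenic, 88 out-of-strand, 29 internal, 21
#' splice-site, 59 proximal truncating, 73 partial amplifications).
#'
#' @param seed Mandatory integer seed; every stochastic draw flows from
#'   it through a fixed per-generator sub-seeding scheme.
#' @param n_samples Number of tumour samples.
#' @param category_mix Named proportions over
#'   `E18_TRUNCATED`, `FL_AMP`, `HOTSPOT`, `WT` (must sum to 1).
#' @param mechanism_mix Named proportions over the E18-truncating
#'   mechanisms (must sum to 1).
#' @param af_fail_rate Fraction of planted rearrangements drawn below
#'   the allele-frequency threshold (from `af_fail_range`), so both
#'   passing and failing junctions are planted.
#' @param af_pass_range,af_fail_range Uniform ranges for passing /
#'   failing allele frequencies (kept clear of the 0.15 boundary).
#' @param decoy_unresolved_rate,decoy_distal_rate Fractions of
#'   wild-type samples receiving an unresolved rearrangement or a
#'   distal truncating mutation (neither may change the category).
#' @param base_cn,full_amp_cn,partial_cn_e18 Copy-number levels for
#'   neutral, amplified and the E18 side of partially amplified
#'   profiles.
#' @param cn_noise_sd Gaussian noise on emitted copy numbers,
#'   truncated at 0.
#' @param junction_depth Total junction reads at the E17 donor.
#' @param usage_partner_pass,usage_partner_fail Planted partner-acceptor
#'   usage for threshold-passing / failing rearrangements.
#' @param n_normals Normal samples in the expression matrix.
#' @param n_driver_genes,driver_base_rate Driver matrix dimensions and
#'   baseline alteration rate.
#' @param driver_log_or Genes x categories matrix of planted log odds
#'   ratios (default all zero); column names from the three altered
#'   categories.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(seed,
                              n_samples = 1000,
                              category_mix = c(E18_TRUNCATED = 0.215,
                                               FL_AMP = 0.132,
                                               HOTSPOT = 0.153,
                                               WT = 0.5),
                              mechanism_mix = c(
                                IN_FRAME_FUSION = 757, FRAME_UNKNOWN = 82,
                                INTERGENIC_SPACE = 291, OUT_OF_STRAND = 88,
                                INTERNAL = 29, SPLICE_MUT = 21,
                                PROXIMAL_TRUNC_MUT = 59,
                                PARTIAL_AMP = 73) / 1400,
                              af_fail_rate = 0.1,
                              af_pass_range = c(0.20, 1.0),
                              af_fail_range = c(0.02, 0.12),
                              decoy_unresolved_rate = 0.02,
                              decoy_distal_rate = 0.02,
                              base_cn = 2, full_amp_cn = 8,
                              partial_cn_e18 = 3,
                              cn_noise_sd = 0.1,
                              junction_depth = 2000,
                              usage_partner_pass = 0.6,
                              usage_partner_fail = 0.08,
                              n_normals = 10,
                              n_driver_genes = 30,
                              driver_base_rate = 0.1,
                              driver_log_or = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(category_mix) - 1) < 1e-9,
            abs(sum(mechanism_mix) - 1) < 1e-9,
            all(category_mix >= 0), all(mechanism_mix >= 0))
  if (is.null(driver_log_or)) {
    driver_log_or <- matrix(0, n_driver_genes, 3,
                            dimnames = list(
                              sprintf("DRV%02d", seq_len(n_driver_genes)),
                              c("E18_TRUNCATED", "FL_AMP", "HOTSPOT")))
  }
  structure(as.list(environment()), class = "SimulationConfig")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

truncated_normal <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' @param config A `SimulationConfig` (see [simulation_config()]).
#' @param out_dir Optional directory; when given, all tables are also
#'   written as plain-text files (GTF/BEDPE/TSV). The same seed yields
#'   a byte-identical bundle.
#' @return List with `fixtures` (gene models and acceptors), `bedpe`,
#'   `seg` (long segment table), `exon_targets` (samples x exons),
#'   `maf`, `junctions`, `expression` (list `tumour`, `normal`),
#'   `drivers` (`CohortMatrix`), and `truth` (per-sample planted truth
#'   and the planted driver log odds ratios).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  fx <- make_toy_gene_fixtures(config$seed)
  fgfr2 <- fx$models$FGFR2
  bicc1 <- fx$models$BICC1
  tacc2 <- fx$models$TACC2
  i17 <- intron_interval(fgfr2, 17)
  i3 <- intron_interval(fgfr2, 3)
  sp <- gene_span(fgfr2)
  region <- c(sp[1] - 1e4, sp[2] + 1e4)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  # --- planted assignments -------------------------------------------------
  set.seed(sub_seed(config$seed, 1))
  category <- sample(names(config$category_mix), n, replace = TRUE,
                     prob = config$category_mix)
  mechanism <- rep(NA_character_, n)
  tr <- category == "E18_TRUNCATED"
  mechanism[tr] <- sample(names(config$mechanism_mix), sum(tr),
                          replace = TRUE, prob = config$mechanism_mix)
  wt <- which(category == "WT")
  n_unres <- round(config$decoy_unresolved_rate * length(wt))
  n_distal <- round(config$decoy_distal_rate * length(wt))
  decoy_unres <- wt[seq_len(n_unres)]
  decoy_distal <- wt[n_unres + seq_len(n_distal)]
  mechanism[decoy_unres] <- "UNRESOLVED_DECOY"
  mechanism[decoy_distal] <- "DISTAL_DECOY"

  re_mechs <- c("IN_FRAME_FUSION", "FRAME_UNKNOWN", "INTERGENIC_SPACE",
                "OUT_OF_STRAND", "INTERNAL")
  is_re <- !is.na(mechanism) &
    mechanism %in% c(re_mechs, "UNRESOLVED_DECOY")
  af <- rep(NA_real_, n)
  re_rows <- which(is_re & mechanism != "UNRESOLVED_DECOY")
  fail <- stats::runif(length(re_rows)) < config$af_fail_rate
  af[re_rows[fail]] <- runif_range(sum(fail), config$af_fail_range)
  af[re_rows[!fail]] <- runif_range(sum(!fail), config$af_pass_range)
  af[decoy_unres] <- runif_range(length(decoy_unres),
                                 config$af_pass_range)

  # expected truth: RE mechanisms only truncate when the allele
  # frequency clears the 0.15 threshold; unresolved and distal decoys
  # never do
  expected <- category
  demote <- re_rows[af[re_rows] <= 0.15]
  expected[demote] <- "WT"
  expected_re_type <- ifelse(mechanism %in% re_mechs, mechanism,
                             ifelse(mechanism == "UNRESOLVED_DECOY",
                                    "UNRESOLVED", NA))

  # --- copy-number profiles ------------------------------------------------
  set.seed(sub_seed(config$seed, 2))
  amp_status <- rep("NONE", n)
  amp_status[category == "FL_AMP"] <- "FULL_LENGTH_AMP"
  amp_status[!is.na(mechanism) & mechanism == "PARTIAL_AMP"] <-
    "PARTIAL_AMP_E1_E17"
  seg_rows <- list()
  gene_cn <- numeric(n)
  exon_targets <- matrix(NA_real_, n, n_exons(fgfr2),
                         dimnames = list(ids, paste0("E",
                                                     seq_len(n_exons(fgfr2)))))
  for (i in seq_len(n)) {
    st <- amp_status[i]
    if (st == "PARTIAL_AMP_E1_E17") {
      split_at <- round(stats::runif(1, i17[1] + 100, i17[2] - 100))
      cn1 <- truncated_normal(1, config$full_amp_cn, config$cn_noise_sd)
      cn2 <- truncated_normal(1, config$partial_cn_e18,
                              config$cn_noise_sd)
      seg_rows[[i]] <- data.frame(
        sample = ids[i], chrom = fgfr2$chromosome,
        start = c(region[1], split_at), end = c(split_at, region[2]),
        value = c(cn1, cn2))
      w1 <- split_at - sp[1]; w2 <- sp[2] - split_at
      gene_cn[i] <- (cn1 * w1 + cn2 * w2) / (w1 + w2)
      base <- c(rep(cn1, 17), cn2)
    } else {
      level <- if (st == "FULL_LENGTH_AMP") config$full_amp_cn
               else config$base_cn
      cn1 <- truncated_normal(1, level, config$cn_noise_sd)
      seg_rows[[i]] <- data.frame(
        sample = ids[i], chrom = fgfr2$chromosome,
        start = region[1], end = region[2], value = cn1)
      gene_cn[i] <- cn1
      base <- rep(cn1, 18)
    }
    exon_targets[i, ] <- truncated_normal(18, base, config$cn_noise_sd)
  }
  seg <- do.call(rbind, seg_rows)

  # --- structural variants -------------------------------------------------
  set.seed(sub_seed(config$seed, 3))
  bedpe_rows <- list()
  for (i in which(is_re)) {
    mech <- mechanism[i]
    a_pos <- round(stats::runif(1, i17[1] + 10, i17[2] - 10))
    a_strand <- if (mech == "UNRESOLVED_DECOY") "-" else "+"
    if (mech %in% c("IN_FRAME_FUSION", "UNRESOLVED_DECOY")) {
      b_chrom <- bicc1$chromosome
      b_pos <- round(stats::runif(1, bicc1$exons$end[1] + 10,
                                  bicc1$exons$start[2] - 10))
      b_strand <- "+"
    } else if (mech == "FRAME_UNKNOWN") {
      b_chrom <- tacc2$chromosome
      b_pos <- round(stats::runif(1, tacc2$exons$end[1] + 10,
                                  tacc2$exons$start[2] - 10))
      b_strand <- "+"
    } else if (mech == "INTERGENIC_SPACE") {
      b_chrom <- "chr10"
      b_pos <- round(runif_range(1, fx$intergenic_region))
      b_strand <- "+"
    } else if (mech == "OUT_OF_STRAND") {
      b_chrom <- bicc1$chromosome
      b_pos <- round(stats::runif(1, bicc1$exons$end[1] + 10,
                                  bicc1$exons$start[2] - 10))
      b_strand <- "-"
    } else {  # INTERNAL
      b_chrom <- fgfr2$chromosome
      b_pos <- round(stats::runif(1, i3[1] + 10, i3[2] - 10))
      b_strand <- "+"
    }
    bedpe_rows[[length(bedpe_rows) + 1]] <- data.frame(
      chrom1 = fgfr2$chromosome, start1 = a_pos, end1 = a_pos + 1,
      chrom2 = b_chrom, start2 = b_pos, end2 = b_pos + 1,
      name = sprintf("RE_%s", ids[i]), score = 0,
      strand1 = a_strand, strand2 = b_strand,
      sample = ids[i], ploidy = af[i] * gene_cn[i])
  }
  bedpe <- if (length(bedpe_rows)) do.call(rbind, bedpe_rows) else NULL

  # --- small variants ------------------------------------------------------
  set.seed(sub_seed(config$seed, 4))
  hs <- default_hotspots()
  hs <- hs[hs$gene == "FGFR2", ]
  aa <- setdiff(unname(AA3), "*")
  maf_rows <- list()
  mut_class <- rep(NA_character_, n)
  e18_acceptor <- if (fgfr2$strand == "+") fgfr2$exons$start[18] - 1
                  else fgfr2$exons$end[18]
  for (i in seq_len(n)) {
    rows <- NULL
    if (category[i] == "HOTSPOT") {
      j <- sample(nrow(hs), 1)
      alt <- sample(setdiff(aa, hs$ref_aa[j]), 1)
      rows <- data.frame(sample = ids[i], gene = "FGFR2",
                         hgvs_p = sprintf("p.%s%d%s", hs$ref_aa[j],
                                          hs$position[j], alt),
                         consequence = "missense", chromosome = NA,
                         position = NA)
      mut_class[i] <- "HOTSPOT"
    } else if (!is.na(mechanism[i]) &&
               mechanism[i] == "PROXIMAL_TRUNC_MUT") {
      pos <- sample(768:783, 1)
      rows <- data.frame(sample = ids[i], gene = "FGFR2",
                         hgvs_p = sprintf("p.%s%d*", sample(aa, 1), pos),
                         consequence = "nonsense", chromosome = NA,
                         position = NA)
      mut_class[i] <- "PROXIMAL_TRUNCATING"
    } else if (!is.na(mechanism[i]) && mechanism[i] == "DISTAL_DECOY") {
      pos <- sample(784:821, 1)
      rows <- data.frame(sample = ids[i], gene = "FGFR2",
                         hgvs_p = sprintf("p.%s%dfs", sample(aa, 1), pos),
                         consequence = "frameshift", chromosome = NA,
                         position = NA)
      mut_class[i] <- "DISTAL_TRUNCATING"
    } else if (!is.na(mechanism[i]) && mechanism[i] == "SPLICE_MUT") {
      rows <- data.frame(sample = ids[i], gene = "FGFR2",
                         hgvs_p = NA,
                         consequence = "splice_site",
                         chromosome = fgfr2$chromosome,
                         position = e18_acceptor)
      mut_class[i] <- "E18_SPLICE"
    }
    if (!is.null(rows)) maf_rows[[length(maf_rows) + 1]] <- rows
  }
  maf <- if (length(maf_rows)) do.call(rbind, maf_rows) else
    data.frame(sample = character(), gene = character(),
               hgvs_p = character(), consequence = character(),
               chromosome = character(), position = numeric())

  # --- junction tables -----------------------------------------------------
  set.seed(sub_seed(config$seed, 5))
  junction_rows <- list()
  partner_usage <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mech <- mechanism[i]
    if (!is.na(mech) && mech %in% re_mechs) {
      u <- if (af[i] > 0.15) config$usage_partner_pass
           else config$usage_partner_fail
      partner_usage[i] <- u
      acc_label <- if (mech %in% c("INTERGENIC_SPACE", "INTERNAL"))
        "IGR1" else "BICC1"
      probs <- c(1 - u - 0.05, 0.03, 0.02, u)
      labels <- c("E18-C1", "E18-C3", "E18-C4", acc_label)
    } else {
      probs <- c(0.96, 0.03, 0.01)
      labels <- c("E18-C1", "E18-C3", "E18-C4")
    }
    counts <- as.integer(stats::rmultinom(1, config$junction_depth,
                                          probs))
    junction_rows[[i]] <- data.frame(sample = ids[i], donor = "E17",
                                     acceptor = labels, count = counts)
  }
  junctions <- do.call(rbind, junction_rows)

  # --- expression ----------------------------------------------------------
  set.seed(sub_seed(config$seed, 6))
  n_ex <- n_exons(fgfr2)
  make_expr <- function(k, e18_ratio) {
    base <- 10 * 2^stats::rnorm(k * n_ex, 0, 0.1)
    m <- matrix(base, k, n_ex)
    m[, n_ex] <- m[, n_ex] * e18_ratio
    colnames(m) <- paste0("E", seq_len(n_ex))
    m
  }
  tum <- make_expr(n, 1)
  truncated <- expected == "E18_TRUNCATED"
  tum[truncated, n_ex] <- tum[truncated, n_ex] * 0.1
  rownames(tum) <- ids
  nor <- make_expr(config$n_normals, 1)
  rownames(nor) <- sprintf("N%03d", seq_len(config$n_normals))

  # --- driver alteration matrix -------------------------------------------
  set.seed(sub_seed(config$seed, 7))
  drivers <- simulate_driver_matrix(expected, config$driver_base_rate,
                                    config$driver_log_or)

  truth <- list(
    samples = data.frame(sample_id = ids, planted_category = category,
                         expected_category = expected,
                         mechanism = mechanism,
                         re_type = expected_re_type,
                         allele_frequency = af,
                         amp_status = amp_status,
                         mutation_class = mut_class,
                         partner_usage = partner_usage,
                         gene_cn = gene_cn,
                         stringsAsFactors = FALSE),
    driver_log_or = config$driver_log_or)

  sim <- list(fixtures = fx, bedpe = bedpe, seg = seg,
              exon_targets = exon_targets, maf = maf,
              junctions = junctions,
              expression = list(tumour = tum, normal = nor),
              drivers = drivers, truth = truth, config = config)
  if (!is.null(out_dir)) write_cohort_bundle(sim, out_dir)
  sim
}

#' Simulate a binary driver alteration matrix with planted odds ratios
#'
#' Gene alteration probabilities follow a logistic model: the log odds
#' of alteration in a sample of category `c` equal the baseline log
#' odds plus the planted log odds ratio of that gene in that category
#' (wild-type samples stay at baseline).
#'
#' @param category Character vector of per-sample categories.
#' @param base_rate Baseline alteration probability.
#' @param log_or Genes x categories matrix of planted log odds ratios.
#' @return A `CohortMatrix`.
#' @export
simulate_driver_matrix <- function(category, base_rate, log_or) {
  n <- length(category)
  genes <- rownames(log_or)
  m <- matrix(0L, n, length(genes), dimnames = list(NULL, genes))
  base_logit <- stats::qlogis(base_rate)
  for (g in seq_along(genes)) {
    shift <- rep(0, n)
    for (cat in colnames(log_or)) {
      shift[category == cat] <- log_or[g, cat]
    }
    m[, g] <- stats::rbinom(n, 1, stats::plogis(base_logit + shift))
  }
  cohort_matrix(m, category)
}

write_cohort_bundle <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f, row = FALSE) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = row, col.names = TRUE)
  }
  write_gene_models_gtf(sim$fixtures$models,
                        file.path(out_dir, "genes.gtf"))
  if (!is.null(sim$bedpe))
    utils::write.table(sim$bedpe, file.path(out_dir, "sv.bedpe"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  wt(sim$seg, "cn_segments.tsv")
  wt(as.data.frame(sim$exon_targets), "cn_exon_targets.tsv", row = TRUE)
  wt(sim$maf, "mutations.tsv")
  wt(sim$junctions, "junctions.tsv")
  wt(as.data.frame(sim$expression$tumour), "expression_tumour.tsv",
     row = TRUE)
  wt(as.data.frame(sim$expression$normal), "expression_normal.tsv",
     row = TRUE)
  wt(as.data.frame(sim$drivers$alterations), "drivers.tsv", row = TRUE)
  wt(sim$truth$samples, "truth_samples.tsv")
  invisible(out_dir)
}
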