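models <- toy$models
fgfr2 <- models$FGFR2
i17 <- intron_interval(fgfr2, 17)
bnd <- function(chrom, pos, orient = "sense")
  annotate_breakend(chrom, pos, orient, models)
a_i17 <- bnd("chr10", i17[1] + 50)

test_that("backbone selection follows protein length with documented ties", {
  expect_equal(select_backbone(models$FGFR2, models$TACC2), "FGFR2")
  expect_equal(select_backbone(models$FGFR2, models$BICC1), "BICC1")
  expect_equal(select_backbone(models$FGFR2, models$LINC1), "FGFR2")
  twin_a <- gene_model("A", "chr1", "+",
                       data.frame(start = 0, end = 300),
                       data.frame(exon_index = 1, start = 0, end = 300))
  twin_b <- gene_model("B", "chr1", "+",
                       data.frame(start = 1000, end = 1300),
                       data.frame(exon_index = 1, start = 1000, end = 1300))
  expect_equal(select_backbone(twin_a, twin_b), "A")
  nc <- models$LINC1
  expect_error(select_backbone(nc, nc), "non-coding")
})

test_that("the six rearrangement types are assigned in rule order", {
  # intronic/intronic, phases 1 vs 1 -> in-frame fusion
  b_compat <- bnd("chr10", models$BICC1$exons$end[1] + 100)
  call <- classify_re(a_i17, b_compat, models, "FGFR2")
  expect_equal(call$re_type, "IN_FRAME_FUSION")
  expect_equal(call$backbone_gene, "BICC1")
  # phases 1 vs 0 -> frame unknown
  b_incompat <- bnd("chr11", models$TACC2$exons$end[1] + 100)
  expect_equal(classify_re(a_i17, b_incompat, models, "FGFR2")$re_type,
               "FRAME_UNKNOWN")
  # intergenic partner
  b_igr <- bnd("chr10", 5e6 + 100)
  expect_equal(classify_re(a_i17, b_igr, models, "FGFR2")$re_type,
               "INTERGENIC_SPACE")
  # both breakends inside the gene of interest
  i3 <- intron_interval(fgfr2, 3)
  b_i3 <- bnd("chr10", i3[1] + 20)
  expect_equal(classify_re(a_i17, b_i3, models, "FGFR2")$re_type,
               "INTERNAL")
  # downstream side antisense-supported
  b_anti <- bnd("chr10", models$BICC1$exons$end[1] + 100, "antisense")
  expect_equal(classify_re(a_i17, b_anti, models, "FGFR2")$re_type,
               "OUT_OF_STRAND")
  # upstream side antisense-supported
  a_anti <- bnd("chr10", i17[1] + 50, "antisense")
  expect_equal(classify_re(a_anti, b_compat, models, "FGFR2")$re_type,
               "UNRESOLVED")
  # single breakend
  expect_equal(classify_re(a_i17, NULL, models, "FGFR2")$re_type,
               "UNRESOLVED")
  expect_equal(classify_re(a_i17, a_i17, models, "FGFR2")$re_type,
               "UNRESOLVED")
  # non-coding partner gene: frame unpredictable
  b_nc <- bnd("chr10", models$LINC1$exons$end[1] + 100)
  expect_equal(classify_re(a_i17, b_nc, models, "FGFR2")$re_type,
               "FRAME_UNKNOWN")
})

test_that("exonic/exonic junctions are frame-tested on base offsets", {
  # FGFR2 exon 17 starts at phase 2; BICC1 exon 2 starts at phase 1.
  e17 <- fgfr2$exons[17, ]
  e2b <- models$BICC1$exons[2, ]
  # offsets chosen so (2 + oa) == (1 + ob) mod 3
  a_ex <- bnd("chr10", e17$start + 10)
  b_in_frame <- bnd("chr10", e2b$start + 11)
  expect_equal(classify_re(a_ex, b_in_frame, models, "FGFR2")$re_type,
               "IN_FRAME_FUSION")
  b_off <- bnd("chr10", e2b$start + 12)
  expect_equal(classify_re(a_ex, b_off, models, "FGFR2")$re_type,
               "FRAME_UNKNOWN")
  # mixed intronic/exonic junctions cannot be called in-frame
  expect_equal(classify_re(a_i17, b_in_frame, models, "FGFR2")$re_type,
               "FRAME_UNKNOWN")
})

test_that("breakend input order does not change the call", {
  for (b in list(bnd("chr10", models$BICC1$exons$end[1] + 100),
                 bnd("chr10", 5e6 + 100),
                 bnd("chr11", models$TACC2$exons$end[1] + 100))) {
    c1 <- classify_re(a_i17, b, models, "FGFR2")
    c2 <- classify_re(b, a_i17, models, "FGFR2")
    expect_identical(c1$re_type, c2$re_type)
    expect_identical(c1$backbone_gene, c2$backbone_gene)
  }
})

test_that("codon-complete frame rule is stricter than phase compatibility", {
  b_compat <- bnd("chr10", models$BICC1$exons$end[1] + 100)
  expect_equal(classify_re(a_i17, b_compat, models, "FGFR2",
                           frame_rule = "codon_complete")$re_type,
               "FRAME_UNKNOWN")  # phase 1 boundary is not codon-complete
})

test_that("allele frequency quotient, clamp and strict 0.15 threshold", {
  b <- bnd("chr10", models$BICC1$exons$end[1] + 100)
  call <- classify_re(a_i17, b, models, "FGFR2", junction_ploidy = 1)
  call <- compute_allele_frequency(call, 2)
  expect_equal(call$allele_frequency, 0.5)
  expect_true(call$e18_truncating)
  call2 <- classify_re(a_i17, b, models, "FGFR2", junction_ploidy = 0.2)
  expect_false(compute_allele_frequency(call2, 2)$e18_truncating)
  expect_equal(compute_allele_frequency(call2, 2)$allele_frequency, 0.1)
  call3 <- classify_re(a_i17, b, models, "FGFR2", junction_ploidy = 5)
  expect_equal(compute_allele_frequency(call3, 4)$allele_frequency, 1)
  expect_error(compute_allele_frequency(call, 0), "positive")
  # breakend outside I17/E18 never flags E18 truncation
  i3 <- intron_interval(fgfr2, 3)
  call4 <- classify_re(bnd("chr10", i3[1] + 10), b, models, "FGFR2",
                       junction_ploidy = 2)
  expect_false(compute_allele_frequency(call4, 2)$e18_truncating)
})

test_that("clonality normalization and the 0.25 insertion call", {
  expect_equal(normalize_clonality(c(40, 10, 8)), c(1.0, 0.25, 0.2))
  expect_equal(normalize_clonality(7), 1.0)
  expect_equal(sb_insertion_hit(normalize_clonality(c(40, 10, 8))),
               c(TRUE, TRUE, FALSE))
  expect_equal(sb_insertion_hit(normalize_clonality(c(40, 9))),
               c(TRUE, FALSE))  # 0.225 < 0.25
  expect_error(normalize_clonality(c(0, 0)), "zero")
})

test_that("sliding-window density counts and conserves totals", {
  d <- sliding_window_density(c(1000, 1100), window = 500)
  expect_equal(d$count[d$pos == 1050], 2L)
  expect_equal(max(d$count), 2L)
  expect_equal(nrow(sliding_window_density(integer())), 0)
  z <- sliding_window_density(integer(), from = 1, to = 10)
  expect_true(all(z$count == 0))
  expect_equal(max(sliding_window_density(42)$count), 1L)
  # total conservation over a non-overlapping tiling of window centres
  set.seed(3)
  pos <- sample(5000:6000, 40, replace = TRUE)
  d <- sliding_window_density(pos, window = 500, from = 4000, to = 7000)
  centres <- seq(4250, 6750, by = 500)
  expect_equal(sum(d$count[match(centres, d$pos)]), length(pos))
})

test_that("every simulated junction receives exactly one known type", {
  cfg <- simulation_config(seed = 7, n_samples = 150)
  sim <- simulate_cohort(cfg)
  res <- classify_sv_table(sim$bedpe, sim$fixtures$models, "FGFR2")
  expect_true(all(res$re_type %in% c("IN_FRAME_FUSION", "FRAME_UNKNOWN",
                                     "INTERGENIC_SPACE", "OUT_OF_STRAND",
                                     "INTERNAL", "UNRESOLVED")))
  expect_equal(nrow(res), nrow(sim$bedpe))
})
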