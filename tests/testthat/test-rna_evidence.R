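jt <- function(...) {
  x <- list(...)
  data.frame(donor = "E17", acceptor = names(x),
             count = as.integer(unlist(x)))
}

test_that("acceptor usage fractions are counts over the donor total", {
  u <- acceptor_usage(jt(`E18-C1` = 80, `E18-C3` = 20))
  expect_equal(as.vector(u), c(0.8, 0.2))
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_equal(as.vector(acceptor_usage(jt(`E18-C1` = 100))), 1.0)
  u2 <- acceptor_usage(jt(`E18-C1` = 50, BICC1 = 50))
  expect_equal(unname(u2["BICC1"]), 0.5)
  # permutation invariance
  a <- jt(`E18-C1` = 10, `E18-C3` = 30, BICC1 = 60)
  b <- a[c(3, 1, 2), ]
  expect_equal(sort(acceptor_usage(a)), sort(acceptor_usage(b)))
  # undefined usage propagates as NA, never as 0
  u0 <- acceptor_usage(jt(`E18-C1` = 0, BICC1 = 0))
  expect_true(all(is.na(u0)))
  expect_true(attr(u0, "undefined"))
  expect_true(is.na(call_e18_truncated_rna(u0)))
})

test_that("RNA truncation call uses a strict 15% junction frequency", {
  expect_true(call_e18_truncated_rna(
    acceptor_usage(jt(`E18-C1` = 80, BICC1 = 20))))
  expect_false(call_e18_truncated_rna(
    acceptor_usage(jt(`E18-C1` = 85, BICC1 = 15))))  # exactly 0.15
  expect_false(call_e18_truncated_rna(
    acceptor_usage(jt(`E18-C1` = 60, `E18-C3` = 40))))  # C3 not evidence
  expect_true(call_e18_truncated_rna(
    acceptor_usage(jt(`E18-C1` = 60, `E18-C3` = 40)),
    evidence_classes = c("partner", "IGR", "SB", "C3", "C4")))
  expect_true(call_e18_truncated_rna(
    acceptor_usage(jt(`E18-C1` = 70, IGR1 = 30))))
})

test_that("chimeric-read filters and the spanning-read>2 rule", {
  mk <- function(bp, n, dup = FALSE, aln = 1, cls = "gene") {
    data.frame(breakpoint = rep(bp, n), alignment_count = aln,
               duplicate_flag = dup, partner_class = cls)
  }
  expect_equal(filter_chimeric_reads(mk("bp1", 3))$breakpoint, "bp1")
  expect_equal(nrow(filter_chimeric_reads(
    rbind(mk("bp1", 2), mk("bp1", 1, dup = TRUE)))), 0)
  expect_equal(nrow(filter_chimeric_reads(mk("bp1", 5, cls = "HLA"))), 0)
  expect_equal(nrow(filter_chimeric_reads(mk("bp1", 5, aln = 2))), 0)
  expect_equal(nrow(filter_chimeric_reads(
    data.frame(breakpoint = character(), alignment_count = integer(),
               duplicate_flag = logical(),
               partner_class = character()))), 0)
  # output is a subset of input breakpoints; refiltering is a no-op
  reads <- rbind(mk("bp1", 4), mk("bp2", 2), mk("bp3", 6, cls = "HLA"))
  kept <- filter_chimeric_reads(reads)
  expect_true(all(kept$breakpoint %in% reads$breakpoint))
  rereads <- data.frame(breakpoint = rep(kept$breakpoint, kept$count),
                        alignment_count = 1, duplicate_flag = FALSE,
                        partner_class = "gene")
  expect_equal(filter_chimeric_reads(rereads), kept)
})

test_that("E18 expression loss against the normal-tissue minimum", {
  x <- c(rep(10, 17), 2)
  expect_true(e18_loss(x, 0.5))            # 0.2 < 0.5
  expect_false(e18_loss(c(rep(10, 17), 10), 0.5))
  expect_error(e18_loss(x, NA_real_), "normal")
  normals <- rbind(c(rep(10, 17), 8), c(rep(10, 17), 5))
  expect_equal(normal_reference_e18(normals), 0.5)
})

test_that("transposon splice ratio and fraction", {
  r <- sb_splice_ratio(90, 10)
  expect_equal(r$fraction, 0.9)
  expect_equal(r$ratio, 9)
  expect_equal(sb_splice_ratio(0, 50)$fraction, 0)
  r2 <- sb_splice_ratio(50, 0)
  expect_equal(r2$ratio, Inf)
  expect_equal(r2$fraction, 1.0)
  expect_error(sb_splice_ratio(0, 0), "no junction reads")
})

test_that("composite FGFR score sums geometric-mean-normalized receptors", {
  m <- rbind(s1 = c(2, 4, 8, 16), s2 = c(2, 4, 8, 16))
  out <- composite_fgfr_expression(m)
  # both samples sit at the per-receptor geometric mean -> score 4
  expect_equal(out$score, c(4, 4))
  expect_true(all(out$high))
  m2 <- rbind(s1 = c(2, 2, 2, 2), s2 = c(8, 8, 8, 8))
  out2 <- composite_fgfr_expression(m2)
  expect_equal(out2$score, c(2, 8))
  expect_equal(out2$high, c(FALSE, TRUE))
  # invariance to rescaling one receptor across all samples
  m3 <- m2
  m3[, 2] <- m3[, 2] * 1000
  expect_equal(composite_fgfr_expression(m3)$score, out2$score)
  # a score of exactly 3 is not high (strict threshold)
  m4 <- rbind(s1 = rep(9, 4), s2 = rep(16, 4))
  out4 <- composite_fgfr_expression(m4)
  expect_equal(out4$score[1], 3)
  expect_false(out4$high[1])
  expect_error(composite_fgfr_expression(m[1, , drop = FALSE]),
               "two samples")
})

test_that("usage outliers flagged at one-sided normal p < 0.01", {
  usage <- c(rep(0.01, 19), 0.5)
  flags <- usage_outlier_z(usage)
  expect_true(flags[20])
  expect_false(any(flags[1:19]))
  # hand Z for the outlier sample
  z <- (0.5 - mean(usage)) / sd(usage)
  expect_true(z > qnorm(0.99))
  expect_warning(f0 <- usage_outlier_z(rep(0.3, 5)), "constant")
  expect_false(any(f0))
  expect_error(usage_outlier_z(c(0.1, 0.2)), "at least 3")
})

test_that("cell-line fusion filter applies the printed boundaries", {
  expect_true(ccle_fusion_filter(0.2, 5, 1.0))
  expect_false(ccle_fusion_filter(0.1, 10, 5))   # FFPM not > 0.1
  expect_false(ccle_fusion_filter(0.5, 4, 5))    # fragments < 5
  expect_false(ccle_fusion_filter(0.5, 5, 0.99)) # RPKM < 1
})

test_that("SJ-dialect junction reader maps donors and acceptors", {
  fgfr2 <- toy$models$FGFR2
  e17 <- fgfr2$exons[17, ]
  e18 <- fgfr2$exons[18, ]
  bicc1_e2 <- toy$models$BICC1$exons[2, ]
  sj <- tempfile(fileext = ".tab")
  lines <- c(
    sprintf("chr10\t%d\t%d\t1\t1\t1\t80\t3\t30",
            e17$end + 1, e18$start),                  # E17 -> E18 (C1)
    sprintf("chr10\t%d\t%d\t1\t1\t0\t15\t0\t25",
            e17$end + 1, bicc1_e2$start),             # E17 -> partner
    sprintf("chr10\t%d\t%d\t1\t1\t0\t5\t0\t25",
            e17$end + 1, as.integer(5e6 + 500)),      # E17 -> intergenic
    sprintf("chr10\t%d\t%d\t1\t1\t1\t99\t0\t25",
            as.integer(e17$end + 200), e18$start))    # wrong donor, dropped
  writeLines(lines, sj)
  out <- read_star_sj(sj, fgfr2, toy$models, acceptors = toy$acceptors)
  expect_equal(nrow(out), 3)
  expect_setequal(out$acceptor, c("E18-C1", "BICC1", "IGR1"))
  expect_equal(out$count[out$acceptor == "E18-C1"], 80)
  u <- acceptor_usage(out)
  expect_equal(unname(u["BICC1"]), 0.15)
})
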