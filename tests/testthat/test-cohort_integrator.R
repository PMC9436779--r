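models <- toy$models
fgfr2 <- models$FGFR2
i17 <- intron_interval(fgfr2, 17)

mk_fusion_call <- function(ploidy = 1, cn = 2) {
  a <- annotate_breakend("chr10", i17[1] + 50, "sense", models)
  b <- annotate_breakend("chr10", models$BICC1$exons$end[1] + 100,
                         "sense", models)
  compute_allele_frequency(
    classify_re(a, b, models, "FGFR2", junction_ploidy = ploidy), cn)
}
amp <- function(status) {
  structure(list(status = status, rule_set = "WGS",
                 cn_e1_e17 = NA_real_, cn_e18 = NA_real_),
            class = "AmplificationCall")
}

test_that("category assignment follows the documented precedence", {
  p <- assign_category("s1", re_calls = list(mk_fusion_call()))
  expect_equal(p$category, "E18_TRUNCATED")
  expect_equal(p$subgroup, "IN_FRAME_FUSION")
  # full amplification beats hotspot
  p <- assign_category("s2", amp_call = amp("FULL_LENGTH_AMP"),
                       mutations = list(classify_mutation("FGFR2",
                                                          "p.N549K")))
  expect_equal(p$category, "FL_AMP")
  # distal truncating mutations never trigger truncation
  p <- assign_category("s3",
                       mutations = list(classify_mutation("FGFR2",
                                                          "p.L800fs")))
  expect_equal(p$category, "WT")
  expect_true(p$annotations$distal_truncating)
  # fusion co-occurring with full amplification keeps the truncated
  # category under a dedicated subgroup
  p <- assign_category("s4", re_calls = list(mk_fusion_call()),
                       amp_call = amp("FULL_LENGTH_AMP"))
  expect_equal(p$category, "E18_TRUNCATED")
  expect_equal(p$subgroup, "FUSION_PLUS_AMP")
  # partial amplification alone truncates
  p <- assign_category("s5", amp_call = amp("PARTIAL_AMP_E1_E17"))
  expect_equal(p$category, "E18_TRUNCATED")
  expect_equal(p$subgroup, "PARTIAL_AMP")
  # sub-threshold fusions do not
  p <- assign_category("s6", re_calls = list(mk_fusion_call(0.2)))
  expect_equal(p$category, "WT")
  expect_error(assign_category("s7"), "no evidence")
})

test_that("assignment is idempotent and partitions samples", {
  p1 <- assign_category("s", re_calls = list(mk_fusion_call()),
                        amp_call = amp("NONE"))
  p2 <- assign_category("s", re_calls = p1$re_calls,
                        amp_call = p1$amp_call,
                        mutations = p1$mutations)
  expect_identical(p1$category, p2$category)
  expect_identical(p1$subgroup, p2$subgroup)
  expect_true(p1$category %in% c("E18_TRUNCATED", "FL_AMP", "HOTSPOT",
                                 "WT"))
})

test_that("cohort summary counts, incidences and fractions agree", {
  profiles <- c(
    replicate(7, assign_category("x", re_calls = list(mk_fusion_call())),
              simplify = FALSE),
    replicate(2, assign_category("y", amp_call = amp("FULL_LENGTH_AMP")),
              simplify = FALSE),
    replicate(1, assign_category("z", amp_call = amp("NONE")),
              simplify = FALSE))
  s <- cohort_summary(profiles, total_assayed = 1000)
  expect_equal(unname(s$category_counts["E18_TRUNCATED"]), 7)
  expect_equal(sum(s$category_counts), 10)
  expect_equal(unname(s$incidence_pct["E18_TRUNCATED"]), 0.70)
  expect_equal(unname(s$fraction_pct$E18_TRUNCATED["IN_FRAME_FUSION"]),
               100)
  expect_error(cohort_summary(profiles, 5), "smaller")
  expect_error(cohort_summary(profiles, 0), "positive")
})

test_that("rounding is half-up at the printed precision", {
  expect_equal(round_half_up(0.545, 2), 0.55)
  expect_equal(round_half_up(55.35, 1), 55.4)
  expect_equal(round_half_up(0.544999, 2), 0.54)
  expect_equal(incidence_pct(0, 100), 0)
  expect_equal(fraction_pct(1, 3), 33.3)
})

test_that("treatment response ratio from volume series", {
  r <- delta_t_delta_c(list(c(200, 150)), list(c(210, 600)))
  expect_equal(r$delta_t, -50)
  expect_equal(r$delta_c, 390)
  expect_equal(r$ratio, -50 / 390, tolerance = 1e-12)
  same <- list(c(100, 300), c(120, 280))
  expect_equal(delta_t_delta_c(same, same)$ratio, 1.0)
  flat <- delta_t_delta_c(list(c(100, 150)), list(c(100, 100)))
  expect_false(flat$defined)
  expect_true(is.na(flat$ratio))
  expect_error(delta_t_delta_c(list(c(100)), list(c(1, 2))))
})
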