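test_that("GTF loading builds the expected coding model", {
  gtf <- tempfile(fileext = ".gtf")
  # 3-exon gene, exons 200/50/30 with CDS 100/50/30 (UTR in exon 1)
  writeLines(c(
    'chr1\ttest\texon\t101\t300\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\ttest\tCDS\t201\t300\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\ttest\texon\t401\t450\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\ttest\tCDS\t401\t450\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\ttest\texon\t601\t630\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\ttest\tCDS\t601\t630\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";'),
    gtf)
  models <- load_gene_models(gtf, "G1")
  m <- models$G1
  expect_s3_class(m, "GeneModel")
  expect_equal(nrow(m$exons), 3)
  # 1-based inclusive GTF -> 0-based half-open
  expect_equal(m$exons$start, c(100, 400, 600))
  expect_equal(m$exons$end, c(300, 450, 630))
  # 180 coding bases -> 59 aa (stop codon included in the CDS)
  expect_equal(m$protein_length, 59L)
  ph <- compute_exon_phases(m)
  expect_equal(ph$start_phase, c(0L, 1L, 0L))
  expect_equal(ph$end_phase, c(1L, 0L, 0L))
})

test_that("empty request, missing gene and non-coding handling", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "NC"; transcript_id "NC.t1";'),
    gtf)
  expect_length(load_gene_models(gtf, character()), 0)
  expect_error(load_gene_models(gtf, "ABSENT"), "gene not found")
  expect_error(load_gene_models(gtf, "NC", require_coding = TRUE),
               "non-coding")
  expect_false(load_gene_models(gtf, "NC")$NC$coding)
  expect_error(compute_exon_phases(load_gene_models(gtf, "NC")$NC),
               "non-coding")
})

test_that("minus-strand exons come back in transcript order", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr2\ttest\texon\t1001\t1100\t.\t-\t.\tgene_id "GM"; transcript_id "GM.t1";',
    'chr2\ttest\tCDS\t1001\t1100\t.\t-\t.\tgene_id "GM"; transcript_id "GM.t1";',
    'chr2\ttest\texon\t2001\t2050\t.\t-\t.\tgene_id "GM"; transcript_id "GM.t1";',
    'chr2\ttest\tCDS\t2001\t2050\t.\t-\t.\tgene_id "GM"; transcript_id "GM.t1";',
    'chr2\ttest\texon\t3001\t3030\t.\t-\t.\tgene_id "GM"; transcript_id "GM.t1";',
    'chr2\ttest\tCDS\t3001\t3030\t.\t-\t.\tgene_id "GM"; transcript_id "GM.t1";'),
    gtf)
  m <- load_gene_models(gtf, "GM")$GM
  expect_equal(m$strand, "-")
  expect_equal(m$exons$start, c(3000, 2000, 1000))  # descending = 5'->3'
  expect_equal(intron_interval(m, 1), c(2050, 3000))
})

test_that("canonical transcript selection prefers the longest CDS", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\texon\t101\t160\t.\t+\t.\tgene_id "G"; transcript_id "G.short";',
    'chr1\ttest\tCDS\t101\t160\t.\t+\t.\tgene_id "G"; transcript_id "G.short";',
    'chr1\ttest\texon\t101\t220\t.\t+\t.\tgene_id "G"; transcript_id "G.long";',
    'chr1\ttest\tCDS\t101\t220\t.\t+\t.\tgene_id "G"; transcript_id "G.long";'),
    gtf)
  expect_equal(load_gene_models(gtf, "G")$G$transcript_id, "G.long")
})

test_that("GTF round trip preserves intervals exactly", {
  path <- tempfile(fileext = ".gtf")
  write_gene_models_gtf(toy$models, path)
  reloaded <- load_gene_models(path, names(toy$models))
  for (g in names(toy$models)) {
    expect_identical(as.numeric(unlist(reloaded[[g]]$exons)),
                     as.numeric(unlist(toy$models[[g]]$exons)),
                     label = g)
    expect_equal(reloaded[[g]]$strand, toy$models[[g]]$strand)
    expect_equal(reloaded[[g]]$protein_length,
                 toy$models[[g]]$protein_length)
  }
})

test_that("phase chain and translation-oracle equivalence on random models", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  for (rep in 1:25) {
    g <- random_coding_gene("R", "chrR", 1e5)
    ph <- compute_exon_phases(g)
    # phase chain: start of exon k+1 equals end of exon k
    if (nrow(ph) > 1)
      expect_equal(ph$start_phase[-1], ph$end_phase[-nrow(ph)])
    # brute force: phases from cumulative concatenated-CDS length
    lens <- g$exons$end - g$exons$start
    expect_equal(ph$end_phase, as.integer(cumsum(lens) %% 3))
    expect_equal(sum(lens) %% 3, 0)
  }
})

test_that("breakend annotation resolves exon, intron and intergenic", {
  fgfr2 <- toy$models$FGFR2
  i17 <- intron_interval(fgfr2, 17)
  b <- annotate_breakend("chr10", i17[1] + 100, "sense", toy$models)
  expect_equal(b$context$type, "intron")
  expect_equal(b$context$gene_id, "FGFR2")
  expect_equal(b$context$index, 17L)
  e18 <- fgfr2$exons[18, ]
  b <- annotate_breakend("chr10", e18$start + 5, "sense", toy$models)
  expect_equal(b$context$type, "exon")
  expect_equal(b$context$index, 18L)
  b <- annotate_breakend("chr10", gene_span(fgfr2)[2] + 1e4, "sense",
                         toy$models)
  expect_equal(b$context$type, "intergenic")
  # half-open boundary: the first exon base is exonic, the base before is not
  b <- annotate_breakend("chr10", fgfr2$exons$start[1], "sense", toy$models)
  expect_equal(b$context$type, "exon")
})
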