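# shared toy annotation: 18-exon FGFR2-like gene plus fusion partners
toy <- make_toy_gene_fixtures(1)

# random fully coding plus-strand gene for frame-oracle checks
random_coding_gene <- function(gene_id, chrom, start, max_exons = 8,
                               exon_len = c(30, 300),
                               intron_len = c(200, 1000)) {
  k <- sample(2:max_exons, 1)
  lens <- sample(exon_len[1]:exon_len[2], k, replace = TRUE)
  lens[k] <- lens[k] - sum(lens) %% 3
  introns <- sample(intron_len[1]:intron_len[2], max(k - 1, 1),
                    replace = TRUE)
  s <- numeric(k); e <- numeric(k); pos <- start
  for (i in seq_len(k)) {
    s[i] <- pos; e[i] <- pos + lens[i]
    pos <- e[i] + if (i < k) introns[i] else 0
  }
  gene_model(gene_id, chrom, "+", data.frame(start = s, end = e),
             data.frame(exon_index = seq_len(k), start = s, end = e))
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Translation-based in-frame oracle, independent of the phase
# arithmetic in classify_re(): materialize the fused coding sequence
# with a random downstream-gene CDS and check by translation that the
# downstream gene's peptide tail survives in the fusion product.
# brk = list(type = "intron"|"exon", index, pos) on a fully coding
# plus-strand toy gene.
oracle_in_frame <- function(gene_a, gene_b, brk_a, brk_b) {
  lens_a <- gene_a$exons$end - gene_a$exons$start
  lens_b <- gene_b$exons$end - gene_b$exons$start
  upstream_len <- function(g, lens, brk) {
    if (brk$type == "intron") sum(lens[seq_len(brk$index)])
    else sum(lens[seq_len(brk$index - 1)]) +
      (brk$pos - g$exons$start[brk$index])
  }
  la <- upstream_len(gene_a, lens_a, brk_a)
  lb_pre <- upstream_len(gene_b, lens_b, brk_b)
  seq_b <- random_nt(sum(lens_b))
  fused <- paste0(random_nt(la), substring(seq_b, lb_pre + 1))
  pep_b <- as.character(Biostrings::translate(
    Biostrings::DNAString(seq_b), no.init.codon = TRUE))
  off_b <- (3 - (lb_pre %% 3)) %% 3
  tail_b <- substring(pep_b, (lb_pre + off_b) / 3 + 1)
  fused_trim <- substring(fused, 1, 3 * (nchar(fused) %/% 3))
  pep_f <- as.character(Biostrings::translate(
    Biostrings::DNAString(fused_trim), no.init.codon = TRUE))
  endsWith(pep_f, tail_b)
}

# draw a random junction on a gene: intronic or mid-exon
random_breakpoint <- function(g, exonic) {
  k <- nrow(g$exons)
  if (!exonic) {
    i <- sample(k - 1, 1)
    iv <- intron_interval(g, i)
    list(type = "intron", index = i,
         pos = sample(seq(iv[1] + 1, iv[2] - 1), 1))
  } else {
    i <- sample(k, 1)
    w <- g$exons$end[i] - g$exons$start[i]
    list(type = "exon", index = i,
         pos = g$exons$start[i] + sample(seq_len(w - 1), 1))
  }
}
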