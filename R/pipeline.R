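#' End-to-end integration of a cohort's evidence tables
#'
#' Applies breakend annotation, rearrangement classification,
#' amplification calling, mutation classification and junction-usage
#' quantification per sample, then assigns each sample its FGFR2
#' alteration category.
#'
#' @param models Named list of `GeneModel` objects.
#' @param gene_of_interest Gene anchoring the analysis.
#' @param bedpe Breakpoint-pair table (see [read_bedpe()]) or `NULL`.
#' @param seg Long segment table (`sample`, `chrom`, `start`, `end`,
#'   `value`, absolute copy number) or `NULL`.
#' @param maf Small-variant table (see [read_maf()]) or `NULL`.
#' @param junctions Junction table (`sample`, `donor`, `acceptor`,
#'   `count`) or `NULL`.
#' @param exon_expression Optional samples x exons matrix plus normals
#'   (list with `tumour`, `normal`) for E18-loss flags.
#' @param af_threshold Rearrangement allele-frequency threshold.
#' @return Named list of `SampleAlterationProfile` objects, one per
#'   sample appearing in any input.
#' @export
integrate_cohort <- function(models, gene_of_interest, bedpe = NULL,
                             seg = NULL, maf = NULL, junctions = NULL,
                             exon_expression = NULL,
                             af_threshold = 0.15) {
  goi <- models[[gene_of_interest]]
  samples <- unique(c(
    if (!is.null(bedpe)) as.character(bedpe$sample),
    if (!is.null(seg)) as.character(seg$sample),
    if (!is.null(maf)) as.character(maf$sample),
    if (!is.null(junctions)) as.character(junctions$sample)))
  normal_ref <- if (!is.null(exon_expression))
    normal_reference_e18(exon_expression$normal) else NA_real_
  profiles <- list()
  for (s in samples) {
    profile <- NULL
    amp_call <- NULL
    gene_cn <- 2
    if (!is.null(seg)) {
      ss <- seg[seg$sample == s, , drop = FALSE]
      if (nrow(ss) > 0) {
        profile <- copy_number_profile(
          s, segments = data.frame(start = ss$start, end = ss$end,
                                   cn = ss$value),
          scale = "absolute_cn")
        amp_call <- call_amp_wgs(profile, goi)
        sp <- gene_span(goi)
        gene_cn <- region_value(profile, sp[1], sp[2])
      }
    }
    re_calls <- list()
    if (!is.null(bedpe)) {
      bb <- bedpe[bedpe$sample == s, , drop = FALSE]
      for (i in seq_len(nrow(bb))) {
        r <- bb[i, ]
        b1 <- annotate_breakend(r$chrom1, r$start1,
                                bedpe_orientation(r$chrom1, r$start1,
                                                  r$strand1, models),
                                models)
        b2 <- annotate_breakend(r$chrom2, r$start2,
                                bedpe_orientation(r$chrom2, r$start2,
                                                  r$strand2, models),
                                models)
        call <- classify_re(b1, b2, models, gene_of_interest,
                            junction_ploidy = r$ploidy)
        if (!is.na(call$junction_ploidy))
          call <- compute_allele_frequency(call, gene_cn, af_threshold)
        re_calls[[length(re_calls) + 1]] <- call
      }
    }
    mutations <- list()
    if (!is.null(maf)) {
      mm <- maf[maf$sample == s, , drop = FALSE]
      for (i in seq_len(nrow(mm))) {
        r <- mm[i, ]
        hp <- if (!is.na(r$hgvs_p) && nzchar(r$hgvs_p)) r$hgvs_p else NULL
        gp <- if ("position" %in% names(mm)) r$position else NA_real_
        mutations[[length(mutations) + 1]] <-
          classify_mutation(r$gene, hgvs_p = hp,
                            consequence = r$consequence,
                            genomic_position = gp, model = goi)
      }
    }
    rna_flags <- NULL
    if (!is.null(junctions)) {
      jj <- junctions[junctions$sample == s, , drop = FALSE]
      if (nrow(jj) > 0) {
        usage <- acceptor_usage(jj)
        rna_flags <- list(usage = usage,
                          e18_truncated = call_e18_truncated_rna(usage))
      }
    }
    if (!is.null(exon_expression) &&
        s %in% rownames(exon_expression$tumour)) {
      loss <- e18_loss(exon_expression$tumour[s, ], normal_ref)
      rna_flags <- c(rna_flags, list(e18_loss = loss))
    }
    profiles[[s]] <- assign_category(s, re_calls = re_calls,
                                     amp_call = amp_call,
                                     mutations = mutations,
                                     rna_flags = rna_flags)
  }
  profiles
}
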