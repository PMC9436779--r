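#' Structural-variant classification into six rearrangement types
#'
#' Breakpoint pairs involving the gene of interest are classified into
#' six rearrangement (RE) types: `IN_FRAME_FUSION`, `FRAME_UNKNOWN`,
#' `INTERGENIC_SPACE`, `OUT_OF_STRAND`, `INTERNAL` and `UNRESOLVED`.
#' Rules are evaluated in a fixed order: unresolved (upstream side
#' antisense-supported, or single breakend), then internal (both ends
#' within the gene of interest), then intergenic partner, then
#' out-of-strand partner, and finally the reading-frame evaluation for
#' intronic/intronic and exonic/exonic junctions.
#'
#' @name sv_classifier
NULL

RE_TYPES <- c("IN_FRAME_FUSION", "FRAME_UNKNOWN", "INTERGENIC_SPACE",
              "OUT_OF_STRAND", "INTERNAL", "UNRESOLVED")

#' Select the classification backbone gene of a fusion pair
#'
#' Of the two partners, the gene encoding the longer protein anchors the
#' classification. If only one gene is coding, that one is used; equal
#' protein lengths are broken by lexicographic gene identifier.
#'
#' @param gene_a,gene_b `GeneModel` objects.
#' @return The backbone `gene_id`.
#' @export
select_backbone <- function(gene_a, gene_b) {
  if (!gene_a$coding && !gene_b$coding)
    stop("both genes non-coding: no backbone")
  if (gene_a$coding && !gene_b$coding) return(gene_a$gene_id)
  if (!gene_a$coding && gene_b$coding) return(gene_b$gene_id)
  if (gene_a$protein_length > gene_b$protein_length) return(gene_a$gene_id)
  if (gene_b$protein_length > gene_a$protein_length) return(gene_b$gene_id)
  sort(c(gene_a$gene_id, gene_b$gene_id))[1]
}

# coding-frame phase at an exonic breakpoint: start phase of the exon
# plus the number of coding bases 5' (in transcript orientation) of the
# break position, mod 3. NA if the exon carries no CDS.
exon_break_phase <- function(model, exon_index, position) {
  if (!model$coding) return(NA_integer_)
  ph <- compute_exon_phases(model)
  row <- ph[ph$exon_index == exon_index, ]
  if (nrow(row) == 0) return(NA_integer_)
  cd <- model$cds[model$cds$exon_index == exon_index, ]
  w <- sum(cd$end - cd$start)
  off <- if (model$strand == "+") {
    sum(pmin(pmax(position - cd$start, 0), cd$end - cd$start))
  } else {
    sum(pmin(pmax(cd$end - position, 0), cd$end - cd$start))
  }
  as.integer((row$start_phase + min(off, w)) %% 3)
}

# phases flanking an intronic breakpoint: end phase of the exon upstream
# of intron k, and start phase of the exon downstream of intron k
intron_flank_phases <- function(model, k) {
  ph <- compute_exon_phases(model)
  up <- ph[ph$exon_index == k, ]
  dn <- ph[ph$exon_index == k + 1, ]
  c(end_up = if (nrow(up)) up$end_phase else NA_integer_,
    start_dn = if (nrow(dn)) dn$start_phase else NA_integer_)
}

#' Classify a breakpoint pair into one of six rearrangement types
#'
#' @param bend1,bend2 `GenomicBreakend` objects (see
#'   [annotate_breakend()]); order does not matter. `bend2 = NULL`
#'   denotes a single breakend. The breakend lying in
#'   `gene_of_interest` is treated as the upstream side (the gene
#'   retains its 5' portion in the derived allele).
#' @param models Named list of `GeneModel` objects.
#' @param gene_of_interest Gene identifier anchoring the classification
#'   (the gene whose E18 truncation is being assessed).
#' @param junction_ploidy Copy number supporting the junction; carried
#'   into [compute_allele_frequency()].
#' @param frame_rule `"phase"` (default): an intronic/intronic junction
#'   is in-frame when the end phase of the upstream exon equals the
#'   start phase of the downstream exon. `"codon_complete"` additionally
#'   requires both flanking exons to end/start on codon boundaries
#'   (phase 0).
#' @return A `RearrangementCall`: list with `breakend_a` (gene of
#'   interest side), `breakend_b`, `re_type`, `backbone_gene`,
#'   `junction_ploidy`, `allele_frequency` (NA until
#'   [compute_allele_frequency()] is applied), `e18_truncating` and
#'   `a_in_i17_e18` (whether the gene-of-interest breakend lies in the
#'   terminal intron or terminal exon).
#' @export
classify_re <- function(bend1, bend2, models, gene_of_interest,
                        junction_ploidy = NA_real_,
                        frame_rule = c("phase", "codon_complete")) {
  frame_rule <- match.arg(frame_rule)
  goi <- models[[gene_of_interest]]
  if (is.null(goi)) stop(sprintf("gene not found: %s", gene_of_interest))
  in_goi <- function(b) !is.null(b) &&
    identical(b$context$gene_id, gene_of_interest)
  single <- is.null(bend2) ||
    (bend1$chromosome == bend2$chromosome &&
       bend1$position == bend2$position)
  if (single) {
    a <- if (in_goi(bend1)) bend1 else bend2
    if (is.null(a) || !in_goi(a)) a <- bend1
    return(new_re_call(a, NULL, "UNRESOLVED", NA_character_,
                       junction_ploidy, goi))
  }
  if (in_goi(bend1)) {
    a <- bend1; b <- bend2
  } else if (in_goi(bend2)) {
    a <- bend2; b <- bend1
  } else {
    stop("neither breakend lies in the gene of interest")
  }
  # rule order: UNRESOLVED -> INTERNAL -> INTERGENIC -> OUT_OF_STRAND -> frame
  if (a$read_orientation == "antisense")
    return(new_re_call(a, b, "UNRESOLVED", NA_character_,
                       junction_ploidy, goi))
  if (in_goi(b))
    return(new_re_call(a, b, "INTERNAL", gene_of_interest,
                       junction_ploidy, goi))
  if (b$context$type == "intergenic")
    return(new_re_call(a, b, "INTERGENIC_SPACE", gene_of_interest,
                       junction_ploidy, goi))
  partner <- models[[b$context$gene_id]]
  backbone <- tryCatch(select_backbone(goi, partner),
                       error = function(e) gene_of_interest)
  if (b$read_orientation == "antisense")
    return(new_re_call(a, b, "OUT_OF_STRAND", backbone,
                       junction_ploidy, goi))
  re_type <- "FRAME_UNKNOWN"
  if (!is.null(partner) && partner$coding && goi$coding) {
    if (a$context$type == "intron" && b$context$type == "intron") {
      pa <- intron_flank_phases(goi, a$context$index)
      if (b$context$index <= n_exons(partner) - 1) {
        pb <- intron_flank_phases(partner, b$context$index)
        ok <- !is.na(pa["end_up"]) && !is.na(pb["start_dn"]) &&
          pa["end_up"] == pb["start_dn"]
        if (frame_rule == "codon_complete")
          ok <- ok && pa["end_up"] == 0L
        if (ok) re_type <- "IN_FRAME_FUSION"
      }
    } else if (a$context$type == "exon" && b$context$type == "exon") {
      fa <- exon_break_phase(goi, a$context$index, a$position)
      fb <- exon_break_phase(partner, b$context$index, b$position)
      if (!is.na(fa) && !is.na(fb) && fa == fb)
        re_type <- "IN_FRAME_FUSION"
    }
  }
  new_re_call(a, b, re_type, backbone, junction_ploidy, goi)
}

new_re_call <- function(a, b, re_type, backbone, junction_ploidy, goi) {
  stopifnot(re_type %in% RE_TYPES)
  last_exon <- n_exons(goi)
  a_term <- identical(a$context$gene_id, goi$gene_id) &&
    ((a$context$type == "intron" && a$context$index == last_exon - 1L) ||
       (a$context$type == "exon" && a$context$index == last_exon))
  structure(list(breakend_a = a, breakend_b = b, re_type = re_type,
                 backbone_gene = backbone,
                 junction_ploidy = junction_ploidy,
                 allele_frequency = NA_real_, e18_truncating = FALSE,
                 a_in_i17_e18 = a_term),
            class = "RearrangementCall")
}

#' @export
print.RearrangementCall <- function(x, ...) {
  cat(sprintf("RearrangementCall %s backbone=%s AF=%s E18-truncating=%s\n",
              x$re_type, x$backbone_gene,
              format(x$allele_frequency), x$e18_truncating))
  invisible(x)
}

#' Rearrangement allele frequency and the E18-truncation threshold
#'
#' The allele frequency of a rearrangement is its junction ploidy
#' divided by the total gene copy number at the upstream breakend,
#' clamped to \[0, 1\]. A rearrangement is E18-truncating when its
#' gene-of-interest breakend lies in the terminal intron (I17) or
#' terminal exon (E18), the allele frequency exceeds the threshold
#' (strictly > 0.15) and the call is not `UNRESOLVED`.
#'
#' @param call A `RearrangementCall`.
#' @param gene_cn Total gene copy number (> 0).
#' @param threshold Allele-frequency threshold, default 0.15.
#' @return The call with `allele_frequency` and `e18_truncating` set.
#' @export
compute_allele_frequency <- function(call, gene_cn, threshold = 0.15) {
  if (!is.finite(gene_cn) || gene_cn <= 0)
    stop("gene copy number must be positive")
  af <- min(max(call$junction_ploidy / gene_cn, 0), 1)
  call$allele_frequency <- af
  call$e18_truncating <- isTRUE(call$a_in_i17_e18) &&
    call$re_type != "UNRESOLVED" && af > threshold
  call
}

#' Normalize transposon-insertion ligation scores to relative clonality
#'
#' Each unique ligation score in a tumour sample is divided by the
#' sample's maximum score, yielding relative clonalities between 0 (no
#' insertion) and 1 (fully clonal insertion).
#'
#' @param ligation_scores Non-negative numeric vector with at least one
#'   positive value.
#' @return Numeric vector of relative clonalities in \[0, 1\].
#' @seealso [sb_insertion_hit()] for the gene-level call.
#' @export
normalize_clonality <- function(ligation_scores) {
  stopifnot(is.numeric(ligation_scores), length(ligation_scores) > 0,
            all(ligation_scores >= 0))
  mx <- max(ligation_scores)
  if (mx <= 0) stop("all ligation scores are zero")
  ligation_scores / mx
}

#' Gene-level insertion call from relative clonalities
#'
#' A gene is called as hit when any insertion reaches a relative
#' clonality of at least 0.25 (boundary included).
#'
#' @param relative_clonality Numeric vector in \[0, 1\].
#' @param threshold Clonality threshold, default 0.25.
#' @return Logical vector of per-insertion hit flags.
#' @export
sb_insertion_hit <- function(relative_clonality, threshold = 0.25) {
  relative_clonality >= threshold
}

#' Sliding-window density of genomic positions
#'
#' Counts, for each 1-bp step of the track, the positions falling in a
#' centred window of `window` bp (half-open: `[x - w/2, x + w/2)` for
#' even `w`), so that windows whose centres are `window` bp apart tile
#' the genome and conserve the total count.
#'
#' @param positions Integer genomic coordinates (may be empty).
#' @param window Window size in bp (default 500).
#' @param from,to Track range; defaults to the span of `positions`
#'   padded by half a window.
#' @return `data.frame` with columns `pos` and `count`.
#' @export
sliding_window_density <- function(positions, window = 500,
                                   from = NULL, to = NULL) {
  stopifnot(window >= 1)
  half <- window %/% 2
  if (length(positions) == 0) {
    if (is.null(from) || is.null(to))
      return(data.frame(pos = integer(), count = integer()))
    pos <- seq.int(from, to)
    return(data.frame(pos = pos, count = integer(length(pos))))
  }
  sp <- sort(as.numeric(positions))
  if (is.null(from)) from <- min(sp) - half
  if (is.null(to)) to <- max(sp) + half
  pos <- seq.int(from, to)
  # positions in [x - half, x - half + window - 1]
  lo <- pos - half
  hi <- lo + window - 1
  count <- findInterval(hi, sp) - findInterval(lo - 1, sp)
  data.frame(pos = pos, count = as.integer(count))
}

#' Classify a table of breakpoint pairs
#'
#' Convenience wrapper applying [annotate_breakend()],
#' [classify_re()] and [compute_allele_frequency()] to each row of a
#' BEDPE-style table (see [read_bedpe()]).
#'
#' @param bedpe `data.frame` with columns `chrom1`, `start1`, `chrom2`,
#'   `start2`, `strand1`, `strand2`, `sample`, `ploidy` (junction
#'   ploidy).
#' @param models Named list of `GeneModel` objects.
#' @param gene_of_interest Gene anchoring classification.
#' @param gene_cn Gene copy number: single value or named vector by
#'   sample.
#' @param threshold Allele-frequency threshold (default 0.15).
#' @return `data.frame` with one row per junction: `sample`, `re_type`,
#'   `backbone_gene`, `allele_frequency`, `e18_truncating`.
#' @export
classify_sv_table <- function(bedpe, models, gene_of_interest,
                              gene_cn = 2, threshold = 0.15) {
  res <- vector("list", nrow(bedpe))
  for (i in seq_len(nrow(bedpe))) {
    r <- bedpe[i, ]
    b1 <- annotate_breakend(r$chrom1, r$start1,
                            bedpe_orientation(r$chrom1, r$start1,
                                              r$strand1, models), models)
    b2 <- annotate_breakend(r$chrom2, r$start2,
                            bedpe_orientation(r$chrom2, r$start2,
                                              r$strand2, models), models)
    call <- classify_re(b1, b2, models, gene_of_interest,
                        junction_ploidy = r$ploidy)
    cn <- if (length(gene_cn) == 1 && is.null(names(gene_cn))) gene_cn
          else gene_cn[[as.character(r$sample)]]
    if (!is.na(call$junction_ploidy))
      call <- compute_allele_frequency(call, cn, threshold)
    res[[i]] <- data.frame(sample = r$sample, re_type = call$re_type,
                           backbone_gene = call$backbone_gene,
                           allele_frequency = call$allele_frequency,
                           e18_truncating = call$e18_truncating)
  }
  do.call(rbind, res)
}

# BEDPE strand columns give read orientation on the reference; relative
# sense/antisense is resolved against the strand of the annotated gene
# (reference "+" for intergenic breakends).
bedpe_orientation <- function(chrom, position, strand, models) {
  ref <- "+"
  for (m in models) {
    if (m$chromosome != chrom) next
    sp <- gene_span(m)
    if (position >= sp[1] && position < sp[2]) {
      ref <- m$strand
      break
    }
  }
  if (strand == ref) "sense" else "antisense"
}

#' Read breakpoint pairs from a BEDPE file
#'
#' Expects at least 10 tab-separated columns (chrom1, start1, end1,
#' chrom2, start2, end2, name, score, strand1, strand2), optionally
#' followed by `sample` and `ploidy`. BEDPE coordinates are 0-based and
#' are kept as such.
#'
#' @param path Path to a BEDPE file (no header).
#' @return `data.frame` with named columns.
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2")
  extra <- c("sample", "ploidy")
  names(df) <- c(base, extra[seq_len(ncol(df) - 10)])
  df
}
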