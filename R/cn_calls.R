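#' Copy-number profiles and amplification calling
#'
#' Four rule sets are implemented for calling full-length and E1-E17
#' partial amplifications of the gene of interest, matching the
#' conventions of whole-genome sequencing (absolute copy number),
#' GISTIC-style log2 ratios, cell-line log2 ratios, and per-exon-target
#' diagnostic panels.
#'
#' @name cn_caller
NULL

AMP_STATUS <- c("NONE", "FULL_LENGTH_AMP", "PARTIAL_AMP_E1_E17")

#' Construct a copy-number profile for one sample
#'
#' @param sample_id Sample identifier.
#' @param segments Optional `data.frame` with columns `start`, `end`
#'   (0-based half-open) and `cn` (segment value on `scale`); segments
#'   must not overlap.
#' @param exon_target_cn Optional numeric vector of per-exon-target copy
#'   numbers (E1..En, transcript order) for panel-style calling.
#' @param median_ploidy Sample median ploidy (> 0).
#' @param scale `"absolute_cn"` or `"log2_ratio"`; declared explicitly
#'   because the calling thresholds differ between scales.
#' @return An object of class `CopyNumberProfile`.
#' @export
copy_number_profile <- function(sample_id, segments = NULL,
                                exon_target_cn = NULL, median_ploidy = 2,
                                scale = c("absolute_cn", "log2_ratio")) {
  scale <- match.arg(scale)
  stopifnot(median_ploidy > 0)
  if (!is.null(segments)) {
    stopifnot(all(c("start", "end", "cn") %in% names(segments)))
    segments <- segments[order(segments$start), , drop = FALSE]
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)]))
      stop("overlapping segments")
  }
  structure(list(sample_id = sample_id, segments = segments,
                 exon_target_cn = exon_target_cn,
                 median_ploidy = median_ploidy, scale = scale),
            class = "CopyNumberProfile")
}

# length-weighted mean segment value over a genomic interval [lo, hi)
region_value <- function(profile, lo, hi) {
  s <- profile$segments
  if (is.null(s)) stop("profile has no segments")
  ov_lo <- pmax(s$start, lo)
  ov_hi <- pmin(s$end, hi)
  w <- pmax(ov_hi - ov_lo, 0)
  if (sum(w) == 0) return(NA_real_)
  sum(s$cn * w) / sum(w)
}

# genomic interval spanned by exons e_from..e_to (transcript order)
exon_block_span <- function(model, e_from, e_to) {
  ex <- model$exons[e_from:e_to, ]
  c(min(ex$start), max(ex$end))
}

#' Length-weighted copy number over the E1-E17 block and over E18
#'
#' @param profile A `CopyNumberProfile` with segments.
#' @param model The gene-of-interest `GeneModel`.
#' @return Named numeric `c(cn_e1_e17, cn_e18)`.
#' @export
exon_block_cn <- function(profile, model) {
  n <- n_exons(model)
  b17 <- exon_block_span(model, 1, n - 1)
  b18 <- exon_block_span(model, n, n)
  c(cn_e1_e17 = region_value(profile, b17[1], b17[2]),
    cn_e18 = region_value(profile, b18[1], b18[2]))
}

#' Does a segment boundary fall inside the terminal intron (I17)?
#'
#' Boundaries within `tol` bp of the intron bounds are accepted, to
#' guard against off-by-one differences between coordinate dialects.
#'
#' @param profile A `CopyNumberProfile` with segments.
#' @param model The gene-of-interest `GeneModel`.
#' @param tol Tolerance in bp (default 1).
#' @return Logical.
#' @export
segment_break_in_i17 <- function(profile, model, tol = 1) {
  iv <- intron_interval(model, n_exons(model) - 1)
  b <- unique(c(profile$segments$start, profile$segments$end))
  # exclude boundaries that are the outer ends of the covered region
  inner <- setdiff(b, c(min(profile$segments$start),
                        max(profile$segments$end)))
  any(inner >= iv[1] - tol & inner <= iv[2] + tol)
}

new_amp_call <- function(status, rule_set, cn_e1_e17 = NA_real_,
                         cn_e18 = NA_real_) {
  stopifnot(status %in% AMP_STATUS)
  structure(list(status = status, rule_set = rule_set,
                 cn_e1_e17 = cn_e1_e17, cn_e18 = cn_e18),
            class = "AmplificationCall")
}

#' @export
print.AmplificationCall <- function(x, ...) {
  cat(sprintf("AmplificationCall [%s] %s (E1-E17 %.2f, E18 %.2f)\n",
              x$rule_set, x$status, x$cn_e1_e17, x$cn_e18))
  invisible(x)
}

#' Amplification calling on absolute copy number (WGS rule set)
#'
#' Copy-number gains strictly greater than 5 are amplifications. A
#' sample is E1-E17 partially amplified when a segment boundary falls in
#' I17, CN(E1-E17) > 5 and CN(E1-E17) - CN(E18) > 2.
#'
#' @param profile A `CopyNumberProfile` on the `absolute_cn` scale.
#' @param model The gene-of-interest `GeneModel`.
#' @return An `AmplificationCall`.
#' @export
call_amp_wgs <- function(profile, model) {
  if (profile$scale != "absolute_cn")
    stop("WGS rule set requires absolute copy number")
  v <- exon_block_cn(profile, model)
  if (segment_break_in_i17(profile, model) &&
      v["cn_e1_e17"] > 5 && (v["cn_e1_e17"] - v["cn_e18"]) > 2)
    return(new_amp_call("PARTIAL_AMP_E1_E17", "WGS",
                        v["cn_e1_e17"], v["cn_e18"]))
  sp <- gene_span(model)
  gene_cn <- region_value(profile, sp[1], sp[2])
  if (gene_cn > 5)
    return(new_amp_call("FULL_LENGTH_AMP", "WGS",
                        v["cn_e1_e17"], v["cn_e18"]))
  new_amp_call("NONE", "WGS", v["cn_e1_e17"], v["cn_e18"])
}

#' Amplification calling on log2(CN/2) segment values (GISTIC-style)
#'
#' Segment values strictly greater than 0.3 (the typical GISTIC
#' amplification threshold) are amplifications; partial amplification
#' requires an I17 segment boundary, value(E1-E17) > 0.3 and
#' value(E1-E17) - value(E18) > 0.3.
#'
#' @inheritParams call_amp_wgs
#' @param profile A `CopyNumberProfile` on the `log2_ratio` scale.
#' @return An `AmplificationCall`.
#' @export
call_amp_tcga <- function(profile, model) {
  if (profile$scale != "log2_ratio")
    stop("TCGA rule set requires log2-ratio segment values")
  v <- exon_block_cn(profile, model)
  if (segment_break_in_i17(profile, model) &&
      v["cn_e1_e17"] > 0.3 && (v["cn_e1_e17"] - v["cn_e18"]) > 0.3)
    return(new_amp_call("PARTIAL_AMP_E1_E17", "TCGA",
                        v["cn_e1_e17"], v["cn_e18"]))
  sp <- gene_span(model)
  gene_v <- region_value(profile, sp[1], sp[2])
  if (gene_v > 0.3)
    return(new_amp_call("FULL_LENGTH_AMP", "TCGA",
                        v["cn_e1_e17"], v["cn_e18"]))
  new_amp_call("NONE", "TCGA", v["cn_e1_e17"], v["cn_e18"])
}

#' Amplification calling on cell-line log2(CN/2) values
#'
#' A gene-level log2(CN/2) of at least 2 (boundary included) is an
#' amplification.
#'
#' @param log2_ratio Gene-level log2(CN/2) value(s).
#' @return Logical vector.
#' @export
call_amp_ccle <- function(log2_ratio) {
  log2_ratio >= 2
}

#' Amplification calling on per-exon panel targets (panel rule set)
#'
#' The amplification threshold is 4 plus the sample's median ploidy. A
#' full-length amplification requires at least 80% of all exon targets
#' at or above the threshold. A partial E1-E17 amplification requires at
#' least 80% of the E1-E17 targets at or above the threshold while the
#' E18 target stays below it (minus `e18_margin`).
#'
#' @param exon_target_cn Numeric vector of per-exon-target copy numbers,
#'   transcript order, terminal exon last.
#' @param median_ploidy Sample median ploidy (> 0).
#' @param e18_margin Extra copy-number margin the E18 target must fall
#'   below the threshold by for a partial call (default 0).
#' @return An `AmplificationCall` with `rule_set = "PANEL"`.
#' @export
call_amp_panel <- function(exon_target_cn, median_ploidy, e18_margin = 0) {
  if (is.null(exon_target_cn) || length(exon_target_cn) < 2)
    stop("per-exon target copy numbers required")
  stopifnot(median_ploidy > 0)
  thr <- 4 + median_ploidy
  n <- length(exon_target_cn)
  e17 <- exon_target_cn[-n]
  e18 <- exon_target_cn[n]
  cn_e1_e17 <- mean(e17)
  if (mean(e17 >= thr) >= 0.8 && e18 < thr - e18_margin)
    return(new_amp_call("PARTIAL_AMP_E1_E17", "PANEL", cn_e1_e17, e18))
  if (mean(exon_target_cn >= thr) >= 0.8)
    return(new_amp_call("FULL_LENGTH_AMP", "PANEL", cn_e1_e17, e18))
  new_amp_call("NONE", "PANEL", cn_e1_e17, e18)
}

#' Read SEG-like copy-number tables
#'
#' Tab-separated with header columns `sample`, `chrom`, `start`, `end`,
#' `value` (start/end 0-based half-open).
#'
#' @param path Path to the TSV file.
#' @return `data.frame`.
#' @export
read_seg <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
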