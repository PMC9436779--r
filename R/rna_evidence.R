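#' RNA-level evidence of E18 truncation
#'
#' Junction-based quantification of alternative last-exon usage,
#' chimeric-read filtering, E18 expression loss, transposon splice
#' ratios, and composite FGFR expression.
#'
#' @name rna_evidence
NULL

#' Classify a junction acceptor label
#'
#' Labels `"E18-C1"`..`"E18-C4"` are the alternative terminal exons;
#' `"SB"` is a transposon splice acceptor; labels starting with
#' `"IGR"` are intergenic pseudo-exons; anything else is a partner-gene
#' acceptor (optionally written `"partner:GENE"`).
#'
#' @param label Character vector of acceptor labels.
#' @return Character vector with classes `"C1"`..`"C4"`, `"SB"`,
#'   `"IGR"`, `"partner"`.
#' @export
acceptor_class <- function(label) {
  vapply(label, function(x) {
    if (grepl("^E18-C[1-4]$", x)) sub("^E18-", "", x)
    else if (x == "SB") "SB"
    else if (grepl("^IGR", x)) "IGR"
    else "partner"
  }, character(1), USE.NAMES = FALSE)
}

#' Per-acceptor junction usage from a donor exon
#'
#' Each acceptor's unique junction read count is divided by the total
#' junction reads leaving the donor. With zero total reads the usage is
#' undefined and `NA` fractions are returned (never 0).
#'
#' @param junctions `data.frame` with columns `donor`, `acceptor`,
#'   `count` (unique junction read counts).
#' @param donor Donor exon label (default `"E17"`).
#' @return Named numeric vector of fractions summing to 1 over the
#'   observed acceptors, or NA-valued if the donor has no reads.
#' @export
acceptor_usage <- function(junctions, donor = "E17") {
  j <- junctions[junctions$donor == donor, , drop = FALSE]
  if (any(j$count < 0) || any(j$count != round(j$count)))
    stop("junction counts must be non-negative integers")
  if (anyDuplicated(j$acceptor)) stop("duplicate acceptor for donor")
  total <- sum(j$count)
  if (nrow(j) == 0 || total == 0) {
    out <- rep(NA_real_, nrow(j))
    names(out) <- j$acceptor
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- j$count / total
  names(out) <- j$acceptor
  attr(out, "undefined") <- FALSE
  out
}

#' RNA-level E18-truncation call from junction usage
#'
#' A sample expresses an E18-truncated transcript when the summed
#' donor-junction usage of the rearrangement-type acceptors exceeds the
#' threshold (strictly > 0.15 of E17 junction reads). By default only
#' rearrangement acceptors (partner genes, intergenic pseudo-exons, and
#' transposon acceptors) count as evidence; the alternative terminal
#' exons C3/C4 can be added via `evidence_classes`. C2 is treated as
#' full-length-like and never counts.
#'
#' @param usage Named fractions from [acceptor_usage()].
#' @param threshold Usage threshold (default 0.15, strict).
#' @param evidence_classes Acceptor classes counting as truncation
#'   evidence (subset of `"partner"`, `"IGR"`, `"SB"`, `"C3"`, `"C4"`).
#' @return Logical, or `NA` if the usage is undefined.
#' @export
call_e18_truncated_rna <- function(usage, threshold = 0.15,
                                   evidence_classes =
                                     c("partner", "IGR", "SB")) {
  stopifnot(all(evidence_classes %in%
                  c("partner", "IGR", "SB", "C3", "C4")))
  if (isTRUE(attr(usage, "undefined"))) return(NA)
  cls <- acceptor_class(names(usage))
  sum(usage[cls %in% evidence_classes]) > threshold
}

#' Filter chimeric reads and keep recurrently supported breakpoints
#'
#' Reads with multiple chimeric alignments, PCR-duplicate flags, or
#' partners mapping to mitochondrial, immunoglobulin or HLA loci are
#' discarded; breakpoints are kept when the surviving read count is
#' strictly greater than `min_count - 1` (default: spanning read count
#' > 2).
#'
#' @param reads `data.frame` with columns `breakpoint` (identifier),
#'   `alignment_count`, `duplicate_flag`, `partner_class`.
#' @param min_count Minimum surviving read count (default 3, i.e.
#'   strictly more than 2 reads).
#' @return `data.frame` of surviving breakpoints with their read counts.
#' @export
filter_chimeric_reads <- function(reads, min_count = 3) {
  if (nrow(reads) == 0)
    return(data.frame(breakpoint = character(), count = integer()))
  stopifnot(all(reads$alignment_count >= 1))
  keep <- reads$alignment_count == 1 & !reads$duplicate_flag &
    !(reads$partner_class %in% c("mitochondrial", "immunoglobulin",
                                 "HLA"))
  surv <- reads[keep, , drop = FALSE]
  if (nrow(surv) == 0)
    return(data.frame(breakpoint = character(), count = integer()))
  tab <- table(surv$breakpoint)
  tab <- tab[tab >= min_count]
  data.frame(breakpoint = names(tab), count = as.integer(tab),
             row.names = NULL)
}

#' E18 expression loss relative to normal tissue
#'
#' E18 expression is normalized to the median expression of E1-E17;
#' the sample shows E18 loss when this normalized value falls below the
#' minimum normalized E18 expression observed across normal samples.
#'
#' @param exon_expression Numeric vector of per-exon expression values
#'   named `E1`..`En` (terminal exon last), or unnamed in transcript
#'   order.
#' @param normal_reference Minimum normalized E18 value over normal
#'   samples (see [normal_reference_e18()]).
#' @return Logical.
#' @export
e18_loss <- function(exon_expression, normal_reference) {
  if (is.na(normal_reference)) stop("at least one normal sample required")
  n <- length(exon_expression)
  med <- stats::median(exon_expression[-n])
  if (med <= 0) stop("median E1-E17 expression must be positive")
  (exon_expression[[n]] / med) < normal_reference
}

#' Minimum normalized E18 expression across normal samples
#'
#' @param normal_matrix Samples x exons matrix of expression values for
#'   normal-tissue samples (terminal exon in the last column).
#' @return The minimum over normals of E18 / median(E1..E17).
#' @export
normal_reference_e18 <- function(normal_matrix) {
  if (is.null(dim(normal_matrix)) || nrow(normal_matrix) < 1)
    stop("at least one normal sample required")
  n <- ncol(normal_matrix)
  min(apply(normal_matrix, 1, function(x) {
    x[n] / stats::median(x[-n])
  }))
}

#' Transposon splice ratio at the E17 donor
#'
#' Quantifies usage of an intron-17-inserted transposon as splice
#' acceptor: the ratio of E17->transposon to E17->E18 spanning reads,
#' and the transposon fraction of the two.
#'
#' @param e17_to_sb,e17_to_e18 Unique junction read counts.
#' @return List with `ratio` (`Inf` when no E17->E18 reads remain) and
#'   `fraction` = SB / (SB + E18).
#' @export
sb_splice_ratio <- function(e17_to_sb, e17_to_e18) {
  stopifnot(e17_to_sb >= 0, e17_to_e18 >= 0)
  total <- e17_to_sb + e17_to_e18
  if (total == 0) stop("no junction reads at the E17 donor")
  list(ratio = if (e17_to_e18 == 0) Inf else e17_to_sb / e17_to_e18,
       fraction = e17_to_sb / total)
}

#' Composite FGFR expression score
#'
#' Each receptor's expression is normalized by its geometric mean
#' across all samples (after replacing zeros by a pseudocount) and the
#' normalized values are summed per sample. A score strictly greater
#' than `threshold` (default 3) flags the sample as FGFR-high.
#'
#' @param expr Samples x receptors matrix (columns FGFR1..FGFR4),
#'   linear-scale non-negative expression.
#' @param pseudocount Value substituted for zeros before taking logs
#'   (default 0.01).
#' @param threshold High-expression threshold on the composite score.
#' @return `data.frame` with `sample`, `score`, `high`.
#' @export
composite_fgfr_expression <- function(expr, pseudocount = 0.01,
                                      threshold = 3) {
  if (is.null(dim(expr)) || nrow(expr) < 2)
    stop("composite expression requires at least two samples")
  if (any(expr < 0)) stop("expression values must be non-negative")
  x <- as.matrix(expr)
  x[x == 0] <- pseudocount
  gm <- exp(colMeans(log(x)))
  score <- rowSums(sweep(x, 2, gm, "/"))
  data.frame(sample = if (!is.null(rownames(x))) rownames(x)
             else as.character(seq_len(nrow(x))),
             score = as.numeric(score), high = as.numeric(score) > threshold,
             row.names = NULL)
}

#' Outlier flags from Z-score normalization of usage ratios
#'
#' Usage values are standardized across the cohort; samples whose
#' one-sided upper-tail normal p value falls below `alpha` (default
#' 0.01) are flagged as high-usage outliers.
#'
#' @param usage Numeric vector of usage ratios across the cohort
#'   (NA allowed; at least 3 defined values required).
#' @param alpha One-sided significance level (default 0.01).
#' @return Logical vector of flags (NA where usage was NA).
#' @export
usage_outlier_z <- function(usage, alpha = 0.01) {
  ok <- !is.na(usage)
  if (sum(ok) < 3) stop("cohort of at least 3 defined usages required")
  mu <- mean(usage[ok])
  sdev <- stats::sd(usage[ok])
  flags <- rep(NA, length(usage))
  if (sdev == 0) {
    warning("constant usage vector: no outliers can be flagged")
    flags[ok] <- FALSE
    return(flags)
  }
  z <- (usage - mu) / sdev
  flags[ok] <- stats::pnorm(z[ok], lower.tail = FALSE) < alpha
  flags
}

#' Fusion-call quality filter for cell-line fusion tables
#'
#' A fusion record is kept only when FFPM > 0.1, spanning fragment
#' count >= 5 and partner expression RPKM >= 1.
#'
#' @param ffpm Fusion fragments per million.
#' @param spanning_fragments Spanning fragment count.
#' @param rpkm Expression RPKM.
#' @return Logical vector.
#' @export
ccle_fusion_filter <- function(ffpm, spanning_fragments, rpkm) {
  ffpm > 0.1 & spanning_fragments >= 5 & rpkm >= 1
}

#' Read a STAR SJ.out.tab-style junction file and label FGFR2 junctions
#'
#' The SJ dialect has columns chrom, intron start (1-based), intron end,
#' strand code (0 undefined, 1 `+`, 2 `-`), motif, annotated flag,
#' unique reads, multimapping reads, max overhang. Junctions whose
#' intron starts at the donor exon's 3' end are assigned to that donor;
#' acceptors are labelled by matching the intron end against `acceptors`
#' (falling back to the partner gene containing the acceptor position,
#' or an intergenic label).
#'
#' @param path SJ.out.tab-style TSV (no header).
#' @param model Gene-of-interest `GeneModel`.
#' @param models Named list of all gene models (for partner labelling).
#' @param acceptors Optional `data.frame` with columns `label`, `chrom`,
#'   `pos` (0-based first base of the acceptor exon) for named
#'   acceptors such as `E18-C3`.
#' @param donor_exon Donor exon index (default: second-to-last exon,
#'   E17).
#' @return `data.frame` with columns `donor`, `acceptor`, `count`.
#' @export
read_star_sj <- function(path, model, models = list(), acceptors = NULL,
                         donor_exon = NULL) {
  sj <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(sj) <- c("chrom", "start", "end", "strand", "motif",
                 "annotated", "unique_reads", "multi_reads", "overhang")
  if (is.null(donor_exon)) donor_exon <- n_exons(model) - 1L
  ex <- model$exons[donor_exon, ]
  # intron start (1-based) follows the donor exon 3' end
  if (model$strand == "+") {
    hit <- sj$chrom == model$chromosome & (sj$start - 1L) == ex$end
    acc_pos <- sj$end  # 1-based last intronic base; acceptor base follows
  } else {
    hit <- sj$chrom == model$chromosome & sj$end == ex$start
    acc_pos <- sj$start - 2L  # 0-based base preceding the intron
  }
  sj <- sj[hit, , drop = FALSE]
  acc_pos <- acc_pos[hit]
  label <- character(nrow(sj))
  for (i in seq_len(nrow(sj))) {
    p0 <- if (model$strand == "+") acc_pos[i] else acc_pos[i]
    lab <- NA_character_
    if (!is.null(acceptors)) {
      m <- acceptors[acceptors$chrom == sj$chrom[i] &
                       acceptors$pos == p0, ]
      if (nrow(m) == 1) lab <- m$label
    }
    if (is.na(lab)) {
      b <- annotate_breakend(sj$chrom[i], p0, "sense", models)
      lab <- if (identical(b$context$gene_id, model$gene_id)) {
        if (b$context$index == n_exons(model)) "E18-C1" else "internal"
      } else if (b$context$type == "intergenic") {
        "IGR"
      } else {
        b$context$gene_id
      }
    }
    label[i] <- lab
  }
  data.frame(donor = rep(paste0("E", donor_exon), nrow(sj)),
             acceptor = label, count = sj$unique_reads)
}
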