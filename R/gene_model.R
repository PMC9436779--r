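#' Gene models with exon/CDS structure and reading-frame arithmetic
#'
#' A `GeneModel` stores the exon and CDS structure of one canonical
#' transcript of a gene, in transcript order (5' to 3' on the coding
#' strand), using 0-based half-open genomic coordinates internally.
#' All reading-frame arithmetic used by the rearrangement classifier is
#' length-based: no genome sequence is required.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (0-based
#'   half-open), one row per exon in transcript order. For minus-strand
#'   genes transcript order means descending genomic coordinates.
#' @param cds Optional `data.frame` with columns `exon_index`, `start`,
#'   `end` giving the coding part of each coding exon, transcript order.
#' @param transcript_id Transcript the model was built from.
#'
#' @return An object of class `GeneModel` with fields `gene_id`,
#'   `chromosome`, `strand`, `exons`, `cds`, `coding`, `protein_length`
#'   (amino acids, stop codon excluded) and `transcript_id`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds = NULL,
                       transcript_id = paste0(gene_id, ".t1")) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[, c("start", "end")]
  if (any(exons$end <= exons$start)) stop("empty exon interval")
  ord <- order(exons$start)
  if (any(exons$start[ord][-1] < exons$end[ord][-nrow(exons)]))
    stop("overlapping exons")
  # enforce transcript order
  expected <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(expected, seq_len(nrow(exons))))
    stop("exons must be given in transcript order")
  coding <- !is.null(cds) && nrow(cds) > 0
  protein_length <- 0L
  if (coding) {
    stopifnot(all(c("exon_index", "start", "end") %in% names(cds)))
    cds <- cds[, c("exon_index", "start", "end")]
    for (i in seq_len(nrow(cds))) {
      e <- exons[cds$exon_index[i], ]
      if (cds$start[i] < e$start || cds$end[i] > e$end)
        stop("CDS interval not contained in its exon")
    }
    total <- sum(cds$end - cds$start)
    if (total %% 3L != 0L)
      stop("total CDS length not divisible by 3")
    protein_length <- as.integer(total / 3L - 1L)  # stop codon included
  }
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 strand = strand, exons = exons, cds = cds,
                 coding = coding, protein_length = protein_length,
                 transcript_id = transcript_id),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s) %d exons, %s, protein %d aa\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$exons),
              if (x$coding) "coding" else "non-coding", x$protein_length))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

#' Genomic span of a gene model (0-based half-open)
#' @param model A `GeneModel`.
#' @return Numeric `c(start, end)`.
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Genomic interval of intron `k` (between exons k and k+1, transcript order)
#' @param model A `GeneModel`.
#' @param k 1-based intron index in transcript order, so intron 17 lies
#'   between exons 17 and 18.
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
intron_interval <- function(model, k) {
  stopifnot(k >= 1, k <= n_exons(model) - 1)
  if (model$strand == "+") {
    c(model$exons$end[k], model$exons$start[k + 1])
  } else {
    c(model$exons$end[k + 1], model$exons$start[k])
  }
}

coding_length_per_exon <- function(model) {
  len <- numeric(n_exons(model))
  if (model$coding) {
    w <- model$cds$end - model$cds$start
    for (i in seq_along(w)) {
      len[model$cds$exon_index[i]] <- len[model$cds$exon_index[i]] + w[i]
    }
  }
  len
}

#' Compute per-exon coding phases
#'
#' The phase of an exon boundary is the position within a codon (0, 1 or
#' 2) at which the exon starts or ends. Phases are computed by cumulative
#' coding length modulo 3; the first coding exon starts at phase 0.
#' Splice-phase compatibility across a fusion junction (end phase of the
#' upstream exon equal to start phase of the downstream exon) is the
#' in-frame criterion used by [classify_re()].
#'
#' @param model A coding `GeneModel`.
#' @return `data.frame` with columns `exon_index`, `start_phase`,
#'   `end_phase`, one row per coding exon in transcript order.
#' @export
compute_exon_phases <- function(model) {
  if (!model$coding) stop("non-coding model: phases undefined")
  len <- coding_length_per_exon(model)
  idx <- which(len > 0)
  cum <- cumsum(len[idx])
  data.frame(exon_index = idx,
             start_phase = as.integer((cum - len[idx]) %% 3),
             end_phase   = as.integer(cum %% 3))
}

#' Annotate a genomic breakend against a set of gene models
#'
#' Total function: a position inside a gene but outside its exons is
#' assigned to the intron with the correct transcript-order index; a
#' position covered by no gene span is intergenic.
#'
#' @param chromosome Chromosome of the breakend.
#' @param position 0-based genomic position.
#' @param read_orientation `"sense"` or `"antisense"`: orientation of the
#'   supporting read sequence relative to the annotated gene's coding
#'   strand.
#' @param models List of `GeneModel` objects.
#' @return A `GenomicBreakend`: list with `chromosome`, `position`,
#'   `read_orientation` and `context` (list with `type` one of
#'   `"exon"`, `"intron"`, `"intergenic"`, plus `gene_id` and 1-based
#'   `index` for genic contexts).
#' @export
annotate_breakend <- function(chromosome, position,
                              read_orientation = "sense", models) {
  stopifnot(read_orientation %in% c("sense", "antisense"))
  context <- list(type = "intergenic", gene_id = NA_character_,
                  index = NA_integer_)
  for (m in models) {
    if (m$chromosome != chromosome) next
    sp <- gene_span(m)
    if (position < sp[1] || position >= sp[2]) next
    hit <- which(position >= m$exons$start & position < m$exons$end)
    if (length(hit) == 1) {
      context <- list(type = "exon", gene_id = m$gene_id,
                      index = as.integer(hit))
    } else {
      for (k in seq_len(n_exons(m) - 1)) {
        iv <- intron_interval(m, k)
        if (position >= iv[1] && position < iv[2]) {
          context <- list(type = "intron", gene_id = m$gene_id,
                          index = as.integer(k))
          break
        }
      }
    }
    break
  }
  structure(list(chromosome = chromosome, position = position,
                 read_orientation = read_orientation, context = context),
            class = "GenomicBreakend")
}

#' Load canonical gene models from a GTF/GFF annotation
#'
#' One model per requested gene. The canonical transcript is the one
#' with the longest total CDS (for non-coding genes, the longest exonic
#' span); ties are broken by lexicographic transcript identifier. GTF
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path Path to a GTF/GFF3 file.
#' @param gene_ids Character vector of gene identifiers to load; empty
#'   vector yields an empty list.
#' @param require_coding If `TRUE`, fail on genes without any CDS.
#' @return Named list of `GeneModel` objects.
#' @export
load_gene_models <- function(path, gene_ids, require_coding = FALSE) {
  if (length(gene_ids) == 0) return(structure(list(), names = character()))
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  out <- list()
  for (g in gene_ids) {
    sel <- gr[!is.na(md$gene_id) & md$gene_id == g]
    if (length(sel) == 0) stop(sprintf("gene not found: %s", g))
    smd <- S4Vectors::mcols(sel)
    tx_ids <- sort(unique(stats::na.omit(smd$transcript_id)))
    score_tx <- function(tx) {
      cdsw <- sum(GenomicRanges::width(
        sel[smd$type == "CDS" & !is.na(smd$transcript_id) &
              smd$transcript_id == tx]))
      exw <- sum(GenomicRanges::width(
        sel[smd$type == "exon" & !is.na(smd$transcript_id) &
              smd$transcript_id == tx]))
      c(cdsw, exw)
    }
    sc <- vapply(tx_ids, score_tx, numeric(2))
    # longest CDS wins; among CDS ties longest exonic extent, then lexical id
    best <- tx_ids[order(-sc[1, ], -sc[2, ], tx_ids)][1]
    keep <- sel[!is.na(smd$transcript_id) & smd$transcript_id == best]
    kmd <- S4Vectors::mcols(keep)
    ex <- keep[kmd$type == "exon"]
    cdsr <- keep[kmd$type == "CDS"]
    if (length(ex) == 0) stop(sprintf("no exons for gene %s", g))
    strand <- as.character(GenomicRanges::strand(ex))[1]
    o <- if (strand == "+") order(GenomicRanges::start(ex)) else
      order(-GenomicRanges::start(ex))
    ex <- ex[o]
    exons <- data.frame(start = GenomicRanges::start(ex) - 1L,
                        end = GenomicRanges::end(ex))
    cds <- NULL
    if (length(cdsr) > 0) {
      cs <- GenomicRanges::start(cdsr) - 1L
      ce <- GenomicRanges::end(cdsr)
      exi <- vapply(seq_along(cs), function(i) {
        which(cs[i] >= exons$start & ce[i] <= exons$end)[1]
      }, integer(1))
      o2 <- order(exi)
      cds <- data.frame(exon_index = exi[o2], start = cs[o2], end = ce[o2])
    } else if (require_coding) {
      stop(sprintf("non-coding model: gene %s has no CDS", g))
    }
    out[[g]] <- gene_model(g, as.character(GenomicRanges::seqnames(ex))[1],
                           strand, exons, cds, transcript_id = best)
  }
  out
}

#' Write gene models to a GTF file
#'
#' Inverse of [load_gene_models()]: internal 0-based half-open intervals
#' are converted back to GTF 1-based inclusive coordinates, so a
#' write/reload round trip reproduces intervals exactly.
#'
#' @param models List of `GeneModel` objects.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  lines <- character()
  fmt <- function(m, type, start0, end0, extra = "") {
    sprintf(paste0("%s\tfgfr2trunc\t%s\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";%s"),
            m$chromosome, type, start0 + 1L, end0, m$strand,
            m$gene_id, m$transcript_id, extra)
  }
  for (m in models) {
    sp <- gene_span(m)
    lines <- c(lines, fmt(m, "transcript", sp[1], sp[2]))
    for (i in seq_len(n_exons(m))) {
      lines <- c(lines, fmt(m, "exon", m$exons$start[i], m$exons$end[i],
                            sprintf(" exon_number \"%d\";", i)))
    }
    if (m$coding) {
      for (i in seq_len(nrow(m$cds))) {
        lines <- c(lines, fmt(m, "CDS", m$cds$start[i], m$cds$end[i]))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
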