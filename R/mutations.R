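#' Small-variant classification: hotspots and E18-truncating mutations
#'
#' Somatic small variants are classified into missense hotspots, E18
#' splice-acceptor-site variants, and proximal versus distal
#' E18-truncating (nonsense/frameshift) mutations. The proximal
#' C-terminal range is E768-Y783 and the distal range P784-T821,
#' reflecting the functional split of the FGFR2 C terminus encoded by
#' exon 18.
#'
#' @name mutation_classifier
NULL

MUT_CATEGORIES <- c("HOTSPOT", "E18_SPLICE", "PROXIMAL_TRUNCATING",
                    "DISTAL_TRUNCATING", "OTHER")

#' Default missense hotspot residues
#'
#' FGFR2 Ser252, Cys382, Asn549, Lys659 and FGFR3 Arg248, Ser249,
#' Tyr373, Lys650.
#'
#' @return `data.frame` with columns `gene`, `position`, `ref_aa`.
#' @export
default_hotspots <- function() {
  data.frame(gene = c(rep("FGFR2", 4), rep("FGFR3", 4)),
             position = c(252L, 382L, 549L, 659L,
                          248L, 249L, 373L, 650L),
             ref_aa = c("S", "C", "N", "K", "R", "S", "Y", "K"))
}

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
         Ter = "*")

aa_to_1 <- function(x) {
  if (is.na(x) || x == "") return(NA_character_)
  if (nchar(x) == 1) return(toupper(x))
  key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  unname(AA3[key])
}

#' Parse a protein-level HGVS change
#'
#' Accepts one- and three-letter forms with or without the `p.` prefix:
#' `"p.N549K"`, `"N549K"`, `"p.Asn549Lys"`, `"p.E769*"`,
#' `"p.L800fs"`, `"p.L800Afs*12"`.
#'
#' @param hgvs_p Character scalar.
#' @return List with `ref_aa`, `position`, `alt_aa` and `consequence`
#'   (`"missense"`, `"nonsense"` or `"frameshift"`); frameshifts are
#'   located at the first altered residue.
#' @export
parse_hgvs_p <- function(hgvs_p) {
  x <- sub("^p\\.", "", trimws(hgvs_p))
  m <- regmatches(x, regexec(
    "^([A-Za-z\\*]{1,3})([0-9]+)([A-Za-z\\*]*?)(fs.*)?$", x))[[1]]
  if (length(m) == 0) stop(sprintf("cannot parse protein change: %s", hgvs_p))
  ref <- aa_to_1(m[2])
  pos <- as.integer(m[3])
  fs <- nzchar(m[5])
  alt <- if (nzchar(m[4])) aa_to_1(m[4]) else NA_character_
  consequence <- if (fs) "frameshift"
    else if (identical(alt, "*")) "nonsense"
    else "missense"
  list(ref_aa = ref, position = pos, alt_aa = alt,
       consequence = consequence)
}

#' Classify a small somatic variant
#'
#' Categories, in order of evaluation: `HOTSPOT` (missense at a
#' configured hotspot residue), `E18_SPLICE` (splice-site variant in the
#' E18 splice-acceptor window: the two intronic bases preceding E18 plus
#' its first exonic base), `PROXIMAL_TRUNCATING` /
#' `DISTAL_TRUNCATING` (nonsense or frameshift with first affected
#' residue inside the configured C-terminal ranges), else `OTHER`.
#'
#' @param gene Gene symbol.
#' @param hgvs_p Optional protein change (HGVS-p); parsed with
#'   [parse_hgvs_p()]. Alternatively give `protein_position`,
#'   `ref_aa`, `alt_aa` and `consequence` directly.
#' @param protein_position First affected residue (1-based).
#' @param ref_aa,alt_aa Amino-acid codes (one-letter).
#' @param consequence One of `"missense"`, `"nonsense"`,
#'   `"frameshift"`, `"splice_site"`.
#' @param genomic_position,chromosome Optional genomic location, used
#'   with `model` to test the E18 splice-acceptor window.
#' @param model Optional gene-of-interest `GeneModel` (required to
#'   resolve splice-site variants).
#' @param hotspots Hotspot residue table (see [default_hotspots()]).
#' @param proximal_range,distal_range Residue ranges for proximal and
#'   distal E18 truncations.
#' @param splice_window_intronic Number of intronic bases upstream of
#'   the E18 acceptor included in the splice window (default 2; the
#'   first exonic base is always included).
#' @return A `MutationCall`: list with `gene`, `protein_position`,
#'   `ref_aa`, `alt_aa`, `consequence`, `category`.
#' @export
classify_mutation <- function(gene, hgvs_p = NULL,
                              protein_position = NA_integer_,
                              ref_aa = NA_character_,
                              alt_aa = NA_character_,
                              consequence = NULL,
                              genomic_position = NA_real_,
                              chromosome = NA_character_,
                              model = NULL,
                              hotspots = default_hotspots(),
                              proximal_range = c(768L, 783L),
                              distal_range = c(784L, 821L),
                              splice_window_intronic = 2L) {
  if (is.null(gene) || is.na(gene) || !nzchar(gene))
    stop("unknown gene")
  if (!is.null(hgvs_p)) {
    p <- parse_hgvs_p(hgvs_p)
    protein_position <- p$position
    ref_aa <- p$ref_aa
    alt_aa <- p$alt_aa
    if (is.null(consequence)) consequence <- p$consequence
  }
  if (is.null(consequence)) {
    consequence <- if (identical(alt_aa, "*")) "nonsense" else "missense"
  }
  stopifnot(consequence %in% c("missense", "nonsense", "frameshift",
                               "splice_site"))
  category <- "OTHER"
  if (consequence == "missense") {
    hs <- hotspots[hotspots$gene == gene, ]
    if (!is.na(protein_position) && protein_position %in% hs$position)
      category <- "HOTSPOT"
  } else if (consequence == "splice_site") {
    if (!is.null(model) && !is.na(genomic_position) &&
        in_e18_acceptor_window(model, genomic_position,
                               splice_window_intronic))
      category <- "E18_SPLICE"
  } else {
    if (!is.na(protein_position)) {
      if (protein_position >= proximal_range[1] &&
          protein_position <= proximal_range[2]) {
        category <- "PROXIMAL_TRUNCATING"
      } else if (protein_position >= distal_range[1] &&
                 protein_position <= distal_range[2]) {
        category <- "DISTAL_TRUNCATING"
      }
    }
  }
  structure(list(gene = gene, protein_position = protein_position,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 consequence = consequence, category = category),
            class = "MutationCall")
}

# splice-acceptor window of the terminal exon: the `intronic` bases of
# I17 immediately preceding E18 in transcript orientation, plus the
# first exonic base of E18
in_e18_acceptor_window <- function(model, position, intronic = 2L) {
  n <- n_exons(model)
  e18 <- model$exons[n, ]
  if (model$strand == "+") {
    win_lo <- e18$start - intronic
    win_hi <- e18$start + 1L       # half-open: includes first exon base
    position >= win_lo && position < win_hi
  } else {
    win_lo <- e18$end - 1L
    win_hi <- e18$end + intronic
    position >= win_lo && position < win_hi
  }
}

#' @export
print.MutationCall <- function(x, ...) {
  cat(sprintf("MutationCall %s %s%s%s (%s) -> %s\n", x$gene,
              ifelse(is.na(x$ref_aa), "", x$ref_aa),
              ifelse(is.na(x$protein_position), "", x$protein_position),
              ifelse(is.na(x$alt_aa), "", x$alt_aa),
              x$consequence, x$category))
  invisible(x)
}

#' Classify a MAF-like table of small variants
#'
#' @param maf `data.frame` with columns `sample`, `gene`, `hgvs_p`
#'   (may be empty for splice-site rows), `consequence`, and optional
#'   `chromosome`, `position` (0-based genomic) for splice-site rows.
#' @param model Optional gene-of-interest `GeneModel` for splice-window
#'   resolution.
#' @param ... Passed to [classify_mutation()].
#' @return The input with a `category` column appended.
#' @export
classify_maf <- function(maf, model = NULL, ...) {
  maf$category <- vapply(seq_len(nrow(maf)), function(i) {
    r <- maf[i, ]
    hp <- if (!is.null(r$hgvs_p) && !is.na(r$hgvs_p) && nzchar(r$hgvs_p))
      r$hgvs_p else NULL
    cons <- if (!is.null(r$consequence) && !is.na(r$consequence))
      r$consequence else NULL
    gp <- if ("position" %in% names(maf)) r$position else NA_real_
    classify_mutation(r$gene, hgvs_p = hp, consequence = cons,
                      genomic_position = gp, model = model, ...)$category
  }, character(1))
  maf
}

#' Read a MAF-like tab-separated variant table
#'
#' @param path Path to a TSV with header (`sample`, `gene`, `hgvs_p`,
#'   `consequence`, optional `chromosome`, `position`).
#' @return `data.frame`.
#' @export
read_maf <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    na.strings = c("NA", ""))
}
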