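#' Integration of DNA and RNA evidence into per-sample categories
#'
#' Each sample is assigned exactly one of four mutually exclusive
#' FGFR2 alteration categories: `E18_TRUNCATED`, `FL_AMP`, `HOTSPOT`,
#' `WT`, with precedence E18_TRUNCATED > FL_AMP > HOTSPOT. Grouped as
#' E18-truncating are: I17/E18 in-frame fusions or non-canonical
#' rearrangements passing the allele-frequency threshold, E1-E17
#' partial amplifications, E18 splice-site mutations and proximal
#' E18-truncating mutations. Distal truncating mutations are recorded
#' but never trigger the truncated category.
#'
#' @name cohort_integrator
NULL

CATEGORIES <- c("E18_TRUNCATED", "FL_AMP", "HOTSPOT", "WT")

SUBGROUPS <- c("IN_FRAME_FUSION", "FUSION_PLUS_AMP", "FRAME_UNKNOWN_RE",
               "INTERGENIC_RE", "OUT_OF_STRAND_RE", "INTERNAL_RE",
               "SPLICE_MUT", "PROXIMAL_TRUNC_MUT", "PARTIAL_AMP",
               "DISTAL_TRUNC_MUT", "FULL_AMP", "HOTSPOT_MUT", "NONE")

#' Assign the per-sample FGFR2 alteration category
#'
#' @param sample_id Sample identifier.
#' @param re_calls List of `RearrangementCall` objects (with allele
#'   frequencies computed), possibly empty.
#' @param amp_call An `AmplificationCall` or `NULL`.
#' @param mutations List of `MutationCall` objects, possibly empty.
#' @param rna_flags Optional list of RNA evidence (e.g. the result of
#'   [call_e18_truncated_rna()] and [e18_loss()]); recorded as
#'   annotation, not used for category assignment.
#' @param tumour_type Optional tumour-type label.
#' @return A `SampleAlterationProfile`: list with `sample_id`,
#'   `category`, `subgroup`, `annotations` and the input evidence.
#'   The subgroup follows the category; a sample carrying both an
#'   in-frame I17/E18 fusion and a full-length amplification is
#'   E18_TRUNCATED with subgroup `FUSION_PLUS_AMP`.
#' @export
assign_category <- function(sample_id, re_calls = list(),
                            amp_call = NULL, mutations = list(),
                            rna_flags = NULL, tumour_type = NA_character_) {
  if (length(re_calls) == 0 && is.null(amp_call) &&
      length(mutations) == 0)
    stop("no evidence lines provided")
  re_trunc <- vapply(re_calls, function(x) isTRUE(x$e18_truncating),
                     logical(1))
  re_types <- vapply(re_calls, function(x) x$re_type, character(1))
  mut_cat <- vapply(mutations, function(x) x$category, character(1))
  amp_status <- if (is.null(amp_call)) "NONE" else amp_call$status
  partial <- amp_status == "PARTIAL_AMP_E1_E17"
  full <- amp_status == "FULL_LENGTH_AMP"
  splice <- any(mut_cat == "E18_SPLICE")
  proximal <- any(mut_cat == "PROXIMAL_TRUNCATING")
  hotspot <- any(mut_cat == "HOTSPOT")
  truncated <- any(re_trunc) || partial || splice || proximal

  subgroup <- "NONE"
  if (truncated) {
    category <- "E18_TRUNCATED"
    trunc_types <- re_types[re_trunc]
    subgroup <- if ("IN_FRAME_FUSION" %in% trunc_types) {
      if (full) "FUSION_PLUS_AMP" else "IN_FRAME_FUSION"
    } else if ("FRAME_UNKNOWN" %in% trunc_types) "FRAME_UNKNOWN_RE"
    else if ("INTERGENIC_SPACE" %in% trunc_types) "INTERGENIC_RE"
    else if ("OUT_OF_STRAND" %in% trunc_types) "OUT_OF_STRAND_RE"
    else if ("INTERNAL" %in% trunc_types) "INTERNAL_RE"
    else if (splice) "SPLICE_MUT"
    else if (proximal) "PROXIMAL_TRUNC_MUT"
    else "PARTIAL_AMP"
  } else if (full) {
    category <- "FL_AMP"
    subgroup <- "FULL_AMP"
  } else if (hotspot) {
    category <- "HOTSPOT"
    subgroup <- "HOTSPOT_MUT"
  } else {
    category <- "WT"
  }
  structure(list(sample_id = sample_id, tumour_type = tumour_type,
                 category = category, subgroup = subgroup,
                 annotations = list(
                   distal_truncating = any(mut_cat == "DISTAL_TRUNCATING"),
                   hotspot = hotspot, full_amp = full,
                   rna = rna_flags),
                 re_calls = re_calls, amp_call = amp_call,
                 mutations = mutations),
            class = "SampleAlterationProfile")
}

#' @export
print.SampleAlterationProfile <- function(x, ...) {
  cat(sprintf("SampleAlterationProfile %s: %s / %s\n", x$sample_id,
              x$category, x$subgroup))
  invisible(x)
}

#' Round half-up at a fixed number of decimals
#'
#' Commercial rounding (0.5 always rounds away from zero for positive
#' values), matching how printed incidences and fractions are reported.
#'
#' @param x Numeric vector (non-negative use intended).
#' @param digits Number of decimals.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Incidence of an alteration class in an assayed cohort, in percent
#'
#' `100 * count / total_assayed`, rounded half-up to 2 decimals.
#'
#' @param count Number of samples in the class.
#' @param total_assayed Total assayed samples (> 0).
#' @return Percent incidence.
#' @export
incidence_pct <- function(count, total_assayed) {
  if (any(total_assayed <= 0)) stop("total assayed must be positive")
  round_half_up(100 * count / total_assayed, 2)
}

#' Within-class fraction, in percent
#'
#' `100 * count / class_total`, rounded half-up to 1 decimal.
#'
#' @param count Subgroup count.
#' @param class_total Total samples in the class (> 0).
#' @return Percent fraction.
#' @export
fraction_pct <- function(count, class_total) {
  if (any(class_total <= 0)) stop("class total must be positive")
  round_half_up(100 * count / class_total, 1)
}

#' Summarize a cohort of sample alteration profiles
#'
#' @param profiles List of `SampleAlterationProfile` objects.
#' @param total_assayed Total number of assayed samples (>= number of
#'   profiles); profiles are the altered/evaluated subset.
#' @return A `CohortSummary`: list with `category_counts`,
#'   `subgroup_counts`, `total_assayed`, `incidence_pct` per category,
#'   and `fraction_pct` of each subgroup within its category.
#' @export
cohort_summary <- function(profiles, total_assayed) {
  if (total_assayed <= 0) stop("total assayed must be positive")
  if (total_assayed < length(profiles))
    stop("total assayed smaller than the number of profiles")
  cats <- vapply(profiles, function(p) p$category, character(1))
  subs <- vapply(profiles, function(p) p$subgroup, character(1))
  category_counts <- table(factor(cats, levels = CATEGORIES))
  inc <- incidence_pct(as.integer(category_counts), total_assayed)
  names(inc) <- names(category_counts)
  sub_split <- split(subs, factor(cats, levels = CATEGORIES))
  frac <- lapply(names(sub_split), function(cl) {
    s <- sub_split[[cl]]
    if (length(s) == 0) return(numeric())
    tt <- table(s)
    out <- fraction_pct(as.integer(tt), length(s))
    names(out) <- names(tt)
    out
  })
  names(frac) <- names(sub_split)
  structure(list(category_counts = category_counts,
                 subgroup_counts = table(subs),
                 total_assayed = total_assayed,
                 incidence_pct = inc, fraction_pct = frac),
            class = "CohortSummary")
}

#' Treatment response ratio from tumour-volume series
#'
#' Delta-T and Delta-C are the mean differences between the last and
#' the first treatment-day volumes over the animals of the treated and
#' control arms; the response ratio is their quotient. A flat or
#' regressing control arm (Delta-C <= 0) leaves the ratio undefined.
#'
#' @param treated,control Lists of per-animal numeric volume series
#'   (each with at least 2 timepoints), or matrices with one row per
#'   animal.
#' @return A `TreatmentResponse`: list with `delta_t`, `delta_c`,
#'   `ratio` (NA when undefined) and `defined`.
#' @export
delta_t_delta_c <- function(treated, control) {
  as_series <- function(x) {
    if (is.matrix(x)) x <- split(x, row(x))
    stopifnot(length(x) >= 1, all(vapply(x, length, integer(1)) >= 2))
    x
  }
  dt <- mean(vapply(as_series(treated),
                    function(v) v[length(v)] - v[1], numeric(1)))
  dc <- mean(vapply(as_series(control),
                    function(v) v[length(v)] - v[1], numeric(1)))
  defined <- dc > 0
  structure(list(delta_t = dt, delta_c = dc,
                 ratio = if (defined) dt / dc else NA_real_,
                 defined = defined),
            class = "TreatmentResponse")
}
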