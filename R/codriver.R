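#' Co-driver enrichment and co-occurrence statistics
#'
#' Enrichment of driver co-alterations across FGFR2 alteration
#' categories: one-tailed proportion Z-tests comparing the focal
#' category against the other altered categories, and two-tailed
#' Fisher's exact tests of each category versus wild-type samples, with
#' Benjamini-Hochberg correction within each analysis family.
#'
#' @name codriver_stats
NULL

#' Binary cohort alteration matrix with category labels
#'
#' @param alterations Samples x genes matrix of 0/1 alteration
#'   indicators (column names are the driver genes).
#' @param category Character vector of per-sample FGFR2 categories
#'   (values among `E18_TRUNCATED`, `FL_AMP`, `HOTSPOT`, `WT`).
#' @param tumour_type Optional per-sample tumour-type labels.
#' @return An object of class `CohortMatrix`.
#' @export
cohort_matrix <- function(alterations, category, tumour_type = NULL) {
  alterations <- as.matrix(alterations)
  stopifnot(all(alterations %in% c(0, 1)),
            nrow(alterations) == length(category),
            all(category %in% CATEGORIES))
  structure(list(alterations = alterations,
                 category = as.character(category),
                 tumour_type = tumour_type),
            class = "CohortMatrix")
}

#' One-tailed proportion Z-test of co-driver enrichment
#'
#' Compares the alteration proportion of `gene` in the focal FGFR2
#' category against the pooled remaining altered categories (default)
#' or against all other samples including wild type. The statistic is
#' the standard two-sample proportion Z with pooled variance; the p
#' value is the one-tailed upper normal tail (enrichment in the focal
#' category).
#'
#' @param cm A `CohortMatrix`.
#' @param gene Driver gene (column of the matrix).
#' @param focal_category Focal FGFR2 category.
#' @param mode `"within_altered"` (focal vs the other altered
#'   categories, wild type excluded) or `"vs_all_others"`.
#' @return List with `z`, `p`, `p1`, `p2`, `n1`, `n2`. A degenerate
#'   pooled proportion (0 or 1) yields `p = 1` with a warning.
#' @export
proportion_z_enrichment <- function(cm, gene, focal_category,
                                    mode = c("within_altered",
                                             "vs_all_others")) {
  mode <- match.arg(mode)
  g <- cm$alterations[, gene]
  focal <- cm$category == focal_category
  other <- if (mode == "within_altered")
    !focal & cm$category != "WT" else !focal
  proportion_z(sum(g[focal]), sum(focal), sum(g[other]), sum(other))
}

#' Two-sample pooled proportion Z statistic (one-tailed upper)
#'
#' @param x1,n1 Successes and size of the focal group.
#' @param x2,n2 Successes and size of the comparison group.
#' @return List with `z`, `p` (one-tailed upper), `p1`, `p2`, `n1`,
#'   `n2`.
#' @export
proportion_z <- function(x1, n1, x2, n2) {
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    warning("degenerate pooled proportion: test undefined")
    return(list(z = 0, p = 1, p1 = p1, p2 = p2, n1 = n1, n2 = n2))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
       p1 = p1, p2 = p2, n1 = n1, n2 = n2)
}

#' Two-tailed Fisher exact p value for a 2x2 table
#'
#' Point-probability summation: all hypergeometric outcomes with
#' probability no greater than the observed one (up to a relative
#' tolerance of 1e-7) contribute to the two-sided p value.
#'
#' @param a,b,c,d Cell counts: rows are exposure (e.g. FGFR2 category
#'   vs WT), columns outcome (gene altered vs not).
#' @return The two-sided exact p value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  if (m + n2 == 0) stop("empty table")
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' Fisher co-occurrence / mutual-exclusivity analysis of one gene
#'
#' Builds the 2x2 table of `category` versus wild-type samples against
#' gene-altered versus not, and reports the two-tailed exact p value,
#' the cross-product odds ratio (with Haldane-Anscombe +0.5 correction
#' on all cells iff any cell is zero) and the Woolf 95% confidence
#' interval on the log odds ratio. Odds ratios above 1 indicate
#' co-occurrence, below 1 mutual exclusivity.
#'
#' @param cm A `CohortMatrix`.
#' @param gene Driver gene.
#' @param category Focal FGFR2 category (compared against `WT`).
#' @param conf_level Confidence level for the Woolf interval.
#' @return One-row `data.frame` with `gene`, `category`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`, `p_fisher`.
#' @export
fisher_cooccurrence <- function(cm, gene, category, conf_level = 0.95) {
  g <- cm$alterations[, gene]
  focal <- cm$category == category
  wt <- cm$category == "WT"
  if (sum(focal) == 0 || sum(wt) == 0) stop("empty margin")
  a <- sum(g[focal] == 1)
  b <- sum(g[focal] == 0)
  cc <- sum(g[wt] == 1)
  d <- sum(g[wt] == 0)
  or <- odds_ratio_ci(a, b, cc, d, conf_level)
  data.frame(gene = gene, category = category, a = a, b = b, c = cc,
             d = d, odds_ratio = or$or, ci_low = or$ci_low,
             ci_high = or$ci_high, p_fisher = fisher_exact_p(a, b, cc, d))
}

#' Cross-product odds ratio with Woolf confidence interval
#'
#' @param a,b,c,d Cell counts. If any cell is zero, 0.5 is added to all
#'   cells (Haldane-Anscombe) before computing both the odds ratio and
#'   the interval.
#' @param conf_level Confidence level.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = exp(log(or) - zq * se),
       ci_high = exp(log(or) + zq * se))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment mapping p values to q values.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return q values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Full co-driver enrichment scan
#'
#' Runs [fisher_cooccurrence()] for every gene within each requested
#' category and applies BH correction within each category's gene list
#' (per-panel correction). Proportion Z-tests are reported alongside.
#'
#' @param cm A `CohortMatrix`.
#' @param genes Driver genes to test (default: all matrix columns).
#' @param categories Focal categories (default: the three altered
#'   categories).
#' @param mode Passed to [proportion_z_enrichment()].
#' @return `data.frame` with one row per gene x category:
#'   2x2 counts, `proportion_z`, `p_z`, `q_z`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_fisher`, `q_fisher`.
#' @export
codriver_enrichment <- function(cm, genes = colnames(cm$alterations),
                                categories = c("E18_TRUNCATED",
                                               "FL_AMP", "HOTSPOT"),
                                mode = "within_altered") {
  out <- list()
  for (cat in categories) {
    rows <- lapply(genes, function(g) {
      fr <- fisher_cooccurrence(cm, g, cat)
      z <- proportion_z_enrichment(cm, g, cat, mode = mode)
      fr$proportion_z <- z$z
      fr$p_z <- z$p
      fr
    })
    block <- do.call(rbind, rows)
    block$q_fisher <- bh_adjust(block$p_fisher)
    block$q_z <- bh_adjust(block$p_z)
    out[[cat]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
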