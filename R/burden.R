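#' Count qualifying-variant carriers of a gene in one group
#'
#' A *carrier* is an individual with dosage >= 1 for at least one qualifying
#' variant of the gene; an individual with qualifying variants in several
#' genes contributes to each of them. A gene absent from the cohort (or with
#' no qualifying variants) counts 0.
#'
#' @param x a [cohort()].
#' @param gene gene symbol (case-insensitive).
#' @param group `"case"` or `"control"`.
#' @param qualifying a [select_qualifying()] result for `x`.
#' @return integer carrier count.
#' @export
carrier_count <- function(x, gene, group = c("case", "control"), qualifying) {
  group <- match.arg(group)
  length(gene_carrier_rows(x, toupper(gene), qualifying,
                           group_index(x, group)))
}

# Row indices (into the roster) of carriers of `gene` among `rows`.
gene_carrier_rows <- function(x, gene, qualifying, rows) {
  v <- qualifying$idx[x$variants$gene[qualifying$idx] == gene]
  if (!length(v)) return(integer())
  d <- x$dosages[rows, v, drop = FALSE]
  rows[which(Matrix::rowSums(d >= 1) > 0)]
}

#' Per-gene collapsing burden scan
#'
#' For every panel gene, collapses its qualifying variants into a
#' carrier/non-carrier indicator, builds the 2x2 table against group sizes
#' (carriers versus group size, i.e. *individual* counts, not allele
#' counts), and attaches the Pearson chi-square (no continuity correction)
#' and both Fisher exact p-values. Genes with no carriers anywhere are kept
#' with p = 1, so the output always has one row per panel gene. Rows are
#' sorted by ascending `p_chi2` (the ranking statistic that reproduces
#' published orderings in this design), ties broken alphabetically.
#'
#' @param x a [cohort()] containing both groups.
#' @param panel a [gene_panel()].
#' @param qualifying a [select_qualifying()] result for `x`.
#' @param adjust optional multiple-testing adjustment of the chi-square
#'   p-value added as column `p_adjusted` (`"bonferroni"`, `"BH"`, or
#'   `NULL`, the default: raw p-values only).
#' @return A data.frame of class `"gene_burden_result"` with columns `gene`,
#'   `case_n`, `case_carriers`, `control_n`, `control_carriers`, `chi2`,
#'   `p_chi2`, `p_fisher_one_sided`, `p_fisher_two_sided`, `rank`.
#' @export
gene_burden_scan <- function(x, panel, qualifying, adjust = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(panel, "gene_panel"),
            inherits(qualifying, "qualifying_set"))
  require_both_groups(x)
  case_rows <- group_index(x, "case")
  ctrl_rows <- group_index(x, "control")
  n_case <- length(case_rows); n_ctrl <- length(ctrl_rows)
  genes <- sort(panel$genes)
  a <- integer(length(genes)); cc <- integer(length(genes))
  for (g in seq_along(genes)) {
    a[g] <- length(gene_carrier_rows(x, genes[g], qualifying, case_rows))
    cc[g] <- length(gene_carrier_rows(x, genes[g], qualifying, ctrl_rows))
  }
  chi2 <- double(length(genes)); p_chi2 <- double(length(genes))
  p1 <- double(length(genes)); p2 <- double(length(genes))
  for (g in seq_along(genes)) {
    tb <- two_by_two(a[g], n_case - a[g], cc[g], n_ctrl - cc[g])
    ch <- pearson_chi2(tb)
    chi2[g] <- ch$statistic; p_chi2[g] <- ch$p
    if (a[g] + cc[g] == 0L) {
      p1[g] <- 1; p2[g] <- 1
    } else {
      p1[g] <- fisher_exact(tb, "one_sided_enrichment")
      p2[g] <- fisher_exact(tb, "two_sided")
    }
  }
  out <- data.frame(gene = genes, case_n = n_case, case_carriers = a,
                    control_n = n_ctrl, control_carriers = cc,
                    chi2 = chi2, p_chi2 = p_chi2,
                    p_fisher_one_sided = p1, p_fisher_two_sided = p2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_chi2, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(adjust)) {
    out$p_adjusted <- stats::p.adjust(out$p_chi2, method = adjust)
  }
  rownames(out) <- NULL
  class(out) <- c("gene_burden_result", "data.frame")
  out
}

#' @export
print.gene_burden_result <- function(x, n = 10L, ...) {
  cat(sprintf("<gene_burden_result> %d genes; top %d by chi-square p:\n",
              nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4,
                   row.names = FALSE)
  invisible(x)
}

#' Per-individual qualifying-variant burden
#'
#' For every individual (both groups): the number of *distinct* qualifying
#' variants carried (dosage >= 1, so a homozygote counts once) and the
#' total qualifying *allele* count (dosage sum, homozygote counts twice).
#'
#' @param x a [cohort()].
#' @param qualifying a [select_qualifying()] result for `x`.
#' @return data.frame with `individual_id`, `group`, `n_variants`,
#'   `n_alleles`, one row per individual in roster order.
#' @export
per_individual_burden <- function(x, qualifying) {
  d <- x$dosages[, qualifying$idx, drop = FALSE]
  data.frame(individual_id = as.character(x$individuals$individual_id),
             group = as.character(x$individuals$group),
             n_variants = as.integer(Matrix::rowSums(d >= 1)),
             n_alleles = as.integer(Matrix::rowSums(d)),
             stringsAsFactors = FALSE)
}

#' Compare mean per-individual burden between groups
#'
#' Convenience wrapper: computes [per_individual_burden()] and runs the
#' one-tailed pooled t-test ([mean_burden_t_test()]) on the distinct-variant
#' counts (cases vs controls).
#'
#' @inheritParams per_individual_burden
#' @param measure `"n_variants"` (distinct sites) or `"n_alleles"`.
#' @return list: the per-individual data.frame plus the t-test result.
#' @export
burden_summary <- function(x, qualifying, measure = c("n_variants",
                                                      "n_alleles")) {
  measure <- match.arg(measure)
  require_both_groups(x)
  per <- per_individual_burden(x, qualifying)
  test <- mean_burden_t_test(per[[measure]][per$group == "case"],
                             per[[measure]][per$group == "control"])
  list(per_individual = per, measure = measure, test = test)
}
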