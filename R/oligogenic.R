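#' Genes hit per individual
#'
#' For every individual in the cohort, the set of panel genes in which they
#' carry at least one qualifying variant (dosage >= 1), with the individual
#' (gene, variant key) pairs retained for reporting. Genes outside the
#' panel are excluded. Output is ordered by individual id.
#'
#' @param x a [cohort()].
#' @param qualifying a [select_qualifying()] result for `x`.
#' @param panel a [gene_panel()].
#' @return data.frame with `individual_id`, `group`, `genes` (list column of
#'   sorted gene symbols), `hits` (list column of `gene|variant` pairs) and
#'   `n_genes` (distinct-gene count).
#' @export
genes_hit_per_individual <- function(x, qualifying, panel) {
  stopifnot(inherits(x, "cohort"), inherits(qualifying, "qualifying_set"),
            inherits(panel, "gene_panel"))
  vidx <- qualifying$idx[x$variants$gene[qualifying$idx] %in% panel$genes]
  d <- x$dosages[, vidx, drop = FALSE] >= 1
  genes_of <- x$variants$gene[vidx]
  keys_of <- variant_key(x$variants)[vidx]
  ord <- order(as.character(x$individuals$individual_id))
  out <- data.frame(
    individual_id = as.character(x$individuals$individual_id)[ord],
    group = as.character(x$individuals$group)[ord],
    stringsAsFactors = FALSE
  )
  glist <- vector("list", length(ord))
  hlist <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    w <- which(d[ord[r], ])
    glist[[r]] <- sort(unique(genes_of[w]))
    o <- order(genes_of[w], keys_of[w])
    hlist[[r]] <- paste(genes_of[w][o], keys_of[w][o], sep = "|")
  }
  out$genes <- glist
  out$hits <- hlist
  out$n_genes <- lengths(glist)
  out
}

#' Multi-gene (potentially oligogenic) carriers
#'
#' Individuals of one group carrying qualifying variants in at least
#' `min_genes` *distinct* panel genes. Two variants in the same gene do not
#' make a multi-gene carrier: the oligogenic hypothesis concerns concurrent
#' hits in different genes.
#'
#' @param hits output of [genes_hit_per_individual()].
#' @param group `"case"` or `"control"`.
#' @param min_genes threshold, >= 2.
#' @return sorted character vector of individual ids.
#' @export
multigene_carriers <- function(hits, group = c("case", "control"),
                               min_genes = 2L) {
  group <- match.arg(group)
  if (min_genes < 2) stop("min_genes must be >= 2", call. = FALSE)
  sort(hits$individual_id[hits$group == group & hits$n_genes >= min_genes])
}

#' Enrichment of multi-gene carriers in cases
#'
#' Builds the 2x2 table of multi-gene carriers versus the rest of each
#' group and attaches the full statistics kernel output: Pearson chi-square
#' (the headline p in this design) and both Fisher exact p-values, plus the
#' case carrier proportion as a percentage rounded to one decimal.
#'
#' @param x a [cohort()] with both groups.
#' @param hits output of [genes_hit_per_individual()] on `x`.
#' @param min_genes distinct-gene threshold, >= 2.
#' @return An object of class `"oligogenic_result"`: list with `min_genes`,
#'   `case_carriers`, `control_carriers`, `case_pct`, `table`
#'   (a [two_by_two()]), `chi2`, `p_chi2`, `p_fisher_one_sided`,
#'   `p_fisher_two_sided`, and `combinations` (the [combination_report()]).
#' @export
oligogenic_enrichment <- function(x, hits, min_genes = 2L) {
  require_both_groups(x)
  case_ids <- multigene_carriers(hits, "case", min_genes)
  ctrl_ids <- multigene_carriers(hits, "control", min_genes)
  n_case <- length(group_index(x, "case"))
  n_ctrl <- length(group_index(x, "control"))
  tb <- two_by_two(length(case_ids), n_case - length(case_ids),
                   length(ctrl_ids), n_ctrl - length(ctrl_ids))
  ch <- pearson_chi2(tb)
  k <- tb$a + tb$c
  p1 <- if (k == 0) 1 else fisher_exact(tb, "one_sided_enrichment")
  p2 <- if (k == 0) 1 else fisher_exact(tb, "two_sided")
  structure(list(
    min_genes = as.integer(min_genes),
    case_carriers = case_ids, control_carriers = ctrl_ids,
    case_pct = round(100 * tb$a / n_case, 1),
    table = tb, chi2 = ch$statistic, p_chi2 = ch$p,
    p_fisher_one_sided = p1, p_fisher_two_sided = p2,
    combinations = combination_report(hits, x, min_genes = min_genes)
  ), class = "oligogenic_result")
}

#' @export
print.oligogenic_result <- function(x, ...) {
  cat(sprintf(
    "<oligogenic_result> >=%d genes: cases %d/%d (%.1f%%), controls %d/%d\n",
    x$min_genes, x$table$a, x$table$a + x$table$b, x$case_pct,
    x$table$c, x$table$c + x$table$d))
  cat(sprintf("  chi2 p = %.3g; Fisher one-sided %.3g, two-sided %.3g\n",
              x$p_chi2, x$p_fisher_one_sided, x$p_fisher_two_sided))
  invisible(x)
}

#' Gene-combination report for multi-gene case carriers
#'
#' One row per (multi-gene case carrier, qualifying panel variant): patient,
#' gene, variant type and nomenclature, ordered by patient id then gene —
#' the standard presentation of candidate oligogenic combinations.
#'
#' @param hits output of [genes_hit_per_individual()].
#' @param x the cohort.
#' @param min_genes distinct-gene threshold for inclusion.
#' @return data.frame with `patient`, `gene`, `consequence`, `hgvs_c`,
#'   `variant`.
#' @export
combination_report <- function(hits, x, min_genes = 2L) {
  carriers <- multigene_carriers(hits, "case", min_genes)
  empty <- data.frame(patient = character(), gene = character(),
                      consequence = character(), hgvs_c = character(),
                      variant = character(), stringsAsFactors = FALSE)
  if (!length(carriers)) return(empty)
  key_all <- variant_key(x$variants)
  rows <- lapply(carriers, function(id) {
    hh <- hits$hits[[match(id, hits$individual_id)]]
    if (!length(hh)) return(empty)
    parts <- strsplit(hh, "|", fixed = TRUE)
    gene <- vapply(parts, `[[`, character(1L), 1L)
    key <- vapply(parts, `[[`, character(1L), 2L)
    vi <- match(key, key_all)
    data.frame(patient = id, gene = gene,
               consequence = x$variants$consequence[vi],
               hgvs_c = if ("hgvs_c" %in% names(x$variants))
                 x$variants$hgvs_c[vi] else NA_character_,
               variant = key, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient, out$gene, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}
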