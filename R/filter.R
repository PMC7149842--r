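#' Qualifying-variant filter configuration
#'
#' Encodes the rarity and consequence criteria that define a *qualifying
#' variant*: minor allele frequency below `maf_internal_max` in the combined
#' case+control cohort, allele frequency below `maf_external_max` in every
#' configured external reference population, an admitted consequence class,
#' and (optionally) membership of a gene panel. Defaults mirror the usual
#' rare-disease burden setting: MAF < 0.001 internally and externally
#' against ExAC and gnomAD, all coding and splice classes admitted
#' (synonymous included — see [coding_consequences()]).
#'
#' Pathogenicity scores are carried through and reported but do not gate
#' qualification unless `min_gerp` / `min_cadd` are set; in published burden
#' designs of this kind the prediction tools inform interpretation, not the
#' qualifying filter.
#'
#' @param maf_internal_max,maf_external_max frequency thresholds in (0, 1].
#' @param external_sources source names checked against `af_<source>`
#'   columns.
#' @param allowed_consequences admitted consequence classes (non-empty
#'   subset of [consequence_levels()]).
#' @param restrict_to_panel if `TRUE`, a variant must lie in the panel
#'   passed to [select_qualifying()].
#' @param min_gerp,min_cadd optional score gates (variant fails if its score
#'   is present and below the gate).
#' @return An object of class `"filter_config"`.
#' @export
filter_config <- function(maf_internal_max = 0.001,
                          maf_external_max = 0.001,
                          external_sources = c("exac", "gnomad"),
                          allowed_consequences = coding_consequences(),
                          restrict_to_panel = FALSE,
                          min_gerp = NULL, min_cadd = NULL) {
  if (!(maf_internal_max > 0 && maf_internal_max <= 1) ||
      !(maf_external_max > 0 && maf_external_max <= 1)) {
    stop("MAF thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (!length(allowed_consequences)) {
    stop("allowed_consequences must be non-empty", call. = FALSE)
  }
  check_consequences(allowed_consequences, "allowed_consequences")
  structure(list(maf_internal_max = maf_internal_max,
                 maf_external_max = maf_external_max,
                 external_sources = tolower(external_sources),
                 allowed_consequences = allowed_consequences,
                 restrict_to_panel = isTRUE(restrict_to_panel),
                 min_gerp = min_gerp, min_cadd = min_cadd),
            class = "filter_config")
}

#' Internal minor allele frequency of a variant
#'
#' The allele frequency of the alternate allele in the combined case and
#' control cohort — total dosage over `2N` chromosomes — folded to
#' `min(f, 1 - f)` so the result is a *minor* allele frequency in
#' `[0, 0.5]`.
#'
#' @param x a [cohort()].
#' @param index variant column index; omit to get the whole vector.
#' @return numeric frequency (or vector over all variants).
#' @export
compute_internal_af <- function(x, index = NULL) {
  n <- n_individuals(x)
  if (n < 1) stop("cohort has no individuals", call. = FALSE)
  if (!is.null(index)) {
    if (index < 1 || index > ncol(x$dosages)) {
      stop(sprintf("variant index %d out of range [1, %d]",
                   index, ncol(x$dosages)), call. = FALSE)
    }
    f <- sum(x$dosages[, index]) / (2 * n)
  } else {
    f <- Matrix::colSums(x$dosages) / (2 * n)
  }
  pmin(f, 1 - f)
}

#' Decide whether one variant qualifies
#'
#' Applies the four criteria in the fixed audit order *internal MAF,
#' external MAF, consequence, panel* (plus optional score gates last) and
#' reports the first failure. The order only affects which reason is
#' reported — the conjunction itself is order-free.
#'
#' @param variant one-row slice of a variant table.
#' @param internal_af the variant's precomputed internal MAF.
#' @param config a [filter_config()].
#' @param panel a [gene_panel()] or `NULL`. The panel criterion applies when
#'   `config$restrict_to_panel` is `TRUE` and a panel is supplied.
#' @return list with `pass` (logical) and `reason` (`NA` when passing, else
#'   one of `"internal"`, `"external"`, `"consequence"`, `"panel"`,
#'   `"score"`).
#' @export
is_qualifying <- function(variant, internal_af, config = filter_config(),
                          panel = NULL) {
  st <- qualifying_status(variant, internal_af, config, panel)
  list(pass = st$pass[1L], reason = st$reason[1L])
}

# Vectorised criterion evaluation over a whole variant table.
qualifying_status <- function(variants, internal_afs, config, panel = NULL) {
  nv <- nrow(variants)
  ext <- external_af_max(variants, config$external_sources)
  fail_internal <- internal_afs >= config$maf_internal_max
  fail_external <- ext >= config$maf_external_max
  fail_consequence <- !(variants$consequence %in% config$allowed_consequences)
  if (config$restrict_to_panel && !is.null(panel)) {
    fail_panel <- !(variants$gene %in% panel$genes)
  } else {
    fail_panel <- rep(FALSE, nv)
  }
  fail_score <- rep(FALSE, nv)
  if (!is.null(config$min_gerp) && "gerp" %in% names(variants)) {
    fail_score <- fail_score |
      (!is.na(variants$gerp) & variants$gerp < config$min_gerp)
  }
  if (!is.null(config$min_cadd) && "cadd" %in% names(variants)) {
    fail_score <- fail_score |
      (!is.na(variants$cadd) & variants$cadd < config$min_cadd)
  }
  reason <- rep(NA_character_, nv)
  reason[fail_score] <- "score"
  reason[fail_panel] <- "panel"
  reason[fail_consequence] <- "consequence"
  reason[fail_external] <- "external"
  reason[fail_internal] <- "internal"
  data.frame(pass = is.na(reason), reason = reason,
             internal_af = internal_afs, external_af = ext,
             stringsAsFactors = FALSE)
}

#' Select the qualifying variants of a cohort
#'
#' Evaluates every variant against a [filter_config()] (computing internal
#' MAFs from the cohort) and returns the retained index set together with a
#' complete per-variant audit trail and removal counts per criterion.
#'
#' If the variant table carries an in-house database AF column
#' (`af_inhouse`) that is *not* among the configured external sources, any
#' retained variant whose in-house AF meets or exceeds the external
#' threshold is flagged with a warning rather than dropped — such
#' inconsistencies between an annotation-time frequency and the filter's
#' own cohort deserve a human look, not silent removal.
#'
#' @param x a [cohort()].
#' @param config a [filter_config()].
#' @param panel optional [gene_panel()]; when supplied, the panel criterion
#'   is active regardless of `config$restrict_to_panel`.
#' @return An object of class `"qualifying_set"`: list with `idx` (retained
#'   variant indices), `internal_af` (per retained variant), `status`
#'   (full audit data.frame over all variants), `audit` (named removal
#'   counts), `config`, `panel_name`.
#' @export
select_qualifying <- function(x, config = filter_config(), panel = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(panel)) config$restrict_to_panel <- TRUE
  afs <- compute_internal_af(x)
  st <- qualifying_status(x$variants, afs, config, panel)
  idx <- which(st$pass)
  audit <- table(factor(st$reason,
                        levels = c("internal", "external", "consequence",
                                   "panel", "score")))
  if ("af_inhouse" %in% names(x$variants) &&
      !("inhouse" %in% config$external_sources)) {
    inh <- x$variants$af_inhouse[idx]
    flag <- which(!is.na(inh) & inh >= config$maf_external_max)
    if (length(flag)) {
      warning(sprintf(
        "%d qualifying variant(s) have in-house database AF >= %g (e.g. %s); retained but flagged",
        length(flag), config$maf_external_max,
        variant_key(x$variants[idx[flag[1L]], , drop = FALSE])),
        call. = FALSE)
    }
  }
  structure(list(idx = idx, internal_af = afs[idx], status = st,
                 audit = c(retained = length(idx), as.vector(audit)) |>
                   stats::setNames(c("retained", names(audit))),
                 config = config,
                 panel_name = if (is.null(panel)) NA_character_ else panel$name),
            class = "qualifying_set")
}

#' @export
print.qualifying_set <- function(x, ...) {
  cat(sprintf("<qualifying_set> %d of %d variants retained\n",
              length(x$idx), nrow(x$status)))
  removed <- x$audit[-1L]
  removed <- removed[removed > 0]
  if (length(removed)) {
    cat("  removed:", paste(sprintf("%s=%d", names(removed), removed),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Screen qualifying variants in known disease genes
#'
#' First-pass review of a qualifying set: every (case individual,
#' qualifying variant) pair in the known-gene panel, with zygosity and
#' frequencies, sorted by gene then patient id. Controls are excluded —
#' this is a diagnostic screen of the affected cohort.
#'
#' @param qualifying a [select_qualifying()] result.
#' @param x the cohort it was computed from.
#' @param known a [gene_panel()] (default: the five known KFS genes).
#' @return data.frame with columns `gene`, `patient`, `variant`, `hgvs_c`,
#'   `consequence`, `zygosity`, `internal_af`, `external_af`.
#' @export
known_gene_screen <- function(qualifying, x, known = known_kfs_genes()) {
  stopifnot(inherits(qualifying, "qualifying_set"), inherits(x, "cohort"))
  idx <- qualifying$idx
  vsub <- x$variants[idx, , drop = FALSE]
  hit <- which(vsub$gene %in% known$genes)
  rows <- list()
  case_idx <- group_index(x, "case")
  case_ids <- as.character(x$individuals$individual_id[case_idx])
  for (h in hit) {
    v <- idx[h]
    dos <- x$dosages[case_idx, v]
    w <- which(dos >= 1)
    if (!length(w)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = vsub$gene[h],
      patient = case_ids[w],
      variant = variant_key(vsub[h, , drop = FALSE]),
      hgvs_c = if ("hgvs_c" %in% names(vsub)) vsub$hgvs_c[h] else NA_character_,
      consequence = vsub$consequence[h],
      zygosity = ifelse(dos[w] >= 2, "hom", "het"),
      internal_af = qualifying$internal_af[h],
      external_af = external_af_max(vsub[h, , drop = FALSE],
                                    qualifying$config$external_sources),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), patient = character(),
                      variant = character(), hgvs_c = character(),
                      consequence = character(), zygosity = character(),
                      internal_af = double(), external_af = double(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$patient), , drop = FALSE] |>
    `rownames<-`(NULL)
}
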