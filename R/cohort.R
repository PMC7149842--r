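#' Case-control cohort container
#'
#' Bundles an individual roster, an annotated variant table and an allele
#' dosage matrix into a single object, the central data structure of the
#' package. The dosage matrix has one row per individual and one column per
#' variant, entries in `{0, 1, 2}` (copies of the alternate allele); it is
#' stored sparse ([Matrix::sparseMatrix]) because rare-variant matrices are
#' almost entirely zero.
#'
#' @param individuals data.frame with columns `individual_id` (non-empty,
#'   unique) and `group` (`"case"` or `"control"`); optional `sex`, `age`.
#' @param variants a variant table, see [as_variant_table()].
#' @param dosages integer matrix (dense or sparse), `nrow(individuals)` x
#'   `nrow(variants)`; if `NULL`, an all-zero matrix is created.
#' @param validate run the full invariant checks (switch off only in tight
#'   simulation loops where inputs are constructed by the package itself).
#' @return An object of class `"cohort"`: a list with elements
#'   `individuals`, `variants`, `dosages`.
#' @export
cohort <- function(individuals, variants, dosages = NULL, validate = TRUE) {
  individuals <- as.data.frame(individuals)
  variants <- as.data.frame(variants)
  if (is.null(dosages)) {
    dosages <- Matrix::sparseMatrix(
      i = integer(), j = integer(), x = double(),
      dims = c(nrow(individuals), nrow(variants))
    )
  }
  if (!methods::is(dosages, "sparseMatrix")) {
    dosages <- methods::as(methods::as(as.matrix(dosages), "dMatrix"),
                           "CsparseMatrix")
  }
  dimnames(dosages) <- list(individuals$individual_id, variant_key(variants))
  obj <- structure(
    list(individuals = individuals, variants = variants, dosages = dosages),
    class = "cohort"
  )
  if (validate) validate_cohort(obj)
  obj
}

#' @rdname cohort
#' @param x a `cohort` object.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ind <- x$individuals
  if (!all(c("individual_id", "group") %in% names(ind))) {
    stop("roster schema error: need columns 'individual_id' and 'group'",
         call. = FALSE)
  }
  ids <- as.character(ind$individual_id)
  if (any(!nzchar(ids)) || anyNA(ids)) {
    stop("roster validation error: empty individual_id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("roster validation error: duplicate individual_id %s",
                 sQuote(ids[duplicated(ids)][1L])), call. = FALSE)
  }
  badg <- setdiff(unique(as.character(ind$group)), c("case", "control"))
  if (length(badg)) {
    stop(sprintf("roster validation error: group must be 'case'/'control', got %s",
                 sQuote(badg[1L])), call. = FALSE)
  }
  as_variant_table(x$variants)
  key <- variant_key(x$variants)
  if (anyDuplicated(key)) {
    stop(sprintf("cohort validation error: duplicate variant key %s",
                 sQuote(key[duplicated(key)][1L])), call. = FALSE)
  }
  if (nrow(x$dosages) != nrow(ind) || ncol(x$dosages) != nrow(x$variants)) {
    stop("cohort validation error: dosage matrix dimensions do not match roster/variants",
         call. = FALSE)
  }
  vals <- unique(x$dosages@x)
  if (length(setdiff(vals, c(0, 1, 2)))) {
    stop("cohort validation error: dosages must be 0, 1 or 2", call. = FALSE)
  }
  invisible(x)
}

#' @rdname cohort
#' @export
n_individuals <- function(x) nrow(x$individuals)

#' Row indices / ids of one group
#'
#' @param x a `cohort`.
#' @param group `"case"` or `"control"`.
#' @return `group_index()` returns integer row indices into the roster and
#'   dosage matrix; `group_ids()` the corresponding individual ids.
#' @export
group_index <- function(x, group = c("case", "control")) {
  group <- match.arg(group)
  which(x$individuals$group == group)
}

#' @rdname group_index
#' @export
group_ids <- function(x, group = c("case", "control")) {
  as.character(x$individuals$individual_id[group_index(x, group)])
}

#' @export
print.cohort <- function(x, ...) {
  ncase <- length(group_index(x, "case"))
  nctrl <- length(group_index(x, "control"))
  cat(sprintf("<cohort> %d cases, %d controls, %d variants in %d genes\n",
              ncase, nctrl, nrow(x$variants),
              length(unique(x$variants$gene))))
  invisible(x)
}

# Internal guard used by every between-group operation.
require_both_groups <- function(x) {
  if (!length(group_index(x, "case")) || !length(group_index(x, "control"))) {
    stop("cohort must contain at least one case and one control", call. = FALSE)
  }
  invisible(x)
}
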