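#' Controlled vocabulary of variant consequence classes
#'
#' The consequence labels recognised throughout the package. These follow the
#' usual exome-annotation granularity: coding point/indel classes plus the
#' three splice classes, with `"other"` as the catch-all for anything the
#' upstream annotator produced that the burden analysis does not model
#' (intronic, UTR, upstream, ...).
#'
#' @return Character vector of the ten recognised consequence labels.
#' @export
consequence_levels <- function() {
  c("missense", "synonymous", "nonsense", "frameshift",
    "inframe_insertion", "inframe_deletion",
    "splice_region", "splice_acceptor", "splice_donor", "other")
}

#' @rdname consequence_levels
#' @details `coding_consequences()` is every class except `"other"`; it is the
#'   default set admitted by [filter_config()]. Synonymous variants are
#'   deliberately included: published qualifying-variant sets in this domain
#'   retain them (e.g. synonymous VANGL1 and CHD7 variants among reported
#'   qualifying variants), so excluding them is opt-in.
#' @export
coding_consequences <- function() {
  setdiff(consequence_levels(), "other")
}

# Internal: validate a vector of consequence labels, error naming the enum.
check_consequences <- function(x, where = "consequence") {
  bad <- setdiff(unique(as.character(x)), consequence_levels())
  if (length(bad)) {
    stop(sprintf(
      "unknown %s label(s): %s; recognised labels are: %s",
      where, paste(sQuote(bad), collapse = ", "),
      paste(consequence_levels(), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}
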