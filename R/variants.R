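#' Construct / validate an annotated variant table
#'
#' A variant table is a plain `data.frame` with one row per biallelic variant
#' and at least the columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`. Optional columns: `transcript`, `hgvs_c`, `hgvs_p`;
#' external allele-frequency columns named `af_<source>` (e.g. `af_exac`,
#' `af_gnomad`), with `NA` meaning the variant is absent ("novel") in that
#' reference population; pathogenicity annotations `gerp`, `cadd` (numeric)
#' and `sift`, `polyphen2`, `mutationtaster` (labels). Coordinates are
#' 1-based VCF-style; variant identity is the tuple (chrom, pos, ref, alt).
#'
#' @param variants data.frame to validate (and lightly coerce: `pos` to
#'   integer, `gene` uppercased).
#' @return The validated data.frame, invisibly classed as before.
#' @export
as_variant_table <- function(variants) {
  stopifnot(is.data.frame(variants))
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing <- setdiff(required, names(variants))
  if (length(missing)) {
    stop(sprintf("variant table schema error: missing column(s) %s",
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  variants$gene <- toupper(as.character(variants$gene))
  variants$consequence <- as.character(variants$consequence)
  check_consequences(variants$consequence)
  if (nrow(variants)) {
    if (any(variants$pos < 1L, na.rm = TRUE) || anyNA(variants$pos)) {
      stop("variant table validation error: 'pos' must be >= 1 and non-missing",
           call. = FALSE)
    }
    same <- variants$ref == variants$alt
    if (any(same)) {
      stop(sprintf("variant table validation error: ref == alt at row %d",
                   which(same)[1L]), call. = FALSE)
    }
    for (col in af_columns(variants)) {
      v <- variants[[col]]
      bad <- which(!is.na(v) & (v < 0 | v > 1))
      if (length(bad)) {
        stop(sprintf(
          "variant table validation error: %s = %g outside [0,1] at row %d",
          col, v[bad[1L]], bad[1L]), call. = FALSE)
      }
    }
  }
  invisible(variants)
}

#' Variant identity keys
#'
#' @param variants a variant table.
#' @return character vector `chrom:pos:ref:alt`, one per row.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

# Names of the external-AF columns present in a variant table.
af_columns <- function(variants) {
  grep("^af_", names(variants), value = TRUE)
}

#' Maximum external allele frequency over chosen sources
#'
#' Returns, per variant, the maximum allele frequency over the requested
#' external sources that are present; a variant absent from every requested
#' source ("novel") scores 0, reflecting that it has not been observed in any
#' reference population.
#'
#' @param variants a variant table (or a single-row slice of one).
#' @param sources character vector of source names; source `s` is read from
#'   column `af_<s>` (lower-cased). Sources whose column does not exist are
#'   ignored.
#' @return numeric vector, one value per row, each in `[0, 1]`.
#' @export
#' @examples
#' v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
#'                 gene = "GDF6", consequence = "missense",
#'                 af_exac = 3e-05, af_gnomad = NA_real_)
#' external_af_max(v, c("exac", "gnomad"))  # 3e-05
external_af_max <- function(variants, sources = c("exac", "gnomad")) {
  cols <- intersect(paste0("af_", tolower(sources)), names(variants))
  if (!length(cols) || !nrow(variants)) {
    return(rep(0, nrow(variants)))
  }
  m <- as.matrix(variants[, cols, drop = FALSE])
  m[is.na(m)] <- -Inf
  out <- apply(m, 1L, max)
  out[!is.finite(out)] <- 0
  pmax(out, 0)
}
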