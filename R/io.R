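#' Read an annotated variant table (TSV)
#'
#' The supported dialect is UTF-8, tab-separated, one data row per variant.
#' Mandatory columns: `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`.
#' Optional: `transcript`, `hgvs_c`, `hgvs_p`; external allele-frequency
#' columns, either canonical (`af_exac`, `af_gnomad`, `af_inhouse`, ...,
#' i.e. `af_<source>`) or annotator-style aliases (`ExAC_AF`, `gnomAD_AF`,
#' any `<Source>_AF`, case-insensitive); score columns `gerp`, `cadd`,
#' `sift`, `polyphen2`, `mutationtaster`; and a `carriers` column listing
#' carrier individual ids separated by `;`, with an optional `:hom` suffix
#' for homozygotes (e.g. `"CS216;CTRL007:hom"`).
#'
#' Missing cells are empty, `"."`, or `"NA"`; in AF columns the literal
#' `"Novel"` (any case) also means missing — the variant is absent from that
#' reference population and is treated as frequency 0 by the filters.
#'
#' @param path TSV file.
#' @return A validated variant table (see [as_variant_table()]) with a
#'   `carriers` character column (possibly empty strings). Zero data rows
#'   give a zero-row table.
#' @export
read_annotated_variants <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("variant file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character())
  names(df) <- canonical_variant_columns(names(df))
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("variant TSV schema error: missing column(s) %s",
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  if (!nrow(df)) {
    df$pos <- integer()
    if (!"carriers" %in% names(df)) df$carriers <- character()
    return(as_variant_table(df))
  }
  na_general <- function(x) replace(x, x %in% c("", ".", "NA"), NA_character_)
  for (col in setdiff(names(df), "carriers")) df[[col]] <- na_general(df[[col]])
  for (col in af_columns(df)) {
    x <- df[[col]]
    x[!is.na(x) & tolower(x) == "novel"] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad)) {
      stop(sprintf("variant TSV validation error: non-numeric %s %s at row %d",
                   col, sQuote(x[bad[1L]]), bad[1L]), call. = FALSE)
    }
    out <- which(!is.na(num) & (num < 0 | num > 1))
    if (length(out)) {
      stop(sprintf(
        "variant TSV validation error: %s = %s outside [0,1] at row %d",
        col, x[out[1L]], out[1L]), call. = FALSE)
    }
    df[[col]] <- num
  }
  for (col in intersect(c("gerp", "cadd"), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (!"carriers" %in% names(df)) df$carriers <- ""
  df$carriers[is.na(df$carriers)] <- ""
  as_variant_table(df)
}

# Map annotator-style column aliases onto the canonical schema.
canonical_variant_columns <- function(nm) {
  low <- tolower(nm)
  out <- low
  alias <- c(chromosome = "chrom", chr = "chrom", position = "pos",
             gene_symbol = "gene", symbol = "gene",
             variant_type = "consequence", zygosity = "zygosity")
  hit <- low %in% names(alias)
  out[hit] <- alias[low[hit]]
  # "<Source>_AF" -> "af_<source>"; leaves canonical "af_*" untouched
  src <- grepl("_af$", low) & !grepl("^af_", low)
  out[src] <- paste0("af_", sub("_af$", "", low[src]))
  out
}

#' Assemble a cohort from a variant table with carriers and a roster
#'
#' Resolves the `carriers` column of [read_annotated_variants()] output
#' (ids separated by `;`, `:hom` suffix for dosage 2) against a roster to
#' build the dosage matrix.
#'
#' @param variants variant table with a `carriers` column.
#' @param individuals roster data.frame (`individual_id`, `group`).
#' @return A [cohort()].
#' @export
build_cohort <- function(variants, individuals) {
  variants <- as_variant_table(variants)
  ids <- as.character(individuals$individual_id)
  i <- integer(); j <- integer(); x <- double()
  if (nrow(variants) && "carriers" %in% names(variants)) {
    for (v in seq_len(nrow(variants))) {
      spec <- variants$carriers[v]
      if (is.na(spec) || !nzchar(spec)) next
      toks <- strsplit(spec, ";", fixed = TRUE)[[1L]]
      toks <- trimws(toks)
      hom <- grepl(":hom$", toks)
      who <- sub(":(hom|het)$", "", toks)
      idx <- match(who, ids)
      if (anyNA(idx)) {
        stop(sprintf("carrier id %s (variant row %d) not in roster",
                     sQuote(who[which(is.na(idx))[1L]]), v), call. = FALSE)
      }
      i <- c(i, idx); j <- c(j, rep.int(v, length(idx)))
      x <- c(x, ifelse(hom, 2, 1))
    }
  }
  dos <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(length(ids), nrow(variants)))
  cohort(individuals, variants, dos)
}

#' Read / write a cohort as a TSV pair
#'
#' `write_cohort()` emits the variant table (with a reconstructed `carriers`
#' column) and the roster as two tab-separated files; `read_cohort()`
#' reverses it. External AFs are written with 10 significant digits so the
#' round trip preserves them; the files carry no timestamps and are
#' byte-reproducible.
#'
#' @param x a [cohort()].
#' @param variants_path,roster_path file paths.
#' @return `read_cohort()` returns a [cohort()]; `write_cohort()` the paths,
#'   invisibly.
#' @export
write_cohort <- function(x, variants_path, roster_path) {
  v <- x$variants
  v$carriers <- carriers_string(x)
  num <- vapply(v, is.numeric, logical(1L)) & names(v) != "pos"
  for (col in names(v)[num]) {
    v[[col]] <- ifelse(is.na(v[[col]]), NA, sprintf("%.10g", v[[col]]))
  }
  write_tsv(v, variants_path)
  write_tsv(x$individuals, roster_path)
  invisible(c(variants_path, roster_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(variants_path, roster_path) {
  variants <- read_annotated_variants(variants_path)
  roster <- utils::read.delim(roster_path, header = TRUE, sep = "\t",
                              quote = "", colClasses = "character")
  build_cohort(variants, roster)
}

# Reconstruct the carriers column ("id" / "id:hom", ';'-joined) from dosages.
carriers_string <- function(x) {
  ids <- as.character(x$individuals$individual_id)
  vapply(seq_len(nrow(x$variants)), function(v) {
    d <- x$dosages[, v]
    w <- which(d >= 1)
    if (!length(w)) return("")
    paste0(ids[w], ifelse(d[w] >= 2, ":hom", ""), collapse = ";")
  }, character(1L))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read genotypes from a VCF with a sidecar annotation table
#'
#' Parses a VCF (v4.x, uncompressed or bgzipped; `GT` must be present in
#' FORMAT) with `VariantAnnotation`, splits multiallelic sites into
#' biallelic records, converts GT calls to alternate-allele dosages
#' (`0/1`, `1/0` and phased equivalents to 1; `1/1` to 2; missing `./.` to 0
#' with a warning reporting the count), and attaches annotations joined on
#' (chrom, pos, ref, alt). VCF records without an annotation row get
#' `consequence = "other"`, an empty gene symbol and no external AFs.
#'
#' @param path VCF file.
#' @param annotations variant table (or path to one, read with
#'   [read_annotated_variants()]); its `carriers` column, if any, is ignored
#'   — genotypes come from the VCF.
#' @param individuals roster data.frame or TSV path. Every VCF sample must
#'   appear in the roster; roster members absent from the VCF get all-zero
#'   dosages.
#' @return A [cohort()].
#' @export
read_vcf <- function(path, annotations, individuals) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf() requires the VariantAnnotation package", call. = FALSE)
  }
  if (is.character(annotations)) {
    annotations <- read_annotated_variants(annotations)
  }
  if (is.character(individuals)) {
    individuals <- utils::read.delim(individuals, header = TRUE, sep = "\t",
                                     quote = "", colClasses = "character")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotypes", call. = FALSE)
  samples <- colnames(gt)
  roster_ids <- as.character(individuals$individual_id)
  absent <- setdiff(samples, roster_ids)
  if (length(absent)) {
    stop(sprintf("roster error: VCF sample(s) %s not in the roster",
                 paste(sQuote(absent), collapse = ", ")), call. = FALSE)
  }
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  pos <- BiocGenerics::start(gr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)

  out_chrom <- character(); out_pos <- integer()
  out_ref <- character(); out_alt <- character()
  di <- integer(); dj <- integer(); dx <- double()
  n_missing <- 0L
  col <- 0L
  for (r in seq_along(gr)) {
    alts <- as.character(altl[[r]])
    alts <- alts[nzchar(alts) & alts != "."]
    if (!length(alts)) next
    toks <- strsplit(gt[r, ], "[/|]")
    for (ai in seq_along(alts)) {
      col <- col + 1L
      out_chrom[col] <- chrom[r]; out_pos[col] <- pos[r]
      out_ref[col] <- ref[r]; out_alt[col] <- alts[ai]
      for (s in seq_along(samples)) {
        tk <- toks[[s]]
        if (any(tk == ".")) { if (ai == 1L) n_missing <- n_missing + 1L; next }
        num <- suppressWarnings(as.integer(tk))
        if (anyNA(num)) {
          stop(sprintf("malformed GT %s for sample %s at VCF record %d",
                       sQuote(gt[r, s]), samples[s], r), call. = FALSE)
        }
        d <- sum(num == ai)
        if (d > 0) {
          di <- c(di, match(samples[s], roster_ids))
          dj <- c(dj, col); dx <- c(dx, d)
        }
      }
    }
  }
  if (n_missing > 0L) {
    warning(sprintf("%d missing genotype call(s) read as dosage 0", n_missing),
            call. = FALSE)
  }
  vt <- data.frame(chrom = out_chrom, pos = out_pos, ref = out_ref,
                   alt = out_alt, stringsAsFactors = FALSE)
  key <- paste(vt$chrom, vt$pos, vt$ref, vt$alt, sep = ":")
  ann_key <- variant_key(annotations)
  m <- match(key, ann_key)
  extra <- setdiff(names(annotations),
                   c("chrom", "pos", "ref", "alt", "carriers"))
  for (colname in extra) {
    val <- annotations[[colname]][m]
    vt[[colname]] <- val
  }
  if (!"gene" %in% names(vt)) vt$gene <- NA_character_
  if (!"consequence" %in% names(vt)) vt$consequence <- NA_character_
  vt$gene[is.na(vt$gene)] <- ""
  vt$consequence[is.na(vt$consequence)] <- "other"
  dos <- Matrix::sparseMatrix(i = di, j = dj, x = dx,
                              dims = c(length(roster_ids), nrow(vt)))
  cohort(individuals, vt, dos)
}

#' Write / read burden-scan and oligogenic result tables
#'
#' Deterministic TSVs: fixed column order, rows in scan rank order,
#' p-values in scientific notation with 6 significant digits. Integer count
#' columns round-trip exactly through `read_burden_table()`.
#'
#' @param results a `gene_burden_result` data.frame from
#'   [gene_burden_scan()].
#' @param path output file.
#' @param allow_empty permit a header-only file for zero results.
#' @export
write_burden_table <- function(results, path, allow_empty = FALSE) {
  if (!nrow(results) && !allow_empty) {
    stop("refusing to write an empty burden table (set allow_empty = TRUE)",
         call. = FALSE)
  }
  out <- as.data.frame(results)
  for (col in c("chi2", "p_chi2", "p_fisher_one_sided", "p_fisher_two_sided")) {
    out[[col]] <- sprintf("%.5e", out[[col]])
  }
  write_tsv(out, path)
}

#' @rdname write_burden_table
#' @export
read_burden_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  for (col in intersect(c("case_n", "case_carriers", "control_n",
                          "control_carriers", "rank"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' @rdname write_burden_table
#' @param result an `oligogenic_result` from [oligogenic_enrichment()].
#' @details `write_oligogenic_table()` writes a `#`-prefixed summary line
#'   (counts, proportions and the three p-values) followed by the
#'   per-individual gene-combination rows.
#' @export
write_oligogenic_table <- function(result, path) {
  hdr <- sprintf(
    paste0("# min_genes=%d\tcase_carriers=%d\tcase_n=%d\tcase_pct=%.1f\t",
           "control_carriers=%d\tcontrol_n=%d\tchi2=%.5e\tp_chi2=%.5e\t",
           "p_fisher_one_sided=%.5e\tp_fisher_two_sided=%.5e"),
    result$min_genes, result$table$a, result$table$a + result$table$b,
    result$case_pct, result$table$c, result$table$c + result$table$d,
    result$chi2, result$p_chi2, result$p_fisher_one_sided,
    result$p_fisher_two_sided)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(result$combinations, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
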