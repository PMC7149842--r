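#' Gene panels
#'
#' A gene panel is a named, case-normalised set of gene symbols. Two panels
#' ship with the package under `inst/extdata`: the 5 known Klippel-Feil
#' syndrome (KFS) genes, and a 96-gene candidate panel for vertebral
#' segmentation defects. The candidate file is a *synthetic stand-in*: it
#' contains the 21 symbols the source study names explicitly, padded to 96
#' with somitogenesis / vertebral-development genes, because the full
#' published list is not redistributable here. Counts and orderings computed
#' on the bundled example cohort do not depend on the identity of the
#' padding genes (they carry no case variants).
#'
#' @param genes character vector of symbols; upper-cased and de-duplicated.
#' @param name label for the panel.
#' @return An object of class `"gene_panel"`.
#' @export
gene_panel <- function(genes, name = "panel") {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene panel", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a gene panel from a plain-text file
#'
#' One symbol per line; `#` starts a comment (whole-line or trailing);
#' blank lines ignored; symbols upper-cased and de-duplicated.
#'
#' @param path file to read.
#' @param name panel label (default: file name without extension).
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("gene panel file not found: %s", path), call. = FALSE)
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop(sprintf("gene panel file %s is empty after removing comments", path),
         call. = FALSE)
  }
  gene_panel(lines, name = name)
}

#' The five known KFS genes
#'
#' GDF6, MEOX1, GDF3, MYO18B and RIPPLY2 — the genes previously reported as
#' causal for Klippel-Feil syndrome, screened first by
#' [known_gene_screen()].
#'
#' @return A [gene_panel()] named `"known_kfs"`.
#' @export
known_kfs_genes <- function() {
  read_gene_panel(system.file("extdata", "panel_known_kfs.txt",
                              package = "oligoburden"),
                  name = "known_kfs")
}

#' @rdname known_kfs_genes
#' @details `candidate_panel()` loads the bundled 96-gene candidate panel
#'   (synthetic stand-in, see [gene_panel()]).
#' @export
candidate_panel <- function() {
  read_gene_panel(system.file("extdata", "panel_candidate96_synthetic.txt",
                              package = "oligoburden"),
                  name = "candidate96")
}
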