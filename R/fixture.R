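# Bundled example cohort ------------------------------------------------
#
# A 37-case / 534-control exome cohort whose qualifying-variant marginals
# match a published Klippel-Feil syndrome burden study: the named case
# carriers and their variants (three MYO18B variants in the known-gene
# screen; thirteen variants across BAZ1B/FREM2/SUFU/VANGL1/KMT2D; the
# oligogenic gene combinations of seven patients), published per-gene
# control carrier counts for the five headline genes, and exactly 30
# controls carrying qualifying variants in >= 2 distinct panel genes.
# Everything not pinned by the published counts (control identities,
# synthetic variant coordinates for variants without printed positions,
# external AFs of synthetic variants) is generated deterministically from
# the seed and cannot influence any count-based statistic.

# The 21 genes named in the source study; the variant tables below.
fixture_case_variants <- function() {
  # printed variants with full coordinates (the three known-gene MYO18B
  # variants, then the thirteen variants of the five associated genes)
  printed <- data.frame(
    patient = c("CS132", "CS1015", "CS1049",
                "CS63", "CS216", "CS519",
                "CS193", "CS1049", "OS1056",
                "CS488", "CS1162", "CS1210",
                "CS63", "CS132", "CS1130", "CS927"),
    gene = c("MYO18B", "MYO18B", "MYO18B",
             "BAZ1B", "BAZ1B", "BAZ1B",
             "FREM2", "FREM2", "FREM2",
             "KMT2D", "KMT2D", "KMT2D",
             "SUFU", "SUFU", "VANGL1", "VANGL1"),
    consequence = c("splice_region", "missense", "missense",
                    "inframe_insertion", "missense", "missense",
                    "missense", "missense", "missense",
                    "missense", "missense", "missense",
                    "missense", "splice_region", "synonymous", "missense"),
    chrom = c("22", "22", "22", "7", "7", "7", "13", "13", "13",
              "12", "12", "12", "10", "10", "1", "1"),
    pos = c(26219648L, 26164545L, 26299670L,
            72861616L, 72912871L, 72892427L,
            39452441L, 39450454L, 39424205L,
            49425124L, 49444297L, 49432200L,
            104375107L, 104375165L, 116206326L, 116227985L),
    ref = c("A", "T", "G", "A", "A", "G", "T", "C", "A",
            "G", "C", "C", "G", "C", "G", "C"),
    alt = c("G", "C", "A", "AGGAGGAGGAGGAAGAAGA", "G", "A", "C", "T", "T",
            "A", "T", "T", "A", "T", "A", "G"),
    transcript = c(NA, NA, NA, "NM_032408.3", "NM_032408.3", "NM_032408.3",
                   "NM_207361.4", "NM_207361.4", "NM_207361.4",
                   "NM_003482.3", "NM_003482.3", "NM_003482.3",
                   "NM_016169.3", "NM_016169.3", "NM_138959.2",
                   "NM_138959.2"),
    hgvs_c = c("c.2695+3A>G", "c.662T>C", "c.5020G>A",
               "c.3804_3821dupGGAGGAGGAGGAAGAAGA", "c.527A>G", "c.1364G>A",
               "c.8842T>C", "c.8479C>T", "c.6410A>T",
               "c.13364G>A", "c.3074C>T", "c.8939C>T",
               "c.1105G>A", "c.1157+6C>T", "c.249G>A", "c.1151C>G"),
    hgvs_p = c(NA, "p.Leu221Pro", "p.Gly1674Arg",
               "p.Glu1268_Glu1273dup", "p.Lys176Arg", "p.Arg455Gln",
               "p.Tyr2948His", "p.Arg2827Cys", "p.Tyr2137Phe",
               "p.Arg4455His", "p.Ser1025Leu", "p.Ala2980Val",
               "p.Val369Ile", NA, "p.Ser83=", "p.Pro384Arg"),
    gerp = c(NA, NA, NA, NA, 5.26, 5.56, 0.57, 3.79, 5.79,
             5.57, 3.4, 2.77, 5.21, NA, NA, 5.44),
    cadd = c(NA, NA, NA, NA, 17.03, 11.17, 25.468, 18.07, 17.11,
             13.45, 6.896, 11.24, 12.54, NA, NA, 25.8),
    af_exac = c(1.7e-05, 3.4e-05, 1.3e-05,
                1.6e-05, 8.2e-06, 1.6e-05,
                3.3e-05, 1.6e-05, 8.3e-06,
                5.8e-05, 5.9e-05, 1.7e-05,
                9.1e-05, 3.3e-05, 1.2e-04, 8.3e-06),
    af_gnomad = c(NA, 3.24e-05, 3.232e-05, rep(NA, 13)),
    af_inhouse = c(0.0029, rep(NA, 15)),
    stringsAsFactors = FALSE
  )
  # oligogenic partner variants whose genomic coordinates were not printed:
  # positions here are deterministic synthetic stand-ins near the real loci
  extra <- data.frame(
    patient = c("CS63", "CS63", "CS132", "CS587", "CS587", "CS587",
                "CS676", "CS676", "CS519", "CS1015", "CS1015"),
    gene = c("GRIP1", "TBX6", "WNT7A", "FUZ", "MAP3K7", "POR",
             "CHD7", "FRAS1", "COG1", "ANKRD11", "HOXD13"),
    consequence = c("splice_acceptor", "missense", "missense", "missense",
                    "missense", "missense", "synonymous", "missense",
                    "missense", "missense", "missense"),
    chrom = c("12", "16", "3", "19", "6", "7", "8", "4", "17", "16", "2"),
    pos = c(66741320L, 30097114L, 13896012L, 50312208L, 91224506L,
            75585130L, 61693427L, 79241502L, 71189308L, 89350702L,
            176957601L),
    ref = c("G", "C", "C", "C", "G", "C", "C", "G", "C", "G", "G"),
    alt = c("A", "T", "T", "A", "A", "T", "T", "A", "T", "T", "A"),
    transcript = NA_character_,
    hgvs_c = c("c.1043-1G>A", "c.499C>T", "c.83C>T", "c.819C>A",
               "c.1115G>A", "c.1798C>T", "c.4008C>T", "c.7423G>A",
               "c.739C>T", "c.6067G>T", "c.814G>A"),
    hgvs_p = c(NA, "p.Arg167Cys", "p.Ser28Leu", "p.Asp273Glu",
               "p.Arg372His", "p.Arg600Trp", "p.Ile1336=", "p.Glu2475Lys",
               "p.His247Tyr", "p.Ala2023Ser", "p.Val272Ile"),
    gerp = NA_real_, cadd = NA_real_,
    af_exac = c(1.1e-05, 2.4e-05, 1.9e-05, 3.1e-05, 1.4e-05, 2.6e-05,
                4.2e-05, 2.2e-05, 1.2e-05, 3.7e-05, 2.9e-05),
    af_gnomad = NA_real_, af_inhouse = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(printed, extra)
}

# Control carrier counts: the five published counts, plus null-expectation
# counts round(534 * a / 37) for the genes whose control columns were not
# printed, so that those genes sit near chi-square p = 1 and the published
# top-5 ordering is a property of the data, not of the code.
fixture_control_counts <- function() {
  c(BAZ1B = 1L, FREM2 = 5L, SUFU = 2L, VANGL1 = 4L, KMT2D = 11L,
    MYO18B = 43L,                         # 3 case carriers -> round(534*3/37)
    GRIP1 = 14L, TBX6 = 14L, WNT7A = 14L, FUZ = 14L, MAP3K7 = 14L,
    POR = 14L, CHD7 = 14L, FRAS1 = 14L, COG1 = 14L, ANKRD11 = 14L,
    HOXD13 = 14L)                         # 1 case carrier -> round(534/37)
}

# The 15 panel genes used to plant the 30 multi-gene control carriers
# (4 control carriers each; 30 controls x 2 genes = 15 genes x 4).
fixture_multigene_genes <- function() {
  c("DLL3", "MESP2", "LFNG", "HES7", "TBX1", "TBXT", "DLL1", "DLL4",
    "NOTCH1", "NOTCH2", "JAG1", "JAG2", "PAX1", "PAX9", "SHH")
}

# chrom/base-position map for genes that receive synthetic control variants
fixture_gene_locus <- function() {
  named <- list(
    BAZ1B = c("7", 72800000), FREM2 = c("13", 39400000),
    SUFU = c("10", 104300000), VANGL1 = c("1", 116200000),
    KMT2D = c("12", 49400000), MYO18B = c("22", 26100000),
    GRIP1 = c("12", 66700000), TBX6 = c("16", 30090000),
    WNT7A = c("3", 13890000), FUZ = c("19", 50300000),
    MAP3K7 = c("6", 91220000), POR = c("7", 75580000),
    CHD7 = c("8", 61690000), FRAS1 = c("4", 79240000),
    COG1 = c("17", 71180000), ANKRD11 = c("16", 89340000),
    HOXD13 = c("2", 176950000)
  )
  mg <- fixture_multigene_genes()
  for (i in seq_along(mg)) {
    named[[mg[i]]] <- c(as.character(i), 50000000 + i * 100000)
  }
  named
}

#' Bundled KFS-scale example cohort
#'
#' Deterministically builds the 37-case / 534-control cohort used throughout
#' the documentation and tests. Its qualifying-variant marginals reproduce a
#' published KFS exome burden design exactly: per-gene case carriers from
#' the named patients, published control carrier counts for the five
#' headline genes (BAZ1B 1, FREM2 5, SUFU 2, VANGL1 4, KMT2D 11), three
#' MYO18B variants among the known KFS genes, the seven multi-gene case
#' carriers with their gene combinations, and exactly 30 multi-gene
#' control carriers. Every variant is a singleton heterozygote — with 571
#' individuals a variant with two carriers would already exceed the
#' internal MAF < 0.001 criterion — so every planted variant qualifies
#' under [filter_config()] defaults.
#'
#' The same seed always yields the identical cohort (the function saves and
#' restores the caller's RNG state).
#'
#' @param seed integer seed controlling control-carrier identities and
#'   synthetic external AFs (none of which affect any count statistic).
#' @return A [cohort()].
#' @export
#' @examples
#' coh <- kfs_fixture_cohort(seed = 1)
#' coh
kfs_fixture_cohort <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  case_v <- fixture_case_variants()
  named_cases <- unique(case_v$patient)
  n_extra <- 37L - length(named_cases)
  case_ids <- c(named_cases, sprintf("KFS%02d", seq_len(n_extra)))
  ctrl_ids <- sprintf("CTRL%03d", seq_len(534L))
  roster <- data.frame(
    individual_id = c(case_ids, ctrl_ids),
    group = c(rep("case", 37L), rep("control", 534L)),
    stringsAsFactors = FALSE
  )

  counts <- fixture_control_counts()
  mg_genes <- fixture_multigene_genes()
  n_single <- sum(counts)
  picked <- sample(534L, n_single + 30L)    # distinct control indices
  single_ctrl <- picked[seq_len(n_single)]
  multi_ctrl <- picked[n_single + seq_len(30L)]

  locus <- fixture_gene_locus()
  syn_variant <- function(gene, k) {
    lc <- locus[[gene]]
    data.frame(patient = NA_character_, gene = gene,
               consequence = "missense", chrom = lc[1L],
               pos = as.integer(as.numeric(lc[2L]) + 13L * k),
               ref = "A", alt = "G", transcript = NA_character_,
               hgvs_c = NA_character_, hgvs_p = NA_character_,
               gerp = NA_real_, cadd = NA_real_,
               af_exac = stats::runif(1L, 0, 5e-05),
               af_gnomad = NA_real_, af_inhouse = NA_real_,
               stringsAsFactors = FALSE)
  }

  ctrl_rows <- list()
  carriers <- character()
  pos_ctr <- stats::setNames(rep(0L, length(locus)), names(locus))
  take <- 0L
  for (gene in names(counts)) {
    for (j in seq_len(counts[[gene]])) {
      take <- take + 1L
      pos_ctr[gene] <- pos_ctr[gene] + 1L
      ctrl_rows[[length(ctrl_rows) + 1L]] <- syn_variant(gene, pos_ctr[gene])
      carriers <- c(carriers, ctrl_ids[single_ctrl[take]])
    }
  }
  # 30 multi-gene controls: control i carries the (2i-1)-th and 2i-th gene
  # of the 15-gene cycle, so consecutive (hence distinct) genes and exactly
  # 4 carriers per gene
  for (i in seq_len(30L)) {
    for (slot in c(2L * i - 1L, 2L * i)) {
      gene <- mg_genes[((slot - 1L) %% 15L) + 1L]
      pos_ctr[gene] <- pos_ctr[gene] + 1L
      ctrl_rows[[length(ctrl_rows) + 1L]] <- syn_variant(gene, pos_ctr[gene])
      carriers <- c(carriers, ctrl_ids[multi_ctrl[i]])
    }
  }
  ctrl_v <- do.call(rbind, ctrl_rows)
  ctrl_v$patient <- carriers

  allv <- rbind(case_v, ctrl_v)
  allv$carriers <- allv$patient
  allv$patient <- NULL
  build_cohort(allv, roster)
}
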