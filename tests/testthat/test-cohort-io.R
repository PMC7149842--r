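# Domain containers and readers/writers.

test_that("read_annotated_variants parses the documented dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tgene\tconsequence\thgvs_c\tExAC_AF\tgnomAD_AF\tcarriers",
    "7\t72912871\tA\tG\tBAZ1B\tmissense\tc.527A>G\t0.0000082\tNovel\tCS216",
    "1\t100\tA\tT\tgdf6\tsynonymous\tc.1A>T\t.\t0.00012\tP1;P2:hom",
    "2\t200\tC\tG\tPAX1\tother\t.\t\t\t"
  ), path)
  v <- read_annotated_variants(path)
  expect_equal(nrow(v), 3L)
  expect_equal(v$af_exac, c(8.2e-06, NA, NA))        # "Novel"/"."/"" absent
  expect_equal(v$af_gnomad, c(NA, 1.2e-04, NA))
  expect_equal(v$gene[2], "GDF6")                     # case-normalised
  expect_equal(v$carriers, c("CS216", "P1;P2:hom", ""))

  roster <- data.frame(individual_id = c("CS216", "P1", "P2"),
                       group = c("case", "case", "control"))
  coh <- build_cohort(v, roster)
  expect_equal(as.vector(coh$dosages[, 2]), c(0, 1, 2))  # het and hom
})

test_that("read_annotated_variants error paths name the problem", {
  miss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tref\talt\tgene\tconsequence", "1\tA\tG\tX\tmissense"),
             miss)
  expect_error(read_annotated_variants(miss), "'pos'")

  badaf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgene\tconsequence\taf_exac",
               "1\t5\tA\tG\tX\tmissense\t1.7"), badaf)
  expect_error(read_annotated_variants(badaf), "outside \\[0,1\\] at row 1")

  badcons <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgene\tconsequence",
               "1\t5\tA\tG\tX\tstopgain"), badcons)
  expect_error(read_annotated_variants(badcons), "missense")  # lists the enum

  hdr_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt\tgene\tconsequence", hdr_only)
  expect_equal(nrow(read_annotated_variants(hdr_only)), 0L)
})

test_that("cohort TSV round-trip preserves dosages, AFs and consequences", {
  coh <- toy_cohort()
  vp <- withr::local_tempfile(fileext = ".tsv")
  rp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, vp, rp)
  back <- read_cohort(vp, rp)
  expect_equal(as.matrix(back$dosages), as.matrix(coh$dosages))
  expect_equal(back$variants$af_exac, coh$variants$af_exac, tolerance = 1e-10)
  expect_equal(back$variants$consequence, coh$variants$consequence)
  expect_equal(back$individuals$group, coh$individuals$group)
  # and again for the (much larger) bundled cohort, exercising sparse paths
  coh2 <- fixture_quiet(seed = 3)
  write_cohort(coh2, vp, rp)
  back2 <- read_cohort(vp, rp)
  expect_equal(as.matrix(back2$dosages), as.matrix(coh2$dosages))
  expect_equal(back2$variants$af_exac, coh2$variants$af_exac,
               tolerance = 1e-10)
})

test_that("cohort validation catches structural errors", {
  roster <- data.frame(individual_id = c("a", "a"),
                       group = c("case", "control"))
  v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                  gene = "X", consequence = "missense")
  expect_error(cohort(roster, v), "duplicate individual_id")
  roster2 <- data.frame(individual_id = c("a", "b"),
                        group = c("case", "control"))
  v2 <- rbind(v, v)
  expect_error(cohort(roster2, v2), "duplicate variant key")
  expect_error(build_cohort(transform(v, carriers = "nobody"), roster2),
               "not in roster")
})

test_that("gene panels normalise, deduplicate and reject empties", {
  p <- withr::local_tempfile()
  writeLines(c("# known genes", "GDF6", "MEOX1", "GDF3", "MYO18B", "RIPPLY2"),
             p)
  panel <- read_gene_panel(p, "known")
  expect_setequal(panel$genes, c("GDF6", "MEOX1", "GDF3", "MYO18B", "RIPPLY2"))

  writeLines(c("bAz1b", "BAZ1B"), p)
  expect_length(read_gene_panel(p)$genes, 1L)

  writeLines(c("# only", "# comments"), p)
  expect_error(read_gene_panel(p), "empty")

  expect_length(candidate_panel()$genes, 96L)
  expect_length(known_kfs_genes()$genes, 5L)
  expect_true(all(known_kfs_genes()$genes %in% candidate_panel()$genes))
})

test_that("burden/oligogenic tables round-trip and respect empty flags", {
  coh <- fixture_quiet(seed = 2)
  panel <- candidate_panel()
  q <- select_fixture_qualifying(coh, panel)
  scan <- gene_burden_scan(coh, panel, q)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_burden_table(scan, path)
  back <- read_burden_table(path)
  expect_equal(nrow(back), 96L)
  expect_equal(back$case_carriers, scan$case_carriers)
  expect_equal(back$control_carriers, scan$control_carriers)
  expect_equal(back$rank, scan$rank)

  one <- scan[1, , drop = FALSE]
  class(one) <- class(scan)
  write_burden_table(one, path)
  expect_length(readLines(path), 2L)  # header + row
  expect_error(write_burden_table(scan[0, ], path), "empty")

  hits <- genes_hit_per_individual(coh, q, panel)
  olig <- oligogenic_enrichment(coh, hits)
  write_oligogenic_table(olig, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# min_genes=2\tcase_carriers=7")
  expect_equal(length(lines), 2L + nrow(olig$combinations))
})
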