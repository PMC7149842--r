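# Qualifying-variant filter.

test_that("compute_internal_af folds to a minor allele frequency", {
  coh <- toy_cohort()  # 7 individuals -> 14 chromosomes
  expect_equal(compute_internal_af(coh, 1), 2 / 14)   # two het carriers
  expect_equal(compute_internal_af(coh, 2), 2 / 14)   # one hom carrier
  expect_equal(compute_internal_af(coh, 3), 1 / 14)
  expect_error(compute_internal_af(coh, 99), "out of range")

  # one het among 571 individuals: the canonical singleton frequency
  n <- 571
  roster <- data.frame(individual_id = sprintf("i%03d", 1:n),
                       group = rep(c("case", "control"), c(37, 534)))
  v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G", gene = "X",
                  consequence = "missense", carriers = "i001")
  coh1 <- build_cohort(v, roster)
  expect_equal(compute_internal_af(coh1, 1), 1 / 1142)
  # all individuals hom-alt folds to 0
  v$carriers <- paste0(sprintf("i%03d", 1:n), ":hom", collapse = ";")
  cohN <- build_cohort(v, roster)
  expect_equal(compute_internal_af(cohN, 1), 0)
})

test_that("external_af_max takes the maximum over present sources", {
  v <- data.frame(chrom = "22", pos = 1L, ref = "A", alt = "G",
                  gene = "MYO18B", consequence = "splice_region",
                  af_exac = 1.7e-05, af_gnomad = NA_real_)
  expect_equal(external_af_max(v), 1.7e-05)
  v$af_exac <- NA_real_
  expect_equal(external_af_max(v), 0)
  v$af_exac <- 3e-05; v$af_gnomad <- 1.2e-04
  expect_equal(external_af_max(v), 1.2e-04)
  expect_equal(external_af_max(v, sources = "exac"), 3e-05)
})

test_that("is_qualifying applies criteria in the fixed audit order", {
  cfg <- filter_config()
  v <- data.frame(chrom = "1", pos = 116206326L, ref = "G", alt = "A",
                  gene = "VANGL1", consequence = "synonymous",
                  af_exac = 1.2e-04)
  panel <- gene_panel(c("VANGL1", "BAZ1B"), "p")
  # published synonymous VANGL1 variant: qualifies under defaults
  res <- is_qualifying(v, 1 / 1142, cfg, panel)
  expect_true(res$pass)
  expect_true(is.na(res$reason))
  # tighter external threshold knocks it out, reason = external
  cfg2 <- filter_config(maf_external_max = 1e-04)
  expect_equal(is_qualifying(v, 1 / 1142, cfg2, panel)$reason, "external")
  # internal failure wins over later criteria
  v2 <- transform(v, consequence = "other")
  expect_equal(is_qualifying(v2, 0.01, cfg, panel)$reason, "internal")
  expect_equal(is_qualifying(v2, 1 / 1142, cfg, panel)$reason, "consequence")
  # off-panel with restriction on
  v3 <- transform(v, gene = "TTN")
  cfg3 <- filter_config(restrict_to_panel = TRUE)
  expect_equal(is_qualifying(v3, 1 / 1142, cfg3, panel)$reason, "panel")
})

test_that("select_qualifying: audit conservation, idempotence, monotonicity", {
  coh <- fixture_quiet(seed = 4)
  panel <- candidate_panel()
  q <- select_fixture_qualifying(coh, panel)
  # conservation: retained + removed = total
  expect_equal(sum(q$audit[-1L]) + q$audit[["retained"]], nrow(coh$variants))
  # fixture variants all qualify by construction
  expect_length(q$idx, nrow(coh$variants))

  # idempotence: filtering the filtered cohort changes nothing
  sub <- cohort(coh$individuals, coh$variants[q$idx, , drop = FALSE],
                coh$dosages[, q$idx, drop = FALSE])
  q2 <- select_fixture_qualifying(sub, panel)
  expect_equal(length(q2$idx), length(q$idx))

  # an injected common variant is removed
  common <- data.frame(chrom = "7", pos = 999999L, ref = "A", alt = "G",
                       gene = "BAZ1B", consequence = "missense",
                       transcript = NA, hgvs_c = NA, hgvs_p = NA,
                       gerp = NA, cadd = NA, af_exac = NA,
                       af_gnomad = 0.05, af_inhouse = NA,
                       carriers = "CTRL001")
  v <- coh$variants
  v$carriers <- ""  # dosages rebuilt below from the fixture matrix
  aug <- cohort(coh$individuals, rbind(v[, names(v)], common[, names(v)]),
                cbind(coh$dosages,
                      Matrix::sparseMatrix(i = 38L, j = 1L, x = 1,
                                           dims = c(571, 1))))
  qa <- suppressWarnings(select_qualifying(aug, filter_config(), panel))
  expect_false(nrow(aug$variants) %in% qa$idx)
  expect_equal(qa$status$reason[nrow(aug$variants)], "external")

  # monotonicity: lowering either threshold never admits a variant
  set.seed(99)
  for (thr in list(c(5e-04, 0.001), c(0.001, 5e-04), c(1e-04, 1e-04))) {
    qt <- suppressWarnings(select_qualifying(
      aug, filter_config(maf_internal_max = thr[1],
                         maf_external_max = thr[2]), panel))
    expect_true(all(qt$idx %in% qa$idx))
  }

  # identity filter returns everything
  qall <- select_qualifying(aug, filter_config(
    maf_internal_max = 1, maf_external_max = 1,
    allowed_consequences = consequence_levels()))
  expect_length(qall$idx, nrow(aug$variants))
})

test_that("the in-house AF anomaly is flagged, not dropped", {
  coh <- kfs_fixture_cohort(seed = 1)
  expect_warning(q <- select_qualifying(coh, filter_config(), candidate_panel()),
                 "in-house database AF")
  # the flagged splice-region variant stays in the qualifying set
  key <- variant_key(coh$variants)
  expect_true(match("22:26219648:A:G", key) %in% q$idx)
})

test_that("known_gene_screen reports case carriers of known genes only", {
  coh <- fixture_quiet(seed = 5)
  q <- select_fixture_qualifying(coh)
  scr <- known_gene_screen(q, coh)
  expect_equal(nrow(scr), 3L)
  expect_true(all(scr$gene == "MYO18B"))
  expect_setequal(scr$patient, c("CS132", "CS1015", "CS1049"))
  expect_true(all(scr$zygosity == "het"))

  # a known-gene variant carried only by a control is not reported
  roster <- data.frame(individual_id = c("p1", "c1"),
                       group = c("case", "control"))
  v <- data.frame(chrom = "6", pos = 10L, ref = "A", alt = "G",
                  gene = "RIPPLY2", consequence = "missense",
                  carriers = "c1")
  coh2 <- build_cohort(v, roster)
  q2 <- select_qualifying(coh2)
  expect_equal(nrow(known_gene_screen(q2, coh2)), 0L)
})
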