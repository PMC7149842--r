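# Independent oracles and small in-code fixtures shared across test files.

# Brute-force Fisher oracle: full enumeration of the hypergeometric pmf via
# stats::dhyper (independent of the package's lgamma accumulation).
oracle_fisher <- function(a, b, c, d, alternative) {
  k <- a + c
  n_case <- a + b; n_ctrl <- c + d
  support <- max(0, k - n_ctrl):min(k, n_case)
  pmf <- stats::dhyper(support, n_case, n_ctrl, k)
  if (alternative == "one_sided_enrichment") {
    sum(pmf[support >= a])
  } else {
    sum(pmf[pmf <= pmf[match(a, support)] * (1 + 1e-07)])
  }
}

# Tiny hand-built cohort: 3 cases, 4 controls, 4 variants.
#   v1 GDF6 missense: case1 het, ctrl1 het
#   v2 GDF6 synonymous: case2 hom
#   v3 MEOX1 other: case1 het
#   v4 PAX1 missense, common in gnomAD: ctrl2 het
toy_cohort <- function() {
  roster <- data.frame(
    individual_id = c("case1", "case2", "case3", "ctrl1", "ctrl2", "ctrl3",
                      "ctrl4"),
    group = rep(c("case", "control"), c(3, 4))
  )
  variants <- data.frame(
    chrom = c("1", "1", "2", "3"),
    pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A", "C"),
    gene = c("GDF6", "GDF6", "MEOX1", "PAX1"),
    consequence = c("missense", "synonymous", "other", "missense"),
    hgvs_c = c("c.1A>G", "c.2C>T", "c.3G>A", "c.4T>C"),
    af_exac = c(1e-05, NA, 2e-05, 1e-04),
    af_gnomad = c(NA, 3e-05, NA, 0.05),
    carriers = c("case1;ctrl1", "case2:hom", "case1", "ctrl2")
  )
  build_cohort(variants, roster)
}

# The fixture cohort triggers one deliberate in-house-AF warning; most tests
# only need the object.
fixture_quiet <- function(seed = 1) {
  kfs_fixture_cohort(seed = seed)
}

select_fixture_qualifying <- function(coh, panel = candidate_panel()) {
  suppressWarnings(select_qualifying(coh, filter_config(), panel))
}
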