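test_that("locus filtering applies the strict missingness and allele bounds", {
  # 10 samples, locus 1 missing in exactly 2 (20%): removed under strict <
  calls <- rbind(
    c("0/1", "0/1", "0/0", "1/1", "0/1", "0/0", "0/1", "1/1", NA, NA),
    c("0/1", "0/1", "0/0", "1/1", "0/1", "0/0", "0/1", "1/1", "0/0", NA),
    c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),
    c("0/1", "0/2", "0/3", "1/4", "2/3", "0/0", "1/1", "2/2", "3/3", "4/4")
  )
  colnames(calls) <- paste0("S", 1:10)
  loci <- data.frame(chrom = "c1", pos = c(10, 20, 30, 40), ref = "A",
                     alt = c("T", "T", "T", "C,G,TT,AA"),
                     stringsAsFactors = FALSE)
  loci$locus_id <- paste0("c1:", loci$pos)
  tab <- polybrix:::new_locus_gtable(loci, calls)
  out <- filter_loci(tab)
  # kept: only locus 2 (10% missing, 2 alleles); removed: 20% missing,
  # monomorphic, pentallelic
  expect_equal(out$loci$locus_id, "c1:20")
  att <- attr(out, "attrition")
  expect_equal(unname(att["n_in"]), 4)
  expect_equal(unname(att["n_kept"]), 1)
  expect_error(filter_loci(tab, max_missing = 1.2), "max_missing")
})

test_that("filtering agrees with a brute-force per-locus scan", {
  for (seed in c(1, 8)) {
    co <- tiny_cohort(seed = seed, n_samples = 20, n_loci = 50,
                      missing_rate = 0.25)
    tab <- cohort_genotype_table(co)
    keep <- bf_filter_keep(tab)
    out <- filter_loci(tab)
    expect_identical(out$loci$locus_id, tab$loci$locus_id[keep])
  }
})

test_that("presence/absence encoding discards dosage and propagates missing", {
  p <- write_test_vcf(c(
    "Chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0/1/1\t0/0",
    "Chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t./././.\t0/1"
  ))
  am <- encode_presence_absence(build_genotype_table(p))
  # 4x call {A,A,T,T}: both alleles present, dosage gone
  expect_equal(unname(am$presence["SA", c("Chr1:100_A", "Chr1:100_T")]),
               c(1L, 1L))
  expect_equal(unname(am$presence["SB", c("Chr1:100_A", "Chr1:100_T")]),
               c(1L, 0L))
  # missing cell propagates to every column of the locus
  expect_true(all(is.na(am$presence["SA", c("Chr1:200_G", "Chr1:200_C")])))
})

test_that("encoding equals the brute-force membership oracle", {
  for (seed in c(3, 17)) {
    co <- tiny_cohort(seed = seed, n_samples = 15, n_loci = 40,
                      missing_rate = 0.15)
    tab <- cohort_genotype_table(co)
    am <- encode_presence_absence(tab)
    oracle <- bf_presence(tab)
    expect_equal(ncol(am$presence), length(oracle))
    for (j in seq_along(oracle)) {
      key <- paste0(am$columns$locus_id[j], "#", am$columns$allele_index[j])
      expect_identical(unname(am$presence[, j]), oracle[[key]])
    }
  }
})

test_that("the Welch screen matches t.test and its closed form", {
  # identical class distributions: t = 0, p = 1
  P0 <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)
  r0 <- welch_screen(P0, c(10, 11, 12, 10, 11, 12))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # hand-computed Welch: t = 5*sqrt(3/2), df = 4
  r1 <- welch_screen(P0, c(14, 15, 16, 9, 10, 11))
  expect_equal(r1$t, 5 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r1$df, 4, tolerance = 1e-12)
  expect_equal(r1$effect, 5)
  # random columns against stats::t.test
  set.seed(60)
  n <- 24
  P <- matrix(sample(c(0L, 1L, NA), n * 12, TRUE, prob = c(.4, .5, .1)),
              n, 12, dimnames = list(paste0("s", 1:n), paste0("m", 1:12)))
  y <- rnorm(n, 10, 2)
  names(y) <- rownames(P)
  res <- welch_screen(P, y, min_class_size = 2)
  for (j in 1:12) {
    ok <- !is.na(P[, j])
    a <- y[ok][P[ok, j] == 1]; b <- y[ok][P[ok, j] == 0]
    if (length(a) >= 2 && length(b) >= 2 && var(a) + var(b) > 0) {
      tt <- t.test(a, b)
      expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p[j], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("untestable columns get NA instead of errors", {
  y <- c(10, 11, 12, 13, 14, 15)
  all_present <- matrix(1L, 6, 1)
  expect_true(is.na(welch_screen(all_present, y)$p))
  small <- matrix(c(1, 1, 0, 0, 0, 0), ncol = 1)
  expect_true(is.na(welch_screen(small, y, min_class_size = 3)$p))
  # zero pooled variance
  zv <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1)
  expect_true(is.na(welch_screen(zv, c(5, 5, 5, 5, 5, 5))$p))
  expect_error(welch_screen(zv, c(1, 2, NA, 4, 5, 6)), "every sample")
})

test_that("BH adjustment reproduces the hand-stepped example and oracle", {
  b1 <- bh_adjust(0.04)
  expect_true(b1$significant)
  b <- bh_adjust(c(0.01, 0.02, 0.03, 0.9))
  expect_equal(b$q, c(0.04, 0.04, 0.04, 0.9))
  expect_identical(b$significant, c(TRUE, TRUE, TRUE, FALSE))
  # NAs are excluded from the family
  bna <- bh_adjust(c(0.01, NA, 0.04))
  expect_equal(bna$m, 2)
  expect_true(is.na(bna$q[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)$q
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("the selection rule combines screen and model verdicts", {
  rec <- data.frame(
    q = c(0.01, 0.01, 0.2, 0.01, 0.01),
    m1_p = c(0.6, 0.004, 0.6, NA, NA),
    m1_flag = c("ok", "ok", "ok", "single_group", "inestimable"),
    m2_p = c(0.001, 0.001, 0.001, 0.01, 0.01)
  )
  out <- select_diagnostic_alleles(rec)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # NA within-group never selects
  rec2 <- data.frame(q = 0.01, m1_p = 0.5, m1_flag = "ok", m2_p = NA)
  expect_false(select_diagnostic_alleles(rec2)$selected)
})

test_that("the discovery engine is deterministic and finds a planted allele", {
  cfg <- sim_config(n_samples = 60, ploidies = 4, n_loci = 150, n_groups = 2,
                    causal_alleles = data.frame(locus = 40, allele = 1,
                                                effect = 2.5),
                    seed = 77)
  co <- simulate_cohort(cfg)
  tab <- cohort_genotype_table(co)
  a1 <- associate_alleles(tab, mean_ssc(co), seed = 5)
  a2 <- associate_alleles(tab, mean_ssc(co), seed = 5)
  expect_identical(a1$records, a2$records)
  truth_id <- paste0(co$truth$alleles$locus_id, "_", co$truth$alleles$allele)
  expect_true(truth_id %in% a1$records$col_id[a1$records$selected])
  # funnel counts are non-increasing
  att <- a1$attrition
  expect_true(att["alleles_tested"] <= att["alleles_encoded"])
  expect_true(att["alleles_bh_significant"] <= att["alleles_tested"])
  expect_true(att["alleles_selected"] <= att["alleles_bh_significant"])
})
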