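test_that("VCF genotypes decode with ploidy-specific calls", {
  p <- write_test_vcf(c(
    "Chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0/1/1\t0/1",
    "Chr1\t200\t.\tG\tC,TT\t.\tPASS\t.\tGT\t./././.\t0/2",
    "Chr1\t300\t.\tA\tT\t.\tPASS\t.\tGT\t./0/1/1\t1/1"
  ))
  tab <- build_genotype_table(p)
  expect_s3_class(tab, "locus_gtable")
  expect_equal(tab$loci$locus_id, c("Chr1:100", "Chr1:200", "Chr1:300"))
  expect_identical(unname(tab$calls[1, "SA"]), "0/0/1/1")
  expect_identical(unname(tab$calls[1, "SB"]), "0/1")
  # fully and partially missing genotypes are both MISSING
  expect_true(is.na(tab$calls[2, "SA"]))
  expect_true(is.na(tab$calls[3, "SA"]))
  # multiallelic record kept as one locus with the full ALT list
  expect_identical(tab$loci$alt[2], "C,TT")
  expect_identical(tab$ploidy[["SA"]], 4L)
  expect_identical(tab$ploidy[["SB"]], 2L)
})

test_that("declared-ploidy and allele-range violations are locus-level errors", {
  p <- write_test_vcf("Chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0/1\t0/1")
  expect_error(build_genotype_table(p, ploidies = c(SA = 4L, SB = 2L)),
               "Chr1:100")
  p2 <- write_test_vcf("Chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0/2/2\t0/1")
  expect_error(build_genotype_table(p2), "out of range")
})

test_that("loci come back sorted by chromosome and position", {
  p <- write_test_vcf(c(
    "Chr2\t50\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0",
    "Chr1\t900\t.\tG\tC\t.\tPASS\t.\tGT\t0/0\t0/1",
    "Chr1\t100\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/1"
  ))
  tab <- build_genotype_table(p)
  expect_equal(tab$loci$locus_id, c("Chr1:100", "Chr1:900", "Chr2:50"))
})

test_that("written cohorts round-trip through the VCF reader", {
  for (seed in c(2, 13)) {
    co <- tiny_cohort(seed = seed, n_samples = 9, n_loci = 40)
    paths <- write_cohort(co, tempfile())
    tab <- build_genotype_table(paths$vcf)
    tab <- apply_depth_missingness(tab, read.delim(paths$depth))
    ord <- order(co$loci$chrom, co$loci$pos)
    expect_identical(unname(tab$calls), unname(co$gt[ord, ]))
    expect_identical(tab$loci$locus_id, co$loci$locus_id[ord])
    # and the in-memory route gives the same table
    mem <- cohort_genotype_table(co)
    expect_identical(mem$calls, tab$calls)
    expect_equal(mem$loci, tab$loci)
  }
})

test_that("an empty cohort writes a header-only VCF that reads back", {
  co <- simulate_cohort(sim_config(n_samples = 3, n_loci = 0, seed = 1))
  paths <- write_cohort(co, tempfile())
  txt <- readLines(paths$vcf)
  expect_true(all(startsWith(txt, "#")))
  tab <- build_genotype_table(paths$vcf)
  expect_equal(nrow(tab$loci), 0)
})

test_that("zero depth forces cells missing, matching a brute-force scan", {
  co <- tiny_cohort(seed = 7, n_samples = 8, n_loci = 25, missing_rate = 0)
  tab <- cohort_genotype_table(co)
  set.seed(42)
  dp <- matrix(rpois(length(tab$calls), 3), nrow = nrow(tab$calls))
  out <- apply_depth_missingness(tab, dp)
  expected_na <- dp == 0 | is.na(tab$calls)
  expect_identical(unname(is.na(out$calls)), unname(expected_na))
  # called cell at zero depth is forced missing; depth >= 1 is untouched
  expect_gt(attr(out, "n_forced_missing"), 0)
  all_pos <- apply_depth_missingness(tab, matrix(1, nrow(dp), ncol(dp)))
  expect_identical(all_pos$calls, tab$calls)
  # idempotence
  again <- apply_depth_missingness(out, dp)
  expect_identical(again$calls, out$calls)
})

test_that("missing cells without a depth entry are reported", {
  co <- tiny_cohort(seed = 3, n_samples = 6, n_loci = 10, missing_rate = 0.3)
  tab <- cohort_genotype_table(co)
  dp <- data.frame(chrom = co$loci$chrom[1], pos = co$loci$pos[1],
                   sample = co$samples$sample_id[1], depth = 5)
  expect_message(apply_depth_missingness(tab, dp), "no depth entry")
})
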