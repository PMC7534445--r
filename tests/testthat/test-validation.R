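test_that("per-environment validation reduces to the Welch screen + BH", {
  set.seed(12)
  n <- 30
  calls <- matrix(sample(c(0L, 1L), n * 6, TRUE), n, 6,
                  dimnames = list(sprintf("s%02d", 1:n), paste0("m", 1:6)))
  y <- rnorm(n, 10, 1.2)
  ph <- data.frame(sample = rownames(calls), environment = "only",
                   ssc_brix = y)
  v <- validate_per_environment(calls, ph)
  sc <- welch_screen(calls, setNames(y, rownames(calls)))
  bh <- bh_adjust(sc$p)
  expect_equal(v$p, sc$p)
  expect_equal(v$q, bh$q)
  expect_identical(v$significant, bh$significant)
})

test_that("identical phenotypes give p = 1 and zero effect", {
  calls <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1,
                  dimnames = list(paste0("s", 1:6), "m1"))
  ph <- data.frame(sample = rep(paste0("s", 1:6), 2),
                   environment = rep(c("e1", "e2"), each = 6),
                   ssc_brix = rep(c(9, 10, 11, 9, 10, 11), 2))
  v <- validate_per_environment(calls, ph)
  expect_equal(v$p, c(1, 1))
  expect_equal(v$effect, c(0, 0))
})

test_that("a planted marker validates in most environments", {
  hits <- vapply(1:60, function(i) {
    set.seed(4000 + i)
    n <- 96
    a <- rbinom(n, 1, 0.4)
    calls <- matrix(as.integer(a), ncol = 1,
                    dimnames = list(sprintf("s%02d", 1:n), "mk"))
    ph <- do.call(rbind, lapply(c("e1", "e2", "e3"), function(e) {
      data.frame(sample = rownames(calls), environment = e,
                 ssc_brix = 10 + 1.5 * a + rnorm(n, 0, 1.5))
    }))
    v <- validate_per_environment(calls, ph)
    sum(v$significant, na.rm = TRUE) >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("a null marker rejects near the nominal rate per environment", {
  rej <- unlist(lapply(1:150, function(i) {
    set.seed(5000 + i)
    n <- 60
    calls <- matrix(rbinom(n, 1, 0.5), ncol = 1,
                    dimnames = list(sprintf("s%02d", 1:n), "mk"))
    ph <- data.frame(sample = rownames(calls), environment = "e1",
                     ssc_brix = rnorm(n, 10, 1))
    validate_per_environment(calls, ph)$p <= 0.05
  }))
  ci <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / length(rej))
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("single-class environments yield NA", {
  calls <- matrix(rep(1L, 8), ncol = 1,
                  dimnames = list(paste0("s", 1:8), "m1"))
  ph <- data.frame(sample = paste0("s", 1:8), environment = "e1",
                   ssc_brix = rnorm(8, 10))
  expect_true(is.na(validate_per_environment(calls, ph)$p))
})

test_that("concordance is symmetric and matches per-cell comparison", {
  t3 <- load_table3_fixture()
  ab <- concordance(t3$sequencing, t3$kasp, target_alleles = t3$target_alleles)
  ba <- concordance(t3$kasp, t3$sequencing, target_alleles = t3$target_alleles)
  expect_equal(ab$n_concordant, ba$n_concordant)
  expect_setequal(ab$discordant, ba$discordant)
  # identity
  self <- concordance(t3$sequencing, t3$sequencing)
  expect_equal(self$n_concordant, self$n_total)
  # order-insensitive genotype strings
  a <- data.frame(sample = "x", position = "p", genotype = "A:T")
  b <- data.frame(sample = "x", position = "p", genotype = "T:A")
  expect_equal(concordance(a, b)$n_concordant, 1)
  # randomly perturbed copies against a brute-force cell scan
  set.seed(33)
  for (i in 1:20) {
    a <- t3$sequencing
    flip <- sample(nrow(a), 5)
    a$genotype[flip] <- "Z:Z"
    r <- concordance(a, t3$sequencing)
    manual <- vapply(split(seq_len(nrow(a)), a$sample), function(rows) {
      all(vapply(rows, function(k) {
        setequal_multiset <- function(u, v) identical(sort(u), sort(v))
        setequal_multiset(strsplit(a$genotype[k], ":")[[1]],
                          strsplit(t3$sequencing$genotype[k], ":")[[1]])
      }, logical(1)))
    }, logical(1))
    expect_equal(r$n_concordant, sum(manual))
  }
})

test_that("mismatched comparison panels are rejected with a listing", {
  a <- data.frame(sample = c("x", "y"), position = "p", genotype = "A:T")
  b <- data.frame(sample = c("x", "z"), position = "p", genotype = "A:T")
  expect_error(concordance(a, b), "z/p")
})

test_that("attrition arithmetic handles edges", {
  expect_equal(assay_attrition_report(10, 0), list(n_usable = 10, pct_failed = 0))
  expect_equal(assay_attrition_report(7, 7), list(n_usable = 0, pct_failed = 100))
  expect_error(assay_attrition_report(5, 6), "exceed")
  expect_error(assay_attrition_report(5, -1), "n_failed")
})

test_that("pooled and per-environment effect sizes are reported", {
  set.seed(77)
  n <- 40
  a <- setNames(rbinom(n, 1, 0.5), sprintf("s%02d", 1:n))
  ph <- do.call(rbind, lapply(c("e1", "e2"), function(e) {
    data.frame(sample = names(a), environment = e,
               ssc_brix = 10 + 1.2 * a + rnorm(n, 0, 0.2))
  }))
  es <- marker_effect_sizes(a, ph)
  expect_equal(es$pooled, 1.2, tolerance = 0.2)
  expect_equal(length(es$per_environment), 2)
})
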