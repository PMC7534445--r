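test_that("the packaged syntenic QTL regions are all recovered", {
  t2 <- load_table2_fixture()
  res <- find_conserved_qtl_regions(t2$blocks, t2$qtls)
  expect_equal(res$regions$block_id, c("region1", "region2", "region3"))
  expect_true(all(res$regions$n_species >= 2))
})

test_that("no QTL means no conserved regions", {
  t2 <- load_table2_fixture()
  res <- find_conserved_qtl_regions(t2$blocks, t2$qtls[0, ])
  expect_equal(nrow(res$regions), 0)
})

test_that("region finding equals a brute-force double loop", {
  for (seed in 1:40) {
    inst <- random_interval_instance(seed)
    res <- find_conserved_qtl_regions(inst$blocks, inst$qtls)
    expect_equal(res$regions$block_id, bf_conserved(inst$blocks, inst$qtls))
  }
})

test_that("region finding is order-invariant and monotone in min_species", {
  inst <- random_interval_instance(7)
  base <- find_conserved_qtl_regions(inst$blocks, inst$qtls)
  perm <- find_conserved_qtl_regions(inst$blocks[sample(nrow(inst$blocks)), ],
                                     inst$qtls[sample(nrow(inst$qtls)), ])
  expect_equal(base$regions, perm$regions)
  for (ms in 2:4) {
    lo <- find_conserved_qtl_regions(inst$blocks, inst$qtls, min_species = ms)
    hi <- find_conserved_qtl_regions(inst$blocks, inst$qtls,
                                     min_species = ms + 1)
    expect_true(all(hi$regions$block_id %in% lo$regions$block_id))
  }
  expect_error(find_conserved_qtl_regions(
    data.frame(block_id = "b", genome = "g", chrom = "c", start = 5, end = 2),
    inst$qtls), "start <= end")
})

test_that("marker containment is endpoint-inclusive", {
  regions <- data.frame(region_id = "r1", chrom = "c1", start = 100, end = 200)
  markers <- data.frame(chrom = "c1", pos = c(100, 200, 201, 99, 150))
  out <- map_markers_to_regions(markers, regions)
  expect_identical(out$region_id, c("r1", "r1", NA, NA, "r1"))
})

test_that("marker mapping equals a brute-force containment scan", {
  set.seed(14)
  regions <- data.frame(region_id = paste0("r", 1:6),
                        chrom = sample(c("c1", "c2"), 6, TRUE),
                        start = sample.int(300, 6))
  regions$end <- regions$start + sample.int(100, 6)
  markers <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                        pos = sample.int(450, 60))
  out <- map_markers_to_regions(markers, regions)
  manual <- vapply(seq_len(nrow(markers)), function(i) {
    hit <- regions$region_id[regions$chrom == markers$chrom[i] &
                               regions$start <= markers$pos[i] &
                               markers$pos[i] <= regions$end]
    if (!length(hit)) NA_character_ else paste(sort(unique(hit)), collapse = ",")
  }, character(1))
  expect_identical(out$region_id, manual)
})

test_that("bait tiling follows the step-and-flush rule", {
  # short exon removed before design
  res <- tile_baits(data.frame(id = c("a", "b"), length = c(49, 200)))
  expect_equal(res$n_removed, 1)
  expect_equal(res$baits$start[res$baits$exon_id == "b"], c(1, 41, 81, 121))
  # exon equal to the bait length: one bait
  one <- tile_baits(data.frame(id = "e", length = 80))
  expect_equal(nrow(one$baits), 1)
  # designable but shorter than a bait: one short-flagged bait
  short <- tile_baits(data.frame(id = "e", length = 60))
  expect_true(short$baits$short)
  expect_equal(short$baits$end, 60)
  expect_error(tile_baits(data.frame(id = "e", length = 100), tiling = 3),
               "evenly")
})

test_that("tiled baits cover every designable base at bounded depth", {
  set.seed(8)
  for (len in c(80, 95, 160, 200, 321)) {
    res <- tile_baits(data.frame(id = "e", length = len))
    cov <- integer(len)
    for (i in seq_len(nrow(res$baits))) {
      rng <- res$baits$start[i]:res$baits$end[i]
      cov[rng] <- cov[rng] + 1L
    }
    expect_true(all(cov >= 1))
    interior <- cov[seq(40, len - 40)]
    expect_true(all(interior <= 3))  # tiling + 1
  }
})

test_that("coverage percentages round half-up to one decimal", {
  expect_equal(coverage_percentage(0, 10), 0)
  expect_equal(coverage_percentage(7, 7), 100)
  expect_equal(coverage_percentage(1, 3), 33.3)
  expect_equal(coverage_percentage(2, 3), 66.7)
  expect_error(coverage_percentage(5, 0), "n_total")
  expect_error(coverage_percentage(5, 4), "exceed")
})
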