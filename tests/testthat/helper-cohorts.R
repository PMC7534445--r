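# shared builders and brute-force oracles for the suite

tiny_cohort <- function(seed = 1, n_samples = 10, n_loci = 30, n_groups = 2,
                        ...) {
  simulate_cohort(sim_config(n_samples = n_samples, n_loci = n_loci,
                             n_groups = n_groups, seed = seed, ...))
}

# write a handcrafted VCF and return its path
write_test_vcf <- function(body_rows, samples = c("SA", "SB")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_rows
  ), path)
  path
}

# brute-force locus filter: per-locus scan with explicit loops
bf_filter_keep <- function(table, max_missing = 0.2, min_alleles = 2,
                           max_alleles = 4) {
  vapply(seq_len(nrow(table$loci)), function(i) {
    calls <- table$calls[i, ]
    miss <- mean(is.na(calls))
    alleles <- unique(unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE)))
    miss < max_missing && length(alleles) >= min_alleles &&
      length(alleles) <= max_alleles
  }, logical(1))
}

# brute-force presence/absence: per-cell membership test
bf_presence <- function(table) {
  n <- length(table$samples)
  out <- list()
  for (i in seq_len(nrow(table$loci))) {
    calls <- table$calls[i, ]
    alleles <- sort(unique(as.integer(
      unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE)))))
    for (a in alleles) {
      col <- vapply(calls, function(cl) {
        if (is.na(cl)) NA_integer_ else
          as.integer(as.character(a) %in% strsplit(cl, "/", fixed = TRUE)[[1]])
      }, integer(1))
      out[[paste0(table$loci$locus_id[i], "#", a)]] <- unname(col)
    }
  }
  out
}

# brute-force step-up Benjamini-Hochberg on a complete p-vector
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force conserved-region finder: double loop over segments and QTL
bf_conserved <- function(blocks, qtls, min_species = 2) {
  hits <- list()
  for (i in seq_len(nrow(blocks))) {
    for (j in seq_len(nrow(qtls))) {
      if (blocks$genome[i] == qtls$genome[j] &&
          blocks$chrom[i] == qtls$chrom[j] &&
          blocks$start[i] <= qtls$end[j] && qtls$start[j] <= blocks$end[i]) {
        hits[[length(hits) + 1L]] <- data.frame(
          block_id = blocks$block_id[i], qtl_name = qtls$qtl_name[j],
          genome = qtls$genome[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(character(0))
  sup <- unique(do.call(rbind, hits))
  keep <- vapply(split(sup, sup$block_id), function(s) {
    length(unique(s$genome)) >= min_species
  }, logical(1))
  sort(names(keep)[keep])
}

random_interval_instance <- function(seed, n_blocks = 8, n_qtl = 12) {
  set.seed(seed)
  genomes <- c("gA", "gB", "gC")
  blocks <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    members <- sample(genomes, sample(2:3, 1))
    starts <- sample.int(500, length(members))
    data.frame(block_id = paste0("b", b), genome = members,
               chrom = sample(c("c1", "c2"), length(members), replace = TRUE),
               start = starts, end = starts + sample.int(80, length(members)),
               stringsAsFactors = FALSE)
  }))
  starts <- sample.int(550, n_qtl)
  qtls <- data.frame(
    qtl_name = paste0("q", seq_len(n_qtl)),
    genome = sample(genomes, n_qtl, replace = TRUE),
    chrom = sample(c("c1", "c2"), n_qtl, replace = TRUE),
    start = starts, end = starts + sample.int(60, n_qtl),
    stringsAsFactors = FALSE
  )
  list(blocks = blocks, qtls = qtls)
}
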