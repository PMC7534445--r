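#' Build a locus genotype table from a multi-sample VCF
#'
#' Reads a VCF (via \pkg{vcfR}) and converts it to the locus-named genotype
#' table the association engine consumes: one row per variant record —
#' multiallelic records are kept as single loci with their full ALT list —
#' and one column per sample holding a slash-separated string of 0-based
#' allele indices whose length is that sample's ploidy. A genotype with any
#' missing entry (`.`) is treated as wholly missing for that cell: no partial
#' dosage is imputed. Loci are sorted by (chrom, pos) and named
#' `"chrom:pos"`.
#'
#' @param vcf path to a VCF file, or a `vcfR::vcfR` object.
#' @param samples optional character vector restricting/ordering the samples.
#' @param ploidies optional named integer vector of declared per-sample
#'   ploidies; when given, any called genotype whose entry count disagrees
#'   raises an error naming the offending locus.
#' @return An object of class `locus_gtable`: list with `loci` (data frame:
#'   chrom, pos, ref, alt, locus_id), `calls` (character matrix loci x
#'   samples, `NA` = missing), `samples`, and `ploidy` (named vector inferred
#'   from the calls; `NA` for samples with no called genotype).
#' @export
build_genotype_table <- function(vcf, samples = NULL, ploidies = NULL) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  stopifnot(methods::is(vcf, "vcfR"))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    sample_ids <- samples %||% setdiff(colnames(vcf@gt), "FORMAT") %||% character()
    return(new_locus_gtable(
      loci = data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        locus_id = character(), stringsAsFactors = FALSE),
      calls = matrix(NA_character_, 0, length(sample_ids),
                     dimnames = list(NULL, sample_ids)),
      ploidies = ploidies))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) {
      stop("samples absent from VCF: ", paste(missing_s, collapse = ", "),
           call. = FALSE)
    }
    gt <- gt[, samples, drop = FALSE]
  }
  loci <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = ifelse(is.na(fix$ALT), "", fix$ALT),
    stringsAsFactors = FALSE
  )
  loci$locus_id <- locus_id(loci$chrom, loci$pos)

  # normalise calls: sort indices within a call, NA anything partially missing
  calls <- normalize_calls(gt, loci, ploidies)

  ord <- order(loci$chrom, loci$pos)
  new_locus_gtable(loci = loci[ord, , drop = FALSE],
                   calls = calls[ord, , drop = FALSE],
                   ploidies = ploidies)
}

# shared constructor/validator; infers per-sample ploidy from call lengths
new_locus_gtable <- function(loci, calls, ploidies = NULL) {
  rownames(loci) <- NULL
  if (anyDuplicated(loci$locus_id)) {
    stop("duplicate locus ids in table", call. = FALSE)
  }
  inferred <- apply(calls, 2L, function(col) {
    lens <- unique(lengths(strsplit(col[!is.na(col)], "/", fixed = TRUE)))
    if (length(lens) > 1) {
      stop("inconsistent ploidy within a sample's calls", call. = FALSE)
    }
    if (length(lens)) lens else NA_integer_
  })
  if (!is.null(ploidies)) {
    inferred <- ifelse(is.na(inferred), ploidies[colnames(calls)], inferred)
  }
  structure(list(loci = loci, calls = calls, samples = colnames(calls),
                 ploidy = inferred),
            class = "locus_gtable")
}

normalize_calls <- function(gt, loci, ploidies = NULL) {
  out <- matrix(NA_character_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = list(NULL, colnames(gt)))
  n_alt <- lengths(strsplit(ifelse(nzchar(loci$alt), loci$alt, ""), ",",
                            fixed = TRUE))
  for (s in seq_len(ncol(gt))) {
    col <- gt[, s]
    toks <- strsplit(col, "[/|]")
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (is.na(col[i]) || length(tk) == 0 || any(tk == ".")) next
      idx <- suppressWarnings(as.integer(tk))
      if (anyNA(idx)) {
        stop(sprintf("malformed GT '%s' at %s for sample %s",
                     col[i], loci$locus_id[i], colnames(gt)[s]), call. = FALSE)
      }
      if (!is.null(ploidies)) {
        pl <- ploidies[colnames(gt)[s]]
        if (!is.na(pl) && length(idx) != pl) {
          stop(sprintf("GT at %s for sample %s has %d entries, declared ploidy %d",
                       loci$locus_id[i], colnames(gt)[s], length(idx), pl),
               call. = FALSE)
        }
      }
      if (any(idx > n_alt[i]) || any(idx < 0)) {
        stop(sprintf("allele index out of range in GT at %s", loci$locus_id[i]),
             call. = FALSE)
      }
      out[i, s] <- paste(sort(idx), collapse = "/")
    }
  }
  out
}

#' Genotype table directly from a simulated cohort
#'
#' In-memory equivalent of writing a cohort with [write_cohort()] and
#' reading it back with [build_genotype_table()] +
#' [apply_depth_missingness()]; the two routes produce identical tables
#' (property-tested), but this one skips the file round trip, which matters
#' in large simulation studies.
#'
#' @param cohort a `sim_cohort`.
#' @return a `locus_gtable`.
#' @export
cohort_genotype_table <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  loci <- cohort$loci[, c("chrom", "pos", "ref", "alt", "locus_id")]
  calls <- cohort$gt
  calls[cohort$depth == 0L] <- NA_character_
  ord <- order(loci$chrom, loci$pos)
  new_locus_gtable(loci = loci[ord, , drop = FALSE],
                   calls = calls[ord, , drop = FALSE],
                   ploidies = setNames(cohort$samples$ploidy,
                                       cohort$samples$sample_id))
}

#' Force genotype cells with zero read depth to missing
#'
#' Applies the depth-based missingness rule: any (locus, sample) cell whose
#' read depth is 0 is recorded as missing regardless of its genotype call;
#' cells with depth >= 1 keep their call. Cells that are already missing but
#' have no depth entry are treated as depth 0 and counted in a message. The
#' input table is not modified. The operation is idempotent.
#'
#' @param table a `locus_gtable`.
#' @param depth_table data frame with columns `chrom, pos, sample, depth`
#'   (the long format written by [write_cohort()]), or a numeric matrix with
#'   the table's dimensions.
#' @return a new `locus_gtable` with zero-depth cells set missing; the number
#'   of cells forced missing is attached as attribute `n_forced_missing`.
#' @export
apply_depth_missingness <- function(table, depth_table) {
  stopifnot(inherits(table, "locus_gtable"))
  L <- nrow(table$loci); n <- length(table$samples)
  if (is.matrix(depth_table)) {
    dp <- depth_table
    stopifnot(nrow(dp) == L, ncol(dp) == n)
  } else {
    depth_table <- as.data.frame(depth_table)
    stopifnot(all(c("chrom", "pos", "sample", "depth") %in% names(depth_table)))
    dp <- matrix(NA_real_, nrow = L, ncol = n,
                 dimnames = list(table$loci$locus_id, table$samples))
    ri <- match(locus_id(depth_table$chrom, depth_table$pos),
                table$loci$locus_id)
    ci <- match(depth_table$sample, table$samples)
    keep <- !is.na(ri) & !is.na(ci)
    dp[cbind(ri[keep], ci[keep])] <- depth_table$depth[keep]
  }
  unaudited_missing <- sum(is.na(dp) & is.na(table$calls))
  if (unaudited_missing > 0) {
    message(unaudited_missing,
            " missing cell(s) had no depth entry; treated as depth 0")
  }
  force_na <- !is.na(dp) & dp == 0
  out <- table
  out$calls[force_na] <- NA_character_
  attr(out, "n_forced_missing") <- sum(force_na & !is.na(table$calls))
  out
}

#' Sequenced-cohort metadata fixture (40 blackberry samples)
#'
#' Loads the packaged summary of the 40 sequenced blackberry cultivars and
#' selections: breeding program (HCRU or UA, 20 each), historical mean SSC
#' in degrees Brix, number and length of circular consensus sequencing (CCS)
#' reads, and the k-means cluster group assigned against each of the two
#' reference assemblies (HV1, RoV3). A `ssc_class` column classifies samples
#' as `"high"` when mean SSC exceeds 11.5 degrees Brix and `"low"` otherwise.
#'
#' @return data frame with 40 rows and columns `program, name, mean_ssc,
#'   ccs_reads, mean_ccs_length, median_ccs_length, hv1_group, rov3_group,
#'   ssc_class`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_samples.tsv", package = "polybrix",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  expected <- c("program", "name", "mean_ssc", "ccs_reads", "mean_ccs_length",
                "median_ccs_length", "hv1_group", "rov3_group")
  if (!identical(names(df), expected) || nrow(df) != 40) {
    stop("table1 fixture is corrupted", call. = FALSE)
  }
  if (any(df$ccs_reads < 0) || any(df$ccs_reads != floor(df$ccs_reads))) {
    stop("table1 fixture: CCS counts must be nonnegative integers", call. = FALSE)
  }
  df$ssc_class <- ifelse(df$mean_ssc > 11.5, "high", "low")
  df
}

#' Summarise CCS read counts
#'
#' @param metadata data frame with columns `program` and `ccs_reads`, e.g.
#'   from [load_table1_fixture()]. An empty input yields a zero total.
#' @return list with `total_reads` and named `per_program_totals`.
#' @export
summarize_ccs <- function(metadata) {
  if (is.null(metadata) || nrow(metadata) == 0) {
    return(list(total_reads = 0, per_program_totals = numeric()))
  }
  per <- tapply(metadata$ccs_reads, metadata$program, sum)
  list(total_reads = sum(metadata$ccs_reads),
       per_program_totals = setNames(as.numeric(per), names(per)))
}

#' @export
print.locus_gtable <- function(x, ...) {
  cat(sprintf("<locus_gtable> %d loci x %d samples (%.1f%% missing)\n",
              nrow(x$loci), length(x$samples),
              100 * mean(is.na(x$calls))))
  invisible(x)
}
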