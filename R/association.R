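#' Filter loci on missingness and allele number
#'
#' Keeps loci whose fraction of missing sample calls is strictly below
#' `max_missing` and whose number of distinct observed alleles — counted over
#' non-missing calls across all samples, the reference allele included
#' whenever it appears in a call — lies within `[min_alleles, max_alleles]`.
#' The strict `<` means a locus missing in exactly 20% of samples is removed
#' under the default threshold. Attrition counts per criterion are attached
#' as attribute `attrition`.
#'
#' @param table a `locus_gtable`.
#' @param max_missing maximum tolerated missing fraction, in `[0, 1]`.
#' @param min_alleles,max_alleles inclusive bounds on the observed allele
#'   count (defaults 2 and 4: biallelic to tetraallelic).
#' @return the filtered `locus_gtable`.
#' @export
filter_loci <- function(table, max_missing = 0.20, min_alleles = 2,
                        max_alleles = 4) {
  stopifnot(inherits(table, "locus_gtable"))
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1) {
    stop("`max_missing` must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(table$loci) == 0) stop("empty genotype table", call. = FALSE)

  miss_frac <- rowMeans(is.na(table$calls))
  pres <- allele_presence_stack(table)
  n_obs_alleles <- Reduce(`+`, lapply(pres, function(pa) {
    as.integer(rowSums(pa, na.rm = TRUE) > 0)
  }))

  ok_miss <- miss_frac < max_missing
  ok_alleles <- n_obs_alleles >= min_alleles & n_obs_alleles <= max_alleles
  keep <- ok_miss & ok_alleles

  out <- table
  out$loci <- table$loci[keep, , drop = FALSE]
  rownames(out$loci) <- NULL
  out$calls <- table$calls[keep, , drop = FALSE]
  attr(out, "attrition") <- c(
    n_in = nrow(table$loci),
    removed_missing = sum(!ok_miss),
    removed_allele_count = sum(ok_miss & !ok_alleles),
    n_kept = sum(keep)
  )
  out
}

#' Encode each locus-allele as a presence/absence marker
#'
#' Dominant coding for polyploids: for every allele observed at a locus
#' (over non-missing calls), a sample is `1` if it carries at least one copy,
#' `0` if it has a called genotype without that allele, and `NA` if its call
#' at that locus is missing — dosage is discarded entirely. Missing cells
#' therefore propagate to all of a locus's columns.
#'
#' @param table a `locus_gtable`, normally already passed through
#'   [filter_loci()].
#' @return An object of class `allele_matrix`: list with `presence`
#'   (integer matrix, samples x columns, entries 1/0/NA), and `columns`
#'   (data frame: `locus_id`, `allele_index` (0-based), `allele` (string),
#'   `col_id` = `"locus_id_allele"`).
#' @export
encode_presence_absence <- function(table) {
  stopifnot(inherits(table, "locus_gtable"))
  n <- length(table$samples)
  L <- nrow(table$loci)
  alt_list <- strsplit(table$loci$alt, ",", fixed = TRUE)
  pres <- allele_presence_stack(table)

  col_locus <- integer(0); col_allele <- integer(0); blocks <- list()
  for (a in seq_along(pres) - 1L) {
    pa <- pres[[a + 1L]]
    rows <- which(rowSums(pa, na.rm = TRUE) > 0)
    if (!length(rows)) next
    blocks[[length(blocks) + 1L]] <- t(pa[rows, , drop = FALSE])
    col_locus <- c(col_locus, rows)
    col_allele <- c(col_allele, rep(a, length(rows)))
  }
  if (length(blocks)) {
    presence <- do.call(cbind, blocks)
    ord <- order(col_locus, col_allele)
    presence <- presence[, ord, drop = FALSE]
    storage.mode(presence) <- "integer"
    col_locus <- col_locus[ord]; col_allele <- col_allele[ord]
    allele_str <- vapply(seq_along(col_locus), function(j) {
      c(table$loci$ref[col_locus[j]], alt_list[[col_locus[j]]])[col_allele[j] + 1L]
    }, character(1))
    columns <- data.frame(locus_id = table$loci$locus_id[col_locus],
                          allele_index = col_allele, allele = allele_str,
                          stringsAsFactors = FALSE)
  } else {
    presence <- matrix(NA_integer_, nrow = n, ncol = 0)
    columns <- data.frame(locus_id = character(), allele_index = integer(),
                          allele = character(), stringsAsFactors = FALSE)
  }
  columns$col_id <- paste0(columns$locus_id, "_", columns$allele)
  dimnames(presence) <- list(table$samples, columns$col_id)
  structure(list(presence = presence, columns = columns),
            class = "allele_matrix")
}

# list over allele indices 0..max of logical L x n matrices: does the call
# contain that allele? NA where the call is missing. One vectorised regex
# pass per allele index keeps genome-scale encoding fast.
allele_presence_stack <- function(table) {
  calls <- table$calls
  max_idx <- max(1L, lengths(strsplit(table$loci$alt, ",", fixed = TRUE)))
  lapply(0:max_idx, function(a) {
    pa <- matrix(grepl(paste0("(?:^|/)", a, "(?:$|/)"), calls, perl = TRUE),
                 nrow = nrow(calls))
    pa[is.na(calls)] <- NA
    pa
  })
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf("<allele_matrix> %d samples x %d locus-allele columns\n",
              nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' Welch's t-test screen of every locus-allele column
#'
#' For each presence/absence column, performs a two-sided Welch (unequal
#' variance) t-test of the phenotype between carriers and non-carriers,
#' with the Welch--Satterthwaite degrees of freedom. Samples whose entry in a
#' column is missing are excluded from that column's test. Columns where
#' either class has fewer than `min_class_size` samples, or where both class
#' variances are zero, get `NA` statistics and are meant to be excluded from
#' the multiple-testing family (see [bh_adjust()]).
#'
#' The computation is vectorised across columns so that genome-scale screens
#' and simulation studies run in milliseconds.
#'
#' @param matrix an `allele_matrix`, or a plain numeric matrix of 1/0/NA
#'   entries (samples x markers).
#' @param ssc numeric phenotype per sample (degrees Brix), in row order of
#'   the matrix or named by sample.
#' @param min_class_size minimum samples per class for a testable column.
#' @return data frame, one row per column: `col_id, n_present, n_absent,
#'   mean_present, mean_absent, effect, t, df, p`. `effect` is
#'   `mean(SSC | present) - mean(SSC | absent)`.
#' @export
welch_screen <- function(matrix, ssc, min_class_size = 3) {
  P <- if (inherits(matrix, "allele_matrix")) matrix$presence else matrix
  if (!is.null(names(ssc)) && !is.null(rownames(P))) {
    if (!all(rownames(P) %in% names(ssc))) {
      stop("phenotype missing for some samples", call. = FALSE)
    }
    ssc <- ssc[rownames(P)]
  }
  stopifnot(length(ssc) == nrow(P))
  if (anyNA(ssc)) stop("`ssc` must be defined for every sample", call. = FALSE)

  M1 <- P == 1L; M1[is.na(M1)] <- FALSE
  M0 <- P == 0L; M0[is.na(M0)] <- FALSE
  n1 <- colSums(M1); n0 <- colSums(M0)
  s1 <- as.numeric(crossprod(M1, ssc)); s0 <- as.numeric(crossprod(M0, ssc))
  q1 <- as.numeric(crossprod(M1, ssc^2)); q0 <- as.numeric(crossprod(M0, ssc^2))
  m1 <- s1 / n1; m0 <- s0 / n0
  v1 <- pmax((q1 - n1 * m1^2) / (n1 - 1), 0)
  v0 <- pmax((q0 - n0 * m0^2) / (n0 - 1), 0)

  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1)))
  p <- 2 * pt(-abs(t), df)

  bad <- n1 < min_class_size | n0 < min_class_size | (v1 + v0) == 0
  t[bad] <- NA_real_; df[bad] <- NA_real_; p[bad] <- NA_real_

  data.frame(
    col_id = colnames(P) %||% paste0("col", seq_len(ncol(P))),
    n_present = n1, n_absent = n0,
    mean_present = m1, mean_absent = m0, effect = m1 - m0,
    t = t, df = df, p = p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg correction with an explicit testable family
#'
#' Step-up false discovery rate control over the non-`NA` p-values only:
#' untestable columns (`NA` from [welch_screen()]) do not count toward the
#' family size `m`. Monotone q-values are returned in the input order, `NA`
#' where the input was `NA`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @param alpha significance level for the reported significant set.
#' @return list with `q` (q-values, same length/order as `pvals`),
#'   `significant` (logical, `FALSE` for `NA` input), and `m` (family size).
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(pvals))
  q[ok] <- p.adjust(pvals[ok], method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha, m = sum(ok))
}
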