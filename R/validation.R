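#' Validate diagnostic markers in each environment
#'
#' For every environment (location-year) separately, compares the phenotype
#' of target-allele carriers against non-carriers with Welch's t-test, then
#' applies a Benjamini-Hochberg correction across the markers tested within
#' that environment (the multiple-testing family is per environment; no
#' cross-environment correction). Effect is carrier mean minus non-carrier
#' mean, degrees Brix. Marker-environment combinations where either class
#' has fewer than `min_class_size` phenotyped samples get `NA`.
#'
#' @param calls matrix of 1/0/NA target-allele presence, samples x markers,
#'   with sample row names and marker column names.
#' @param phenotypes data frame with columns `sample`, `environment`,
#'   `ssc_brix`; replicate rows per sample-environment are averaged first.
#' @param alpha significance level.
#' @param min_class_size minimum class size per test.
#' @return data frame, one row per (marker, environment): `marker,
#'   environment, n_present, n_absent, effect, t, df, p, q, significant`.
#' @export
validate_per_environment <- function(calls, phenotypes, alpha = 0.05,
                                     min_class_size = 3) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)),
            all(c("sample", "environment", "ssc_brix") %in% names(phenotypes)))
  envs <- unique(phenotypes$environment)
  out <- list()
  for (e in envs) {
    ph <- phenotypes[phenotypes$environment == e, , drop = FALSE]
    y <- tapply(ph$ssc_brix, ph$sample, mean, na.rm = TRUE)
    common <- intersect(rownames(calls), names(y)[!is.na(y)])
    res <- welch_screen(calls[common, , drop = FALSE], y[common],
                        min_class_size = min_class_size)
    bh <- bh_adjust(res$p, alpha = alpha)
    out[[e]] <- data.frame(
      marker = res$col_id, environment = e,
      n_present = res$n_present, n_absent = res$n_absent,
      effect = res$effect, t = res$t, df = res$df, p = res$p,
      q = bh$q, significant = bh$significant,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled and per-environment effect sizes for a marker
#'
#' Reports the carrier minus non-carrier mean SSC difference both pooled
#' over all environments (of per-sample means) and within each environment.
#'
#' @param calls 1/0/NA presence vector named by sample (one marker).
#' @param phenotypes data frame `sample, environment, ssc_brix`.
#' @return list with `pooled` (degrees Brix) and named `per_environment`.
#' @export
marker_effect_sizes <- function(calls, phenotypes) {
  eff <- function(y) {
    common <- intersect(names(calls)[!is.na(calls)], names(y)[!is.na(y)])
    cc <- calls[common]
    if (!any(cc == 1) || !any(cc == 0)) return(NA_real_)
    mean(y[common][cc == 1]) - mean(y[common][cc == 0])
  }
  y_all <- tapply(phenotypes$ssc_brix, phenotypes$sample, mean, na.rm = TRUE)
  per_env <- vapply(split(phenotypes, phenotypes$environment), function(ph) {
    eff(tapply(ph$ssc_brix, ph$sample, mean, na.rm = TRUE))
  }, numeric(1))
  list(pooled = eff(y_all), per_environment = per_env)
}

split_genotype <- function(x) strsplit(x, ":", fixed = TRUE)

#' Genotype concordance between two calling methods
#'
#' Compares genotype strings (alleles joined by `":"`, e.g. `"A:T"`) between
#' two methods per sample and position. Comparison is order-insensitive:
#' `"A:T"` matches `"T:A"`. When `target_alleles` is supplied (named by
#' position), every allele is first collapsed to `target` versus `other`
#' before the multiset comparison — the appropriate rule for biallelic
#' assays such as KASP that can only distinguish the target allele from
#' everything else and must not be read as dosage calls. A sample is fully
#' concordant iff all of its positions match.
#'
#' @param method_a,method_b data frames with columns `sample`, `position`,
#'   and a genotype column (the last column is used if no column named
#'   `genotype` exists). Both must cover the same (sample, position) pairs.
#' @param target_alleles optional named character vector: target allele per
#'   position.
#' @return object of class `concordance_report`: list with `pairs` (per
#'   sample x position: both calls and `match`), `per_sample` (sample,
#'   `concordant` flag), `n_concordant`, `n_total`, and `discordant`
#'   (sample names).
#' @export
concordance <- function(method_a, method_b, target_alleles = NULL) {
  gcol <- function(df) {
    if ("genotype" %in% names(df)) df$genotype else df[[ncol(df)]]
  }
  a <- data.frame(sample = method_a$sample, position = method_a$position,
                  call_a = gcol(method_a), stringsAsFactors = FALSE)
  b <- data.frame(sample = method_b$sample, position = method_b$position,
                  call_b = gcol(method_b), stringsAsFactors = FALSE)
  key_a <- paste(a$sample, a$position, sep = "\r")
  key_b <- paste(b$sample, b$position, sep = "\r")
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    only_a <- setdiff(key_a, key_b); only_b <- setdiff(key_b, key_a)
    stop("inputs do not cover the same (sample, position) pairs: ",
         paste(gsub("\r", "/", c(only_a, only_b)), collapse = ", "),
         call. = FALSE)
  }
  b <- b[match(key_a, key_b), , drop = FALSE]
  pairs <- cbind(a, call_b = b$call_b)

  classify <- function(alleles, pos) {
    if (is.null(target_alleles)) return(alleles)
    tgt <- target_alleles[[pos]]
    if (is.null(tgt) || is.na(tgt)) return(alleles)
    ifelse(alleles == tgt, "target", "other")
  }
  pairs$match <- vapply(seq_len(nrow(pairs)), function(i) {
    aa <- sort(classify(split_genotype(pairs$call_a[i])[[1]], pairs$position[i]))
    bb <- sort(classify(split_genotype(pairs$call_b[i])[[1]], pairs$position[i]))
    identical(aa, bb)
  }, logical(1))

  per_sample <- data.frame(
    sample = unique(pairs$sample),
    concordant = vapply(unique(pairs$sample), function(s) {
      all(pairs$match[pairs$sample == s])
    }, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, per_sample = per_sample,
                 n_concordant = sum(per_sample$concordant),
                 n_total = nrow(per_sample),
                 discordant = per_sample$sample[!per_sample$concordant]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d of %d samples fully concordant\n",
              x$n_concordant, x$n_total))
  if (length(x$discordant)) {
    cat("  discordant:", paste(x$discordant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sequencing-versus-KASP genotype fixture (13 samples x 3 positions)
#'
#' Loads the packaged comparison of 13 blackberry samples genotyped both by
#' sequencing and by KASP assay at three chromosome 1 positions
#' (Ro01:14978562, Ro01:14978613, Ro01:14979298). The target diagnostic
#' alleles at the three positions (`T`, `GT`, `A`) are attached, since the
#' KASP assays report only presence of the target allele.
#'
#' @return list with data frames `sequencing` and `kasp` (columns `sample,
#'   position, genotype`) and the named `target_alleles` vector.
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_concordance.tsv",
                      package = "polybrix", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(df), c("sample", "position", "sequencing", "kasp")) ||
      nrow(df) != 39) {
    stop("table3 fixture is corrupted", call. = FALSE)
  }
  list(
    sequencing = data.frame(sample = df$sample, position = df$position,
                            genotype = df$sequencing, stringsAsFactors = FALSE),
    kasp = data.frame(sample = df$sample, position = df$position,
                      genotype = df$kasp, stringsAsFactors = FALSE),
    target_alleles = c("Ro01:14978562" = "T", "Ro01:14978613" = "GT",
                       "Ro01:14979298" = "A")
  )
}

#' Assay attrition arithmetic
#'
#' @param n_designed number of assays designed.
#' @param n_failed number that performed poorly or were monomorphic.
#' @return list with `n_usable` and `pct_failed` (percent, one decimal,
#'   half-up).
#' @export
assay_attrition_report <- function(n_designed, n_failed) {
  stopifnot_scalar_count(n_designed, "n_designed", min = 1)
  stopifnot_scalar_count(n_failed, "n_failed", min = 0)
  if (n_failed > n_designed) {
    stop("`n_failed` cannot exceed `n_designed`", call. = FALSE)
  }
  list(n_usable = n_designed - n_failed,
       pct_failed = round_half_up(100 * n_failed / n_designed, 1))
}
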