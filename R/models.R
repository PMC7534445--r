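#' Group-by-allele interaction model (structure-dependence test)
#'
#' Fits `SSC ~ Group + Allele + Group:Allele` by ordinary least squares and
#' tests the interaction with an extra-sum-of-squares F-test against
#' `SSC ~ Group + Allele`. A significant interaction means the allele's
#' effect differs between population groups, i.e. the association is not
#' structure-independent. Samples with a missing allele entry are excluded.
#' Groups where only one allele class occurs make some interaction columns
#' inestimable; `lm` drops the aliased columns and the F-test degrees of
#' freedom shrink accordingly. With a single group the interaction is
#' undefined and the flag `"single_group"` is returned; with no estimable
#' interaction column the flag is `"inestimable"`.
#'
#' @param ssc numeric phenotype per sample (degrees Brix).
#' @param groups group label per sample (coerced to factor).
#' @param allele 1/0/NA presence per sample.
#' @return list `F`, `p`, `df` (interaction df), `flag` (`"ok"`,
#'   `"single_group"` or `"inestimable"`).
#' @export
fit_model1 <- function(ssc, groups, allele) {
  d <- data.frame(ssc = ssc, g = factor(groups), a = allele)
  d <- d[!is.na(d$a) & !is.na(d$ssc), , drop = FALSE]
  d$g <- droplevels(d$g)
  if (nlevels(d$g) < 2) {
    return(list(F = NA_real_, p = NA_real_, df = NA_integer_,
                flag = "single_group"))
  }
  if (length(unique(d$a)) < 2) {
    return(list(F = NA_real_, p = NA_real_, df = NA_integer_,
                flag = "inestimable"))
  }
  red <- lm(ssc ~ g + a, data = d)
  full <- lm(ssc ~ g + a + g:a, data = d)
  an <- anova(red, full)
  df_int <- an$Df[2]
  if (is.na(df_int) || df_int < 1 || an$Res.Df[2] < 1) {
    return(list(F = NA_real_, p = NA_real_, df = NA_integer_,
                flag = "inestimable"))
  }
  list(F = an$F[2], p = an$`Pr(>F)`[2], df = as.integer(df_int), flag = "ok")
}

#' Allele-within-group model (structure-corrected association test)
#'
#' Fits the nested model `SSC ~ Group + Group:Allele` (the allele effect is
#' estimated separately within each group) and tests all within-group allele
#' terms jointly with an extra-sum-of-squares F-test against `SSC ~ Group`.
#' Significance means the allele is associated with the trait over and above
#' population structure. With a single group this reduces exactly to the
#' one-way comparison `SSC ~ Allele` versus the intercept, whose F equals
#' the square of the pooled-variance two-sample t statistic. An allele
#' constant within every group leaves no estimable term: flag
#' `"inestimable"`.
#'
#' @inheritParams fit_model1
#' @return list `F`, `p`, `df` (joint within-group allele df), `flag`.
#' @export
fit_model2 <- function(ssc, groups, allele) {
  d <- data.frame(ssc = ssc, g = factor(groups), a = allele)
  d <- d[!is.na(d$a) & !is.na(d$ssc), , drop = FALSE]
  d$g <- droplevels(d$g)
  varies_within <- any(vapply(split(d$a, d$g), function(a) {
    length(unique(a)) > 1
  }, logical(1)))
  if (!varies_within || nrow(d) < 3) {
    return(list(F = NA_real_, p = NA_real_, df = NA_integer_,
                flag = "inestimable"))
  }
  if (nlevels(d$g) < 2) {
    red <- lm(ssc ~ 1, data = d)
    full <- lm(ssc ~ a, data = d)
  } else {
    red <- lm(ssc ~ g, data = d)
    full <- lm(ssc ~ g + g:a, data = d)
  }
  an <- anova(red, full)
  df_a <- an$Df[2]
  if (is.na(df_a) || df_a < 1 || an$Res.Df[2] < 1) {
    return(list(F = NA_real_, p = NA_real_, df = NA_integer_,
                flag = "inestimable"))
  }
  list(F = an$F[2], p = an$`Pr(>F)`[2], df = as.integer(df_a), flag = "ok")
}

# closed-form equivalents of fit_model1/fit_model2 computed from
# (group x allele-class) cell sums; exact OLS projections, so they agree
# with the lm route to numerical precision (property-tested). Used on the
# hot path where thousands of screen-significant columns need both tests.
model_tests_fast <- function(y, g, a) {
  na_out <- list(F = NA_real_, p = NA_real_, df = NA_integer_)
  ok <- !is.na(a) & !is.na(y)
  y <- y[ok]; a <- a[ok]
  y <- y - mean(y)  # centering improves the conditioning of the SS algebra
  g <- as.integer(factor(g[ok]))
  n <- length(y)
  res <- list(m1 = c(na_out, flag = "inestimable"),
              m2 = c(na_out, flag = "inestimable"))
  if (n < 3) return(res)
  G <- max(g)
  cell <- (g - 1L) * 2L + a + 1L
  n_gc <- tabulate(cell, nbins = 2L * G)
  s_gc <- vapply(seq_len(2L * G), function(cc) sum(y[cell == cc]), 0)
  nonempty <- which(n_gc > 0)
  C <- length(nonempty)
  sst <- sum(y^2)
  sse_cell <- sst - sum(s_gc[nonempty]^2 / n_gc[nonempty])
  n_g <- tabulate(g, nbins = G)
  s_g <- vapply(seq_len(G), function(gg) sum(y[g == gg]), 0)
  sse_g <- sst - sum(s_g[n_g > 0]^2 / n_g[n_g > 0])
  df_res <- n - C
  both_classes <- length(unique(a)) > 1

  # model 2: Group + Group:Allele (the cell-mean model) vs Group
  df_a <- C - sum(n_g > 0)
  if (df_a >= 1 && df_res >= 1 && both_classes) {
    f2 <- ((sse_g - sse_cell) / df_a) / (sse_cell / df_res)
    res$m2 <- list(F = f2, p = stats::pf(f2, df_a, df_res, lower.tail = FALSE),
                   df = as.integer(df_a), flag = "ok")
  }

  # model 1: interaction vs additive Group + Allele
  if (G < 2) {
    res$m1 <- c(na_out, flag = "single_group")
    return(res)
  }
  if (!both_classes || df_res < 1) return(res)
  # weighted LS of cell means on the additive design
  cg <- (nonempty - 1L) %/% 2L + 1L   # group of each nonempty cell
  ca <- (nonempty - 1L) %% 2L         # allele class of each nonempty cell
  X <- cbind(1, outer(cg, 2:G, `==`) + 0, ca)
  w <- n_gc[nonempty]
  m_gc <- s_gc[nonempty] / w
  fit <- lm.wfit(X, m_gc, w)
  rank_add <- fit$rank
  df_int <- C - rank_add
  if (df_int < 1) return(res)
  sse_add <- sse_cell + sum(w * fit$residuals^2)
  f1 <- ((sse_add - sse_cell) / df_int) / (sse_cell / df_res)
  res$m1 <- list(F = f1, p = stats::pf(f1, df_int, df_res, lower.tail = FALSE),
                 df = as.integer(df_int), flag = "ok")
  res
}

#' Apply the diagnostic-allele selection rule
#'
#' An allele is selected for marker design iff its screening q-value is at
#' most `alpha`, its group-by-allele interaction is \emph{not} significant
#' (interaction p > `alpha`, or undefined because there is a single group),
#' and its within-group allele term \emph{is} significant (p <= `alpha`).
#' An inestimable within-group term never selects.
#'
#' @param records data frame carrying columns `q`, `m1_p`, `m1_flag`,
#'   `m2_p` (as produced by [associate_alleles()]).
#' @param alpha significance level.
#' @return the input with a logical `selected` column replaced/added.
#' @export
select_diagnostic_alleles <- function(records, alpha = 0.05) {
  stopifnot(all(c("q", "m1_p", "m1_flag", "m2_p") %in% names(records)))
  pass_q <- !is.na(records$q) & records$q <= alpha
  pass_m1 <- (!is.na(records$m1_p) & records$m1_p > alpha) |
    (is.na(records$m1_p) & records$m1_flag == "single_group")
  pass_m2 <- !is.na(records$m2_p) & records$m2_p <= alpha
  records$selected <- pass_q & pass_m1 & pass_m2
  records
}

#' Discover SSC-associated alleles in a genotype table
#'
#' The full discovery engine: filters loci on missingness and allele number,
#' encodes presence/absence locus-allele markers, screens them with Welch's
#' t-test and a Benjamini-Hochberg correction, obtains population-structure
#' groups (inferred by [infer_structure_groups()] or supplied externally),
#' fits the interaction and within-group models to every screen-significant
#' allele, and applies the selection rule of [select_diagnostic_alleles()].
#' The multiple-testing family is the set of testable columns of this one
#' table; when two reference genomes are analysed, run the engine once per
#' genome's table so each gets its own correction.
#'
#' @param table a `locus_gtable`.
#' @param ssc numeric per-sample mean SSC (degrees Brix), named by sample or
#'   in the table's sample order.
#' @param groups optional externally supplied group labels per sample (named
#'   by sample or in table order); when `NULL`, structure is inferred.
#' @param alpha significance level used for the screen and both models.
#' @param max_missing,min_alleles,max_alleles passed to [filter_loci()].
#' @param min_class_size passed to [welch_screen()].
#' @param k_range,pc_variance,n_starts passed to [infer_structure_groups()].
#' @param seed seed for the structure inference.
#' @return object of class `ssc_assoc`: list with `records` (one row per
#'   tested locus-allele: counts, Welch statistics, `q`, model statistics,
#'   `selected`, `effect`), `grouping` (a `structure_grouping` or the
#'   external labels), `matrix` (the `allele_matrix`), `attrition` (named
#'   funnel counts) and `alpha`.
#' @export
associate_alleles <- function(table, ssc, groups = NULL, alpha = 0.05,
                              max_missing = 0.20, min_alleles = 2,
                              max_alleles = 4, min_class_size = 3,
                              k_range = 1:10, pc_variance = 0.9,
                              n_starts = 50, seed = 1L) {
  stopifnot(inherits(table, "locus_gtable"))
  filtered <- filter_loci(table, max_missing = max_missing,
                          min_alleles = min_alleles,
                          max_alleles = max_alleles)
  am <- encode_presence_absence(filtered)
  if (!is.null(names(ssc))) ssc <- ssc[filtered$samples]
  if (anyNA(ssc) || length(ssc) != length(filtered$samples)) {
    stop("`ssc` must cover every sample in the table", call. = FALSE)
  }

  screen <- welch_screen(am, ssc, min_class_size = min_class_size)
  bh <- bh_adjust(screen$p, alpha = alpha)
  screen$q <- bh$q

  grouping <- NULL
  if (is.null(groups)) {
    grouping <- infer_structure_groups(am, k_range = k_range,
                                       pc_variance = pc_variance,
                                       n_starts = n_starts, seed = seed)
    groups <- grouping$groups
  } else {
    if (!is.null(names(groups))) groups <- groups[filtered$samples]
    stopifnot(length(groups) == length(filtered$samples))
  }

  screen$m1_F <- NA_real_; screen$m1_p <- NA_real_
  screen$m1_flag <- NA_character_
  screen$m2_F <- NA_real_; screen$m2_p <- NA_real_
  screen$m2_flag <- NA_character_
  to_model <- which(bh$significant)
  for (j in to_model) {
    m <- model_tests_fast(ssc, groups, am$presence[, j])
    screen$m1_F[j] <- m$m1$F; screen$m1_p[j] <- m$m1$p
    screen$m1_flag[j] <- m$m1$flag
    screen$m2_F[j] <- m$m2$F; screen$m2_p[j] <- m$m2$p
    screen$m2_flag[j] <- m$m2$flag
  }
  records <- cbind(am$columns[, c("locus_id", "allele_index", "allele",
                                  "col_id")],
                   screen[, setdiff(names(screen), "col_id")])
  records <- select_diagnostic_alleles(records, alpha = alpha)

  attrition <- c(
    loci_in = unname(attr(filtered, "attrition")["n_in"]),
    loci_filtered = unname(attr(filtered, "attrition")["n_kept"]),
    alleles_encoded = ncol(am$presence),
    alleles_tested = bh$m,
    alleles_bh_significant = sum(bh$significant),
    alleles_selected = sum(records$selected)
  )
  structure(list(records = records, grouping = grouping,
                 groups = setNames(as.integer(factor(groups)),
                                   filtered$samples),
                 matrix = am, attrition = attrition, alpha = alpha),
            class = "ssc_assoc")
}

#' @export
print.ssc_assoc <- function(x, ...) {
  a <- x$attrition
  cat("<ssc_assoc>\n")
  cat(sprintf("  loci: %d in -> %d after filters\n", a["loci_in"],
              a["loci_filtered"]))
  cat(sprintf("  locus-alleles: %d encoded, %d tested, %d BH-significant, %d selected (alpha = %g)\n",
              a["alleles_encoded"], a["alleles_tested"],
              a["alleles_bh_significant"], a["alleles_selected"], x$alpha))
  invisible(x)
}
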