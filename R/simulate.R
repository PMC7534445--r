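#' Configure a synthetic mixed-ploidy association cohort
#'
#' Builds and validates the configuration for [simulate_cohort()]. The
#' defaults describe the kind of cohort the package's discovery engine is
#' designed for: 40 clonal samples of even ploidy between 4x and 8x from a
#' small number of structured breeding groups, around a thousand biallelic to
#' tetraallelic loci, soluble solids content (SSC) phenotyped as three
#' replicate juice measurements per sample in each of four location-year
#' environments, and depth-driven missingness at random (locus, sample) cells.
#'
#' Two kinds of trait-affecting alleles can be planted:
#' * `causal_alleles` carry the same additive presence effect in every group
#'   (structure-independent associations the pipeline should recover);
#' * `interaction_alleles` carry an effect whose sign flips between groups
#'   (`+effect` in odd-numbered groups, `-effect` in even-numbered ones) and
#'   whose carrier frequency differs by group, emulating associations that are
#'   artifacts of population structure and should be rejected by the
#'   group-by-allele interaction test.
#'
#' Effects are dominant: a sample gets the full effect if it carries at least
#' one copy of the allele, matching the presence/absence marker coding used
#' downstream.
#'
#' @param n_samples number of clonal individuals.
#' @param ploidies even integer vector of per-sample ploidies, recycled to
#'   `n_samples`. The real distribution of ploidies in breeding germplasm is
#'   rarely known, so it is configuration, not an assertion.
#' @param n_loci number of variant loci.
#' @param n_groups number of population-structure groups (1--4 typical).
#' @param group_assignment optional integer vector in `1:n_groups` per sample;
#'   default assigns samples to groups in contiguous blocks of near-equal size.
#' @param n_alleles_range integer range (min, max) of alleles per locus
#'   (reference included) drawn uniformly per locus.
#' @param causal_alleles data frame with columns `locus` (index into
#'   `1:n_loci`), `allele` (0-based allele index at that locus, 0 = REF) and
#'   `effect` (degrees Brix added for carriers). May be empty.
#' @param interaction_alleles data frame with the same columns; `effect` is
#'   the magnitude of the sign-flipping group-specific effect.
#' @param carrier_freq per-copy frequency of each planted causal allele,
#'   identical in every group so the association is structure-independent.
#'   The default 0.12 yields presence frequencies near 0.4--0.65 across
#'   ploidies 4x--8x.
#' @param interaction_freqs length-2 numeric: per-copy frequency of each
#'   planted interaction allele in odd- and even-numbered groups. Unequal
#'   frequencies give the allele a nonzero marginal effect, so it reaches the
#'   screening stage and must be caught by the interaction model.
#' @param dirichlet_alpha concentration of the per-group Dirichlet draw of
#'   allele frequencies at background loci; small values give strongly
#'   differentiated (structure-informative) loci.
#' @param baseline_ssc intercept of the phenotype model, degrees Brix.
#' @param group_shifts numeric per-group additive phenotype shift, degrees
#'   Brix (recycled to `n_groups`).
#' @param env_effects named numeric vector of additive environment
#'   (location-year) offsets, degrees Brix; the names are the environment
#'   labels.
#' @param n_reps replicate phenotype measurements per sample per environment.
#' @param residual_sd standard deviation of the Gaussian residual drawn once
#'   per (sample, environment), degrees Brix — the non-genetic biological and
#'   genotype-by-environment variation that replicate juicing does not
#'   average away.
#' @param rep_sd standard deviation of additional independent replicate-level
#'   measurement noise, degrees Brix (default 0: replicates within an
#'   environment repeat the sample-environment value exactly).
#' @param missing_rate probability that a (locus, sample) cell has zero read
#'   depth and therefore a missing genotype; must be < 1.
#' @param depth_mean mean read depth of covered cells (depth is
#'   `1 + Poisson(depth_mean - 1)` so covered cells always have depth >= 1).
#' @param seed integer seed fixing every random draw of the simulation.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 40,
                       ploidies = c(4L, 6L, 8L),
                       n_loci = 1000,
                       n_groups = 2,
                       group_assignment = NULL,
                       n_alleles_range = c(2L, 4L),
                       causal_alleles = NULL,
                       interaction_alleles = NULL,
                       carrier_freq = 0.12,
                       interaction_freqs = c(0.25, 0.05),
                       dirichlet_alpha = 0.5,
                       baseline_ssc = 10,
                       group_shifts = 0,
                       env_effects = c("loc1_2015" = 0, "loc1_2016" = -0.7,
                                       "loc2_2015" = 0.5, "loc2_2016" = -0.3),
                       n_reps = 3,
                       residual_sd = 1.5,
                       rep_sd = 0,
                       missing_rate = 0.10,
                       depth_mean = 20,
                       seed = 1L) {
  stopifnot_scalar_count(n_samples, "n_samples", min = 1)
  stopifnot_scalar_count(n_loci, "n_loci", min = 0)
  stopifnot_scalar_count(n_groups, "n_groups", min = 1)
  stopifnot_scalar_count(seed, "seed", min = 0)

  ploidies <- as.integer(rep_len(ploidies, n_samples))
  if (any(ploidies < 2L) || any(ploidies %% 2L != 0L)) {
    stop("all ploidies must be even integers >= 2", call. = FALSE)
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (length(n_alleles_range) != 2L || n_alleles_range[1] < 2L ||
      n_alleles_range[2] > 4L || n_alleles_range[1] > n_alleles_range[2]) {
    stop("`n_alleles_range` must be within [2, 4] with min <= max", call. = FALSE)
  }
  if (is.null(group_assignment)) {
    group_assignment <- sort(rep_len(seq_len(n_groups), n_samples))
  }
  group_assignment <- as.integer(group_assignment)
  if (length(group_assignment) != n_samples ||
      any(!group_assignment %in% seq_len(n_groups))) {
    stop("`group_assignment` must map each sample to 1..n_groups", call. = FALSE)
  }
  group_shifts <- rep_len(as.numeric(group_shifts), n_groups)
  if (is.null(names(env_effects)) || anyNA(env_effects)) {
    stop("`env_effects` must be a named, NA-free numeric vector", call. = FALSE)
  }

  check_planted <- function(df, what) {
    if (is.null(df)) return(data.frame(locus = integer(), allele = integer(),
                                       effect = numeric()))
    df <- as.data.frame(df)
    stopifnot(all(c("locus", "allele", "effect") %in% names(df)))
    if (any(df$locus < 1 | df$locus > n_loci)) {
      stop(sprintf("%s: locus index out of 1..n_loci", what), call. = FALSE)
    }
    if (any(df$allele < 0 | df$allele > n_alleles_range[2] - 1L)) {
      stop(sprintf("%s: allele index out of range for n_alleles_range", what),
           call. = FALSE)
    }
    if (any(!is.finite(df$effect))) {
      stop(sprintf("%s: effects must be finite", what), call. = FALSE)
    }
    df$locus <- as.integer(df$locus)
    df$allele <- as.integer(df$allele)
    df
  }
  causal_alleles <- check_planted(causal_alleles, "causal_alleles")
  interaction_alleles <- check_planted(interaction_alleles, "interaction_alleles")
  both <- intersect(paste(causal_alleles$locus, causal_alleles$allele),
                    paste(interaction_alleles$locus, interaction_alleles$allele))
  if (length(both)) stop("an allele cannot be both causal and interaction", call. = FALSE)

  structure(list(
    n_samples = n_samples, ploidies = ploidies, n_loci = n_loci,
    n_groups = n_groups, group_assignment = group_assignment,
    n_alleles_range = as.integer(n_alleles_range),
    causal_alleles = causal_alleles, interaction_alleles = interaction_alleles,
    carrier_freq = carrier_freq, interaction_freqs = interaction_freqs,
    dirichlet_alpha = dirichlet_alpha, baseline_ssc = baseline_ssc,
    group_shifts = group_shifts, env_effects = env_effects, n_reps = n_reps,
    residual_sd = residual_sd, rep_sd = rep_sd, missing_rate = missing_rate,
    depth_mean = depth_mean, seed = as.integer(seed)
  ), class = "sim_config")
}

# one Dirichlet(alpha) draw per row via gamma normalisation
rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)  # guard against underflow at tiny alpha
  g / sum(g)
}

#' Simulate a mixed-ploidy association cohort
#'
#' Generates genotypes, read depths and replicate phenotypes under the model
#' described in [sim_config()]. All randomness comes from `config$seed`; the
#' draw order is fixed (per-locus allele counts, per-locus-per-group allele
#' frequencies, genotypes locus by locus, missingness mask, depths, phenotype
#' residuals), so a given config reproduces bitwise-identical cohorts.
#'
#' The phenotype of sample `s` in environment `e` is
#' `baseline + env_effect(e) + group_shift(group(s)) + sum of planted effects
#' carried by s + N(0, residual_sd)`, with the residual drawn once per
#' (sample, environment); each of the `n_reps` replicate measurements
#' repeats that value plus independent `N(0, rep_sd)` measurement noise.
#' Carrier status is decided on the true (pre-masking) genotype; missingness
#' only hides genotypes, it does not change phenotypes.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_cohort`: a list with elements
#'   `loci` (data frame: chrom, pos, ref, alt, locus_id),
#'   `samples` (data frame: sample_id, ploidy, group),
#'   `gt` (character matrix, loci x samples, slash-separated 0-based allele
#'   indices, `NA` where masked missing),
#'   `depth` (integer matrix, loci x samples, 0 exactly where `gt` is `NA`),
#'   `phenotypes` (data frame: sample, environment, replicate, ssc_brix),
#'   `truth` (planted alleles with per-sample carrier matrix), and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  L <- config$n_loci
  grp <- config$group_assignment
  ploidy <- config$ploidies

  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    ploidy = ploidy, group = grp, stringsAsFactors = FALSE
  )

  # loci spread across 7 chromosomes, positions strictly increasing
  chrom_of <- if (L > 0) paste0("Chr", ((seq_len(L) - 1L) %% 7L) + 1L) else
    character(0)
  pos_of <- 1000L + 500L * (((seq_len(L) - 1L) %/% 7L) + 1L)
  ord <- order(chrom_of, pos_of)
  chrom_of <- chrom_of[ord]; pos_of <- pos_of[ord]
  # planted-allele locus indices refer to the sorted order
  bases <- c("A", "C", "G", "T")

  n_alleles <- if (L > 0) {
    sample(seq(config$n_alleles_range[1], config$n_alleles_range[2]),
           L, replace = TRUE)
  } else integer()
  planted <- rbind(
    cbind(config$causal_alleles, type = if (nrow(config$causal_alleles)) "causal" else character()),
    cbind(config$interaction_alleles, type = if (nrow(config$interaction_alleles)) "interaction" else character())
  )
  if (nrow(planted)) {
    need <- tapply(planted$allele, planted$locus, max) + 1L
    idx <- as.integer(names(need))
    n_alleles[idx] <- pmax(n_alleles[idx], pmin(4L, pmax(2L, need)))
  }

  allele_strings <- lapply(n_alleles, function(k) {
    bases[seq_len(k)]  # REF = "A", ALTs C, G, T; identity is positional
  })

  gt <- matrix(NA_character_, nrow = L, ncol = n,
               dimnames = list(NULL, samples$sample_id))
  carrier <- NULL
  if (nrow(planted)) {
    carrier <- matrix(FALSE, nrow = n, ncol = nrow(planted))
  }

  odd_group <- (grp %% 2L) == 1L
  copies_by_group <- split(seq_len(n), grp)

  dosage_list <- vector("list", L)
  for (l in seq_len(L)) {
    k <- n_alleles[l]
    here <- planted[planted$locus == l, , drop = FALSE]
    # per-group allele frequencies
    freqs <- matrix(0, nrow = config$n_groups, ncol = k)
    for (g in seq_len(config$n_groups)) {
      f <- rdirichlet1(k, config$dirichlet_alpha)
      if (nrow(here)) {
        # pin planted-allele frequencies; renormalise the rest
        pin <- numeric(k)
        for (j in seq_len(nrow(here))) {
          a <- here$allele[j] + 1L
          pin[a] <- if (here$type[j] == "causal") config$carrier_freq else
            config$interaction_freqs[if ((g %% 2L) == 1L) 1L else 2L]
        }
        free <- pin == 0
        f[!free] <- pin[!free]
        rem <- 1 - sum(pin)
        f[free] <- if (any(free)) rem * (f[free] / sum(f[free])) else f[free]
      }
      freqs[g, ] <- f
    }
    # draw chromosome copies group by group; tabulate per (sample, allele)
    dosage <- matrix(0L, nrow = n, ncol = k)
    for (g in seq_len(config$n_groups)) {
      idx <- copies_by_group[[as.character(g)]]
      if (is.null(idx) || !length(idx)) next
      draws <- sample.int(k, sum(ploidy[idx]), replace = TRUE,
                          prob = freqs[g, ])
      owner <- rep(idx, times = ploidy[idx])
      dosage <- dosage + matrix(tabulate((draws - 1L) * n + owner,
                                         nbins = n * k), nrow = n)
    }
    dosage_list[[l]] <- dosage
    if (nrow(here)) {
      rows <- match(paste(here$locus, here$allele, here$type),
                    paste(planted$locus, planted$allele, planted$type))
      for (j in seq_len(nrow(here))) {
        carrier[, rows[j]] <- dosage[, here$allele[j] + 1L] > 0L
      }
    }
  }

  # render GT strings via a per-k code lookup (dosage < 9 always: ploidy <= 8)
  for (k in unique(n_alleles)) {
    rows <- which(n_alleles == k)
    codes <- vapply(rows, function(l) {
      as.numeric(dosage_list[[l]] %*% 9^(0:(k - 1L)))
    }, numeric(n))
    codes <- matrix(codes, nrow = n)
    u <- unique(as.vector(codes))
    dec <- vapply(u, function(cd) {
      d <- integer(k)
      for (j in seq_len(k)) { d[j] <- cd %% 9; cd <- cd %/% 9 }
      paste(rep(seq_len(k) - 1L, d), collapse = "/")
    }, character(1))
    gt[rows, ] <- t(matrix(dec[match(as.vector(codes), u)], nrow = n))
  }

  # missingness mask and depths
  miss <- matrix(runif(L * n) < config$missing_rate, nrow = L, ncol = n)
  depth <- matrix(1L + rpois(L * n, max(config$depth_mean - 1, 0)), nrow = L,
                  ncol = n, dimnames = dimnames(gt))
  depth[miss] <- 0L
  gt_masked <- gt
  gt_masked[miss] <- NA_character_

  # phenotypes: replicate-level residuals
  envs <- names(config$env_effects)
  genet <- config$baseline_ssc + config$group_shifts[grp]
  if (nrow(planted)) {
    for (j in seq_len(nrow(planted))) {
      if (planted$type[j] == "causal") {
        genet <- genet + planted$effect[j] * carrier[, j]
      } else {
        sgn <- ifelse(odd_group, 1, -1)
        genet <- genet + planted$effect[j] * sgn * carrier[, j]
      }
    }
  }
  se_res <- matrix(rnorm(n * length(envs), 0, config$residual_sd),
                   nrow = n, dimnames = list(samples$sample_id, envs))
  ph <- expand.grid(replicate = seq_len(config$n_reps), environment = envs,
                    sample = samples$sample_id, stringsAsFactors = FALSE)
  ph <- ph[, c("sample", "environment", "replicate")]
  ph$ssc_brix <- genet[match(ph$sample, samples$sample_id)] +
    config$env_effects[ph$environment] +
    se_res[cbind(ph$sample, ph$environment)] +
    if (config$rep_sd > 0) rnorm(nrow(ph), 0, config$rep_sd) else 0
  rownames(ph) <- NULL

  loci <- data.frame(
    chrom = chrom_of, pos = pos_of,
    ref = vapply(allele_strings, `[`, character(1), 1L),
    alt = vapply(allele_strings, function(a) paste(a[-1], collapse = ","),
                 character(1)),
    locus_id = locus_id(chrom_of, pos_of),
    stringsAsFactors = FALSE
  )

  truth <- list(alleles = if (nrow(planted)) data.frame(
    locus = planted$locus,
    locus_id = loci$locus_id[planted$locus],
    allele_index = planted$allele,
    allele = vapply(seq_len(nrow(planted)), function(j) {
      allele_strings[[planted$locus[j]]][planted$allele[j] + 1L]
    }, character(1)),
    effect = planted$effect, type = planted$type,
    stringsAsFactors = FALSE
  ) else data.frame(), carriers = carrier)

  structure(list(loci = loci, samples = samples, gt = gt_masked,
                 gt_true = gt, depth = depth, phenotypes = ph,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' Per-sample mean SSC from replicate phenotypes
#'
#' Averages all replicate measurements across environments for each sample,
#' the phenotype the discovery engine consumes.
#'
#' @param cohort a `sim_cohort`, or a phenotype data frame with columns
#'   `sample` and `ssc_brix`.
#' @return named numeric vector of mean SSC per sample, degrees Brix.
#' @export
mean_ssc <- function(cohort) {
  ph <- if (inherits(cohort, "sim_cohort")) cohort$phenotypes else cohort
  out <- tapply(ph$ssc_brix, ph$sample, mean)
  setNames(as.numeric(out), names(out))
}

#' Write a simulated cohort to standard files
#'
#' Emits a VCF 4.2 with mixed-ploidy `GT` (and `DP`) fields, a long-format
#' TSV read-depth table (`chrom, pos, sample, depth`) and a TSV phenotype
#' table (`sample, environment, replicate, ssc_brix`). The files round-trip
#' losslessly through [build_genotype_table()] and
#' [apply_depth_missingness()].
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the three file paths
#'   (`vcf`, `depth`, `phenotypes`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                depth = file.path(dir, "depth.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"))

  n <- nrow(cohort$samples)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=polybrix-simulate",
    sprintf("##contig=<ID=%s>", unique(cohort$loci$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t")
  )
  body <- character(0)
  if (nrow(cohort$loci) > 0) {
    cells <- vapply(seq_len(n), function(s) {
      g <- cohort$gt[, s]
      g[is.na(g)] <- vapply(which(is.na(g)), function(i) {
        paste(rep(".", cohort$samples$ploidy[s]), collapse = "/")
      }, character(1))
      paste0(g, ":", cohort$depth[, s])
    }, character(nrow(cohort$loci)))
    cells <- matrix(cells, nrow = nrow(cohort$loci))
    body <- paste(cohort$loci$chrom, cohort$loci$pos, ".", cohort$loci$ref,
                  ifelse(nzchar(cohort$loci$alt), cohort$loci$alt, "."),
                  ".", "PASS", ".", "GT:DP",
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), paths$vcf)

  dp <- data.frame(
    chrom = rep(cohort$loci$chrom, times = n),
    pos = rep(cohort$loci$pos, times = n),
    sample = rep(cohort$samples$sample_id, each = nrow(cohort$loci)),
    depth = as.vector(cohort$depth)
  )
  write.table(dp, paths$depth, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$phenotypes, paths$phenotypes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
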