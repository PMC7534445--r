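#' Infer population-structure groups by PCA + k-means with a BIC choice of k
#'
#' A discriminant-analysis-of-principal-components style grouping: columns
#' with at least 20% missing entries are dropped, remaining missing entries
#' are mean-imputed per column, the centered 1/0 matrix is decomposed by PCA,
#' and the fewest leading components reaching `pc_variance` of the total
#' variance are retained. k-means (with `n_starts` restarts) is run on the
#' retained scores for every `k` in `k_range` and the number of groups is
#' chosen by minimising
#' \deqn{BIC(k) = n \log(WSS_k / n) + k \log(n),}
#' where `WSS_k` is the total within-cluster sum of squares. Ties and exact
#' zero `WSS` favour the smallest `k`. Deterministic under a fixed seed.
#'
#' An externally supplied grouping (for instance published cluster labels)
#' can be used downstream instead of this inference; see
#' [associate_alleles()]'s `groups` argument.
#'
#' @param matrix an `allele_matrix` or a plain 1/0/NA matrix
#'   (samples x markers).
#' @param k_range candidate numbers of groups.
#' @param pc_variance fraction of variance the retained components must
#'   reach, in (0, 1].
#' @param n_starts random restarts per k-means run.
#' @param max_col_missing columns with a missing fraction at or above this
#'   are excluded before PCA.
#' @param seed integer seed.
#' @return object of class `structure_grouping`: list with `k` (chosen),
#'   `groups` (integer labels per sample, named), `bic` (named per candidate
#'   k), `n_pcs` retained, `k_range`, and `seed`.
#' @export
infer_structure_groups <- function(matrix, k_range = 1:10, pc_variance = 0.9,
                                   n_starts = 50, max_col_missing = 0.20,
                                   seed = 1L) {
  P <- if (inherits(matrix, "allele_matrix")) matrix$presence else matrix
  n <- nrow(P)
  samples <- rownames(P) %||% sprintf("S%03d", seq_len(n))
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1 & k_range <= n]
  if (n < 2) {
    return(structure(list(k = 1L, groups = setNames(rep(1L, n), samples),
                          bic = c(`1` = NA_real_), n_pcs = 0L,
                          k_range = 1L, seed = seed),
                     class = "structure_grouping"))
  }
  set.seed(seed)

  keep <- colMeans(is.na(P)) < max_col_missing
  X <- P[, keep, drop = FALSE]
  # mean-impute within column (imputation is used only here, never in tests)
  cm <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- cm[idx[, 2]]
  X <- X[, apply(X, 2, function(col) var(col) > 0), drop = FALSE]

  if (ncol(X) == 0) {
    # no informative variation: a single group
    return(structure(list(k = 1L, groups = setNames(rep(1L, n), samples),
                          bic = setNames(rep(NA_real_, length(k_range)),
                                         k_range),
                          n_pcs = 0L, k_range = k_range, seed = seed),
                     class = "structure_grouping"))
  }

  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pcs <- which(cumvar >= pc_variance)[1]
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]

  bic <- setNames(rep(NA_real_, length(k_range)), k_range)
  labels <- vector("list", length(k_range))
  tot_ss <- sum(scale(scores, scale = FALSE)^2)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      wss <- tot_ss
      labels[[i]] <- rep(1L, n)
    } else if (k >= n) {
      wss <- 0
      labels[[i]] <- seq_len(n)
    } else {
      km <- suppressWarnings(
        kmeans(scores, centers = k, nstart = n_starts, iter.max = 50)
      )
      wss <- km$tot.withinss
      labels[[i]] <- km$cluster
    }
    bic[i] <- if (wss <= 0) -Inf else n * log(wss / n) + k * log(n)
  }
  best <- which.min(bic)  # first minimum => smallest k on ties / -Inf
  structure(list(k = k_range[best],
                 groups = setNames(as.integer(labels[[best]]), samples),
                 bic = bic, n_pcs = n_pcs, k_range = k_range, seed = seed),
            class = "structure_grouping")
}

#' @export
print.structure_grouping <- function(x, ...) {
  cat(sprintf("<structure_grouping> k = %d (of %s), %d PCs retained\n",
              x$k, paste(range(x$k_range), collapse = ".."), x$n_pcs))
  invisible(x)
}
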