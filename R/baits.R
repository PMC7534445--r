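#' Tile capture baits over exon sequences
#'
#' Reproduces the arithmetic of a standard target-capture bait design: exons
#' shorter than `min_exon` nucleotides are removed before design; for each
#' remaining exon of length at least `bait_length`, baits of `bait_length`
#' are placed from position 1 at a step of `bait_length / tiling` with a
#' final bait flush to the exon end; exons at least `min_exon` but shorter
#' than `bait_length` get a single exon-length bait flagged `short`.
#'
#' @param exons data frame with columns `id` and `length` (nucleotides).
#' @param bait_length bait size in nucleotides.
#' @param tiling tiling density; must divide `bait_length` evenly.
#' @param min_exon minimum designable exon length.
#' @return list with `baits` (data frame: `exon_id, start, end, short`),
#'   `n_designable` (exons with at least one bait), `n_removed`, and
#'   `coverage_pct` (100 x designable length / total submitted length, one
#'   decimal, half-up).
#' @export
tile_baits <- function(exons, bait_length = 80, tiling = 2, min_exon = 50) {
  exons <- as.data.frame(exons)
  stopifnot(all(c("id", "length") %in% names(exons)),
            all(exons$length > 0))
  if (bait_length %% tiling != 0) {
    stop("`tiling` must divide `bait_length` evenly", call. = FALSE)
  }
  step <- bait_length %/% tiling
  keep <- exons$length >= min_exon
  designable <- exons[keep, , drop = FALSE]

  baits <- lapply(seq_len(nrow(designable)), function(i) {
    len <- designable$length[i]
    if (len < bait_length) {
      return(data.frame(exon_id = designable$id[i], start = 1L, end = len,
                        short = TRUE, stringsAsFactors = FALSE))
    }
    starts <- seq.int(1L, len - bait_length + 1L, by = step)
    flush <- len - bait_length + 1L
    if (starts[length(starts)] != flush) starts <- c(starts, flush)
    data.frame(exon_id = designable$id[i], start = starts,
               end = starts + bait_length - 1L, short = FALSE,
               stringsAsFactors = FALSE)
  })
  baits <- if (length(baits)) do.call(rbind, baits) else
    data.frame(exon_id = character(), start = integer(), end = integer(),
               short = logical(), stringsAsFactors = FALSE)
  list(
    baits = baits,
    n_designable = nrow(designable),
    n_removed = sum(!keep),
    coverage_pct = round_half_up(
      100 * sum(designable$length) / sum(exons$length), 1)
  )
}

#' Percentage of covered items, one decimal
#'
#' @param n_covered,n_total nonnegative counts, `n_covered <= n_total`,
#'   `n_total > 0`.
#' @return `100 * n_covered / n_total` rounded half-up to one decimal.
#' @export
coverage_percentage <- function(n_covered, n_total) {
  stopifnot_scalar_count(n_covered, "n_covered", min = 0)
  stopifnot_scalar_count(n_total, "n_total", min = 1)
  if (n_covered > n_total) {
    stop("`n_covered` cannot exceed `n_total`", call. = FALSE)
  }
  round_half_up(100 * n_covered / n_total, 1)
}
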