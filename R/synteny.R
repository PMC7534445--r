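#' Find synteny blocks supported by trait QTL from multiple species
#'
#' A synteny block (a set of corresponding segments, one per genome, sharing
#' a block id) is reported as a conserved trait region iff the QTL intervals
#' overlapping its member segments — same genome, same chromosome, at least
#' one shared base (1-based inclusive coordinates) — come from at least
#' `min_species` distinct genomes. Every supporting QTL is listed.
#'
#' @param blocks data frame, one row per member segment: `block_id, genome,
#'   chrom, start, end`.
#' @param qtls data frame of QTL intervals: `qtl_name, genome, chrom, start,
#'   end` (extra columns such as `trait` or `crop` are carried through).
#' @param min_species minimum number of distinct supporting genomes.
#' @return list with `regions` (data frame: `block_id, n_species,
#'   supporting_qtl` comma-joined) and `support` (data frame of every
#'   (block, QTL) overlap).
#' @export
find_conserved_qtl_regions <- function(blocks, qtls, min_species = 2) {
  blocks <- as.data.frame(blocks); qtls <- as.data.frame(qtls)
  stopifnot(all(c("block_id", "genome", "chrom", "start", "end") %in%
                  names(blocks)),
            all(c("qtl_name", "genome", "chrom", "start", "end") %in%
                  names(qtls)))
  if (any(blocks$start > blocks$end) || (nrow(qtls) && any(qtls$start > qtls$end))) {
    stop("intervals must satisfy start <= end", call. = FALSE)
  }
  empty <- list(
    regions = data.frame(block_id = character(), n_species = integer(),
                         supporting_qtl = character(), stringsAsFactors = FALSE),
    support = data.frame(block_id = character(), qtl_name = character(),
                         genome = character(), stringsAsFactors = FALSE)
  )
  if (nrow(qtls) == 0 || nrow(blocks) == 0) return(empty)

  # cross-genome intervals never overlap: prefix seqnames with the genome id
  seg <- GenomicRanges::GRanges(
    seqnames = paste(blocks$genome, blocks$chrom, sep = "|"),
    ranges = IRanges::IRanges(blocks$start, blocks$end)
  )
  qg <- GenomicRanges::GRanges(
    seqnames = paste(qtls$genome, qtls$chrom, sep = "|"),
    ranges = IRanges::IRanges(qtls$start, qtls$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(seg, qg))
  support <- data.frame(
    block_id = blocks$block_id[S4Vectors_from(hits)],
    qtl_name = qtls$qtl_name[S4Vectors_to(hits)],
    genome = qtls$genome[S4Vectors_to(hits)],
    stringsAsFactors = FALSE
  )
  support <- unique(support)
  if (nrow(support) == 0) return(empty)

  by_block <- split(support, support$block_id)
  regions <- do.call(rbind, lapply(by_block, function(s) {
    data.frame(block_id = s$block_id[1],
               n_species = length(unique(s$genome)),
               supporting_qtl = paste(sort(unique(s$qtl_name)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  regions <- regions[regions$n_species >= min_species, , drop = FALSE]
  regions <- regions[order(regions$block_id), , drop = FALSE]
  rownames(regions) <- NULL
  support <- support[support$block_id %in% regions$block_id, , drop = FALSE]
  rownames(support) <- NULL
  list(regions = regions, support = support)
}

# thin indirection so the Bioconductor accessors are easy to stub in tests
S4Vectors_from <- function(hits) S4Vectors::queryHits(hits)
S4Vectors_to <- function(hits) S4Vectors::subjectHits(hits)

#' Assign markers to genomic regions by containment
#'
#' Each marker position is annotated with the id of the region containing
#' it, endpoints inclusive (1-based); markers in no region get `NA`, markers
#' in several get all ids comma-joined.
#'
#' @param markers data frame with columns `chrom, pos` (plus any id column,
#'   carried through).
#' @param regions data frame with columns `region_id, chrom, start, end`, on
#'   the same genome as the markers.
#' @return the `markers` data frame with a `region_id` column added.
#' @export
map_markers_to_regions <- function(markers, regions) {
  markers <- as.data.frame(markers); regions <- as.data.frame(regions)
  stopifnot(all(c("chrom", "pos") %in% names(markers)),
            all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  if (nrow(markers) == 0) {
    markers$region_id <- character(0)
    return(markers)
  }
  mg <- GenomicRanges::GRanges(markers$chrom,
                               IRanges::IRanges(markers$pos, markers$pos))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mg, rg))
  ids <- rep(NA_character_, nrow(markers))
  qh <- S4Vectors_from(hits); sh <- S4Vectors_to(hits)
  for (i in unique(qh)) {
    ids[i] <- paste(sort(unique(regions$region_id[sh[qh == i]])),
                    collapse = ",")
  }
  markers$region_id <- ids
  markers
}

#' Load the packaged conserved syntenic sugar-QTL fixture
#'
#' Three cross-genus synteny blocks (segments in the peach Ppv1, strawberry
#' Fvv1 and apple Mdv1 assemblies) together with the sugar-related QTL
#' intervals reported in those genomes; each block carries QTL from at least
#' two species.
#'
#' @return list with data frames `blocks` and `qtls`.
#' @export
load_table2_fixture <- function() {
  blocks <- read.delim(system.file("extdata", "table2_synteny_blocks.tsv",
                                   package = "polybrix", mustWork = TRUE),
                       stringsAsFactors = FALSE)
  qtls <- read.delim(system.file("extdata", "table2_qtl.tsv",
                                 package = "polybrix", mustWork = TRUE),
                     stringsAsFactors = FALSE)
  list(blocks = blocks, qtls = qtls)
}
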