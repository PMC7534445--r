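# IUPAC nucleotide ambiguity codes, keyed by the sorted base set they cover
IUPAC_CODES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W", "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V", "ACGT" = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- IUPAC_CODES[[key]]
  if (is.null(code)) stop("cannot IUPAC-encode bases: ", key, call. = FALSE)
  code
}

#' Design a KASP-style flanking consensus sequence
#'
#' Builds the consensus template submitted for allele-specific assay design:
#' the target diagnostic allele substituted into the reference at its
#' position, flanked by `flank` reference bases on each side, with every
#' other SNP site in the window replaced by the IUPAC ambiguity code
#' covering the reference base plus its alternates ("designed with a
#' preference toward the target allele": the target itself is written
#' verbatim, never ambiguity-coded). Insertion/deletion variants in the
#' flanks cannot be represented in an ungapped template; they are reported
#' as warning flags instead, with their distance from the target, because
#' flanking indels are a known cause of assay failure.
#'
#' @param ref_seq reference sequence covering the window, as a single
#'   character string of A/C/G/T.
#' @param ref_start 1-based genomic position of the first base of `ref_seq`.
#' @param variants data frame of polymorphic sites in the window: columns
#'   `pos` (1-based), `ref`, `alt` (comma-separated alternates). Must
#'   include the target site.
#' @param target_pos genomic position of the target variant.
#' @param target_allele the diagnostic allele to write at `target_pos`; must
#'   be one of that site's recorded alleles (REF or an ALT).
#' @param flank flanking length in bases on each side of the target.
#' @return object of class `consensus_template`: list with `sequence`,
#'   `target_offset` (1-based offset of the target allele within
#'   `sequence`), `target_allele`, `locus` (`"pos"`-less id is the caller's
#'   concern; the genomic `target_pos` is stored), `flank`,
#'   `ambiguity_sites` (offsets recoded), and `indel_flags` (data frame of
#'   flanking indels: pos, distance, ref, alt).
#' @export
design_consensus <- function(ref_seq, ref_start, variants, target_pos,
                             target_allele, flank = 50) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1)
  variants <- as.data.frame(variants)
  stopifnot(all(c("pos", "ref", "alt") %in% names(variants)))
  tv <- variants[variants$pos == target_pos, , drop = FALSE]
  if (nrow(tv) != 1) {
    stop("target position absent from the variant record", call. = FALSE)
  }
  site_alleles <- c(tv$ref, strsplit(tv$alt, ",", fixed = TRUE)[[1]])
  if (!target_allele %in% site_alleles) {
    stop("target allele absent from the variant record", call. = FALSE)
  }

  win_start <- target_pos - flank
  win_end <- target_pos + nchar(tv$ref) - 1L + flank
  ref_end <- ref_start + nchar(ref_seq) - 1L
  if (win_start < ref_start || win_end > ref_end) {
    stop("reference sequence does not cover the flanking window", call. = FALSE)
  }
  left <- substr(ref_seq, win_start - ref_start + 1L,
                 target_pos - ref_start)
  right <- substr(ref_seq, target_pos - ref_start + 1L + nchar(tv$ref),
                  win_end - ref_start + 1L)
  seq_chars <- c(strsplit(left, "")[[1]], strsplit(target_allele, "")[[1]],
                 strsplit(right, "")[[1]])
  target_offset <- flank + 1L

  others <- variants[variants$pos != target_pos, , drop = FALSE]
  ambiguity_sites <- integer(0)
  indel_flags <- data.frame(pos = integer(), distance = integer(),
                            ref = character(), alt = character(),
                            stringsAsFactors = FALSE)
  for (i in seq_len(nrow(others))) {
    v <- others[i, ]
    alts <- strsplit(v$alt, ",", fixed = TRUE)[[1]]
    in_window <- v$pos >= win_start && v$pos <= win_end
    if (!in_window) next
    is_indel <- any(nchar(alts) != nchar(v$ref)) || nchar(v$ref) > 1
    if (is_indel) {
      indel_flags <- rbind(indel_flags, data.frame(
        pos = v$pos, distance = abs(v$pos - target_pos),
        ref = v$ref, alt = v$alt, stringsAsFactors = FALSE
      ))
      next
    }
    off <- v$pos - win_start + 1L
    # offsets past the target shift by the target-allele length difference
    if (v$pos > target_pos) {
      off <- off + nchar(target_allele) - nchar(tv$ref)
    }
    if (off == target_offset) next  # never ambiguity-code the target itself
    seq_chars[off] <- iupac_code(c(v$ref, alts))
    ambiguity_sites <- c(ambiguity_sites, off)
  }
  if (nrow(indel_flags)) {
    warning(sprintf("%d indel variant(s) in the flanking window (nearest %d bp from target); templates are ungapped so these may interfere with the assay",
                    nrow(indel_flags), min(indel_flags$distance)),
            call. = FALSE)
  }
  structure(list(
    sequence = paste(seq_chars, collapse = ""),
    target_offset = target_offset,
    target_allele = target_allele,
    target_pos = target_pos, flank = flank,
    ambiguity_sites = sort(ambiguity_sites),
    indel_flags = indel_flags
  ), class = "consensus_template")
}

#' @export
print.consensus_template <- function(x, ...) {
  cat(sprintf("<consensus_template> %d nt, target '%s' at offset %d\n",
              nchar(x$sequence), x$target_allele, x$target_offset))
  if (nrow(x$indel_flags)) {
    cat(sprintf("  warning: %d flanking indel(s), nearest %d bp from target\n",
                nrow(x$indel_flags), min(x$indel_flags$distance)))
  }
  invisible(x)
}

#' Write consensus templates to FASTA
#'
#' @param templates a `consensus_template` or list of them.
#' @param path output FASTA path.
#' @param names optional record names; defaults to `pos_allele`.
#' @return invisibly, `path`.
#' @export
write_consensus_fasta <- function(templates, path, names = NULL) {
  if (inherits(templates, "consensus_template")) templates <- list(templates)
  if (is.null(names)) {
    names <- vapply(templates, function(t) {
      paste0("target_", t$target_pos, "_", t$target_allele)
    }, character(1))
  }
  lines <- unlist(lapply(seq_along(templates), function(i) {
    c(paste0(">", names[i]), templates[[i]]$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}
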