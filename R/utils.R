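# internal helpers shared across modules

# round half-up to `digits` decimals; base round() is half-to-even which
# disagrees with how percentages are conventionally printed in reports
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}

# canonical locus id used everywhere ("Ro01:14978562" style)
locus_id <- function(chrom, pos) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", pos)
}

# stable md5 of an R object, used to stamp pipeline artifacts with the config
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}
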