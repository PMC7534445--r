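#' Run the simulate -> table -> associate -> validate workflow
#'
#' Orchestrates the package's stages as one reproducible run. A config list
#' controls which stages execute; every artifact written to the run
#' directory carries the MD5 hash of the config, and a rerun with the same
#' config reproduces identical deterministic outputs. Stage failures abort
#' with the stage name; files already written are left in place.
#'
#' @param config list with elements:
#'   * `sim`: a [sim_config()] (required unless `vcf`/`depth`/`phenotypes`
#'     paths are given);
#'   * `vcf`, `depth`, `phenotypes`: input paths for a pre-existing cohort;
#'   * `alpha` (default 0.05), `max_missing` (0.2), `min_alleles` (2),
#'     `max_alleles` (4), `min_class_size` (3);
#'   * `structure`: `"infer"` (default) or a named vector of external group
#'     labels;
#'   * `k_range` (default `1:10`), `seed` (default 1);
#'   * `stages`: character subset of `c("simulate", "table", "associate",
#'     "validate")` (default all that are applicable).
#' @param out_dir run directory (created).
#' @return invisibly, a list with the association result (`assoc`), the
#'   validation table (`validation`), the config hash and `out_dir`.
#' @export
run_ssc_pipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  defaults <- list(alpha = 0.05, max_missing = 0.20, min_alleles = 2,
                   max_alleles = 4, min_class_size = 3, structure = "infer",
                   k_range = 1:10, seed = 1L,
                   stages = c("simulate", "table", "associate", "validate"))
  config <- utils::modifyList(defaults, config)
  hash <- config_hash(config[setdiff(names(config), "stages")])
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  cat(sprintf("config_hash\t%s\n", hash),
      file = file.path(out_dir, "config_hash.txt"))
  writeLines(jsonlite::toJSON(config[setdiff(names(config), "stages")],
                              auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE, pretty = TRUE),
             file.path(out_dir, "config.json"))

  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logf("stage %s: done", name)
    res
  }

  stamp_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    writeLines(paste0("# config_hash=", hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }

  paths <- config[c("vcf", "depth", "phenotypes")]
  cohort <- NULL
  if ("simulate" %in% config$stages && !is.null(config$sim)) {
    sim_out <- stage("simulate", {
      co <- simulate_cohort(config$sim)
      p <- write_cohort(co, file.path(out_dir, "cohort"))
      logf("simulated %d loci x %d samples", nrow(co$loci), nrow(co$samples))
      list(cohort = co, paths = p)
    })
    cohort <- sim_out$cohort
    paths <- sim_out$paths
  }
  if (!("table" %in% config$stages) || is.null(paths$vcf)) {
    logf("stopping after requested stages")
    return(invisible(list(assoc = NULL, validation = NULL,
                          config_hash = hash, out_dir = out_dir)))
  }

  tab <- stage("table", {
    t0 <- build_genotype_table(paths$vcf)
    dp <- read.delim(paths$depth, stringsAsFactors = FALSE)
    t1 <- apply_depth_missingness(t0, dp)
    logf("genotype table: %d loci x %d samples", nrow(t1$loci),
         length(t1$samples))
    t1
  })
  ph <- read.delim(paths$phenotypes, stringsAsFactors = FALSE)
  ssc <- tapply(ph$ssc_brix, ph$sample, mean)
  ssc <- setNames(as.numeric(ssc), names(ssc))

  if (!("associate" %in% config$stages)) {
    return(invisible(list(assoc = NULL, validation = NULL,
                          config_hash = hash, out_dir = out_dir)))
  }
  assoc <- stage("associate", {
    groups <- if (identical(config$structure, "infer")) NULL else config$structure
    a <- associate_alleles(tab, ssc, groups = groups, alpha = config$alpha,
                           max_missing = config$max_missing,
                           min_alleles = config$min_alleles,
                           max_alleles = config$max_alleles,
                           min_class_size = config$min_class_size,
                           k_range = config$k_range, seed = config$seed)
    logf("attrition: %s", paste(names(a$attrition), a$attrition,
                                sep = "=", collapse = ", "))
    a
  })
  stamp_tsv(assoc$records, "association.tsv")
  stamp_tsv(data.frame(sample = names(assoc$groups), group = assoc$groups),
            "groups.tsv")

  validation <- NULL
  if ("validate" %in% config$stages && any(assoc$records$selected)) {
    validation <- stage("validate", {
      sel <- assoc$records$col_id[assoc$records$selected]
      calls <- assoc$matrix$presence[, sel, drop = FALSE]
      v <- validate_per_environment(calls, ph, alpha = config$alpha,
                                    min_class_size = config$min_class_size)
      stamp_tsv(v, "validation.tsv")
      v
    })
  }

  report <- summarize_run(out_dir)
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(list(assoc = assoc, validation = validation, config_hash = hash,
                 out_dir = out_dir))
}

read_stamped_tsv <- function(path) {
  if (!file.exists(path)) return(NULL)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Summarise a pipeline run directory
#'
#' Recounts the attrition funnel (loci in, after filters, tested,
#' BH-significant, model-selected, validated) directly from the stage TSVs
#' of a run directory and formats a short markdown report. Missing stage
#' outputs are listed as absent rather than failing.
#'
#' @param run_dir a directory produced by [run_ssc_pipeline()].
#' @return character vector of markdown lines (also suitable for
#'   `writeLines`).
#' @export
summarize_run <- function(run_dir) {
  hash_file <- file.path(run_dir, "config_hash.txt")
  hash <- if (file.exists(hash_file)) {
    strsplit(readLines(hash_file)[1], "\t")[[1]][2]
  } else "(absent)"
  assoc <- read_stamped_tsv(file.path(run_dir, "association.tsv"))
  valid <- read_stamped_tsv(file.path(run_dir, "validation.tsv"))
  groups <- read_stamped_tsv(file.path(run_dir, "groups.tsv"))

  lines <- c("# SSC association run summary", "",
             paste0("config hash: `", hash, "`"), "")
  if (is.null(assoc)) {
    lines <- c(lines, "association table: absent", "",
               "| stage | count |", "|---|---|",
               "| alleles tested | 0 |", "| BH-significant | 0 |",
               "| selected | 0 |", "| validated | 0 |")
  } else {
    n_tested <- sum(!is.na(assoc$p))
    n_sig <- sum(!is.na(assoc$q) & assoc$q <= 0.05)
    n_sel <- sum(assoc$selected)
    n_val <- if (is.null(valid)) NA_integer_ else
      length(unique(valid$marker[valid$significant]))
    lines <- c(lines,
               "| stage | count |", "|---|---|",
               sprintf("| locus-allele columns | %d |", nrow(assoc)),
               sprintf("| tested (Welch) | %d |", n_tested),
               sprintf("| BH-significant | %d |", n_sig),
               sprintf("| model-selected | %d |", n_sel),
               if (is.na(n_val)) "| validated | (absent) |" else
                 sprintf("| validated in >=1 environment | %d |", n_val))
  }
  if (!is.null(groups)) {
    tab <- table(groups$group)
    lines <- c(lines, "",
               sprintf("groups: %s",
                       paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                             collapse = ", ")))
  }
  lines
}
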