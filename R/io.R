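#' Read a per-sample MRD measurement table
#'
#' Reads the canonical delimited measurement table: one row per sample and
#' assay, mandatory columns `patient_id`, `assay` (NGS or MFC),
#' `cells_assayed`, `tumor_count`, and optional columns `tumor_load` (a
#' direct-TL override in \[0, 1\]), `response` and `timepoint`. Comma and
#' tab delimiters are auto-detected; numeric fields accept plain, `1.1e6`
#' exponential and `1.1 x 10^6` / `1.1 × 10^6` scientific notation.
#'
#' Rows violating the invariants (non-positive cell counts, tumor counts
#' exceeding the cells assayed, unknown assay or response tokens, overrides
#' outside \[0, 1\]) are rejected with a line-numbered error so source files
#' can be fixed in place.
#'
#' @param path Path to a CSV/TSV file with a header row.
#'
#' @return A validated tibble of measurements.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,assay,cells_assayed,tumor_count,response,timepoint",
#'              "P1,NGS,1.1e6,45,CR,post_ASCT1",
#'              "P1,MFC,5.0e6,0,CR,post_ASCT1"), tf)
#' read_measurements(tf)
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
  mandatory <- c("patient_id", "assay", "cells_assayed", "tumor_count")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  out <- tibble::tibble(
    patient_id = raw$patient_id,
    assay = toupper(raw$assay),
    cells_assayed = parse_scientific(raw$cells_assayed),
    tumor_count = parse_scientific(raw$tumor_count)
  )
  out$tumor_load <- if ("tumor_load" %in% names(raw))
    parse_scientific(raw$tumor_load) else NA_real_
  out$response <- if ("response" %in% names(raw)) {
    r <- raw$response
    r[is.na(r) | r == ""] <- "NA"
    r
  } else "NA"
  out$timepoint <- if ("timepoint" %in% names(raw)) {
    tp <- raw$timepoint
    tp[is.na(tp) | tp == ""] <- "NA"
    tp
  } else "NA"

  # data line numbers (header is line 1)
  line <- seq_len(nrow(out)) + 1L
  problems <- character()
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      problems <<- c(problems, sprintf("line %d: %s",
                                       line[which(bad)], msg))
    }
  }
  flag(is.na(out$cells_assayed) | out$cells_assayed < 1,
       "cells_assayed must be a number >= 1")
  flag(!out$assay %in% .mrd_assays, "unknown assay token (expected NGS|MFC)")
  flag(is.na(out$tumor_count) & is.na(out$tumor_load),
       "tumor_count and tumor_load both absent")
  flag(!is.na(out$tumor_count) & out$tumor_count < 0,
       "tumor_count must be non-negative")
  flag(!is.na(out$tumor_count) & !is.na(out$cells_assayed) &
         out$tumor_count > out$cells_assayed,
       "tumor_count exceeds cells_assayed")
  flag(!is.na(out$tumor_load) & (out$tumor_load < 0 | out$tumor_load > 1),
       "tumor_load override outside [0, 1]")
  flag(!out$response %in% .mrd_responses, "unknown response token")
  flag(!out$timepoint %in% .mrd_timepoints, "unknown timepoint token")
  if (length(problems)) {
    stop("invalid measurement rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]: writes the canonical comma-separated
#' measurement table (UTF-8, header row) so that a write/read round trip
#' preserves all records.
#'
#' @param measurements Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# normalize "1.1e6", "1.1 x 10^6", "1.1 × 10^6", "10^-5" to numbers
parse_scientific <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  x <- gsub("×", "x", x)
  x <- sub("^([0-9.+-]+)\\s*x\\s*10\\^\\s*([0-9+-]+)$", "\\1e\\2", x)
  x <- sub("^10\\^\\s*([0-9+-]+)$", "1e\\1", x)
  suppressWarnings(as.numeric(x))
}

#' Run the full cohort analysis
#'
#' Chains the cohort-level analytics into one summary object: the cut-off
#' sweep, the NGS/MFC concordance with kappa, the response-stratified MRD
#' rates, the tumor-load comparison and the per-sample calls at the primary
#' cut-off.
#'
#' @param measurements Measurement table (see [read_measurements()]).
#' @param cutoff Primary MRD cut-off for the concordance, stratification,
#'   tumor-load comparison and per-sample calls. Default 1e-5.
#' @param cutoffs Cut-off set for the sweep. Default [mrd_cutoffs()].
#' @param constants An [assay_constants()] object.
#' @param tl_scale,n_outliers Passed to [compare_tl()].
#'
#' @return A list of class `cohort_summary` with elements `sweep`,
#'   `concordance`, `stratified`, `tl_comparison`, `calls` and `cutoff`.
#'   `concordance` and `tl_comparison` are `NULL` (with a warning) when the
#'   cohort cannot support them (no complete pairs, too few concordant
#'   positives).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 60, seed = 2))
#' summary <- summarize_cohort(cohort$measurements)
#' summary$concordance
summarize_cohort <- function(measurements, cutoff = 1e-5,
                             cutoffs = mrd_cutoffs()$value,
                             constants = assay_constants(),
                             tl_scale = "log10", n_outliers = 2) {
  conc <- tryCatch(
    mrd_concordance(measurements, cutoff, constants),
    error = function(e) {
      warning("concordance skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  tlc <- tryCatch(
    compare_tl(measurements, cutoff, constants, tl_scale, n_outliers),
    error = function(e) {
      warning("tumor-load comparison skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  structure(
    list(
      sweep = sweep_cutoffs(measurements, cutoffs, constants),
      concordance = conc,
      stratified = stratify_by_response(measurements, cutoff, constants),
      tl_comparison = tlc,
      calls = mrd_call(measurements, cutoff, constants),
      cutoff = cutoff
    ),
    class = "cohort_summary"
  )
}

#' Write a cohort analysis report to disk
#'
#' Emits the standard report files for a [summarize_cohort()] result:
#' `sweep.csv`, `concordance.json`, `stratified.csv`, `tl_comparison.json`,
#' `calls.csv` and `run_metadata.json` (package version, input hash, seed).
#' Proportions in the CSVs are formatted as percentages to one decimal;
#' the JSON files carry full precision.
#'
#' @param summary A `cohort_summary` object.
#' @param dir Output directory; created if absent.
#' @param seed Optional seed to record in the run metadata.
#'
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(summary, dir, seed = NULL) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  written <- character()
  emit_csv <- function(df, name) {
    pct <- dplyr::mutate(df, dplyr::across(
      dplyr::starts_with("prop_"), ~ sprintf("%.1f", 100 * .x)))
    p <- file.path(dir, name)
    write.csv(pct, p, row.names = FALSE, na = "")
    written <<- c(written, p)
  }
  emit_json <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    written <<- c(written, p)
  }

  emit_csv(summary$sweep, "sweep.csv")
  emit_csv(summary$stratified$by_response, "stratified.csv")
  emit_csv(summary$calls, "calls.csv")
  if (!is.null(summary$concordance)) {
    co <- summary$concordance
    emit_json(list(cutoff = co$cutoff, n_total = co$n_total,
                   counts = as.list(co$counts),
                   proportions = as.list(co$proportions),
                   kappa = co$kappa, kappa_n = co$kappa_n,
                   n_excluded = co$n_excluded),
              "concordance.json")
  }
  if (!is.null(summary$tl_comparison)) {
    tc <- summary$tl_comparison
    emit_json(tc[c("n_pairs", "pearson_r", "cor_p_value",
                   "pearson_r_outliers_removed", "n_outliers_removed",
                   "outlier_patients", "t_statistic", "p_value", "scale",
                   "cutoff")],
              "tl_comparison.json")
  }
  emit_json(list(
    package = "mrdeval",
    version = as.character(packageVersion("mrdeval")),
    cutoff = summary$cutoff,
    input_hash = rlang::hash(summary$calls[c("patient_id", "assay",
                                             "cells_assayed", "tumor_count")]),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC")
  ), "run_metadata.json")
  invisible(written)
}
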