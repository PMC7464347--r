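#' Sweep MRD status counts over a set of cut-offs
#'
#' Calls every measurement at every cut-off and tabulates, per assay and
#' cut-off, how many samples are MRD-positive, MRD-negative and
#' nonassessable. Lowering the cut-off can only move samples out of the
#' negative class (towards positive at first, then — once the cut-off
#' undercuts a sample's LOD — towards nonassessable), which is the mechanism
#' that makes very deep study-wide cut-offs costly in assessability.
#'
#' @param measurements Measurement table (see [read_measurements()]).
#' @param cutoffs Numeric vector of cut-offs (fractions); defaults to the
#'   consensus set [mrd_cutoffs()].
#' @param constants An [assay_constants()] object.
#'
#' @return A tibble with one row per (assay, cutoff): columns `assay`,
#'   `cutoff`, `n`, `positive`, `negative`, `nonassessable` and the matching
#'   `prop_*` proportions of `n`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 40, seed = 1))
#' sweep_cutoffs(cohort$measurements)
sweep_cutoffs <- function(measurements, cutoffs = mrd_cutoffs()$value,
                          constants = assay_constants()) {
  measurements <- tibble::as_tibble(measurements)
  if (nrow(measurements) == 0) {
    stop("measurement table is empty", call. = FALSE)
  }
  if (length(cutoffs) == 0) stop("no cutoffs supplied", call. = FALSE)
  cutoffs <- sort(unique(cutoffs), decreasing = TRUE)

  res <- lapply(cutoffs, function(co) {
    mrd_call(measurements, cutoff = co, constants = constants) |>
      dplyr::count(.data$assay, .data$status) |>
      tidyr::pivot_wider(names_from = "status", values_from = "n",
                         values_fill = 0L) |>
      dplyr::mutate(cutoff = co)
  })
  out <- dplyr::bind_rows(res)
  for (col in .mrd_statuses) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out |>
    dplyr::mutate(n = .data$positive + .data$negative + .data$nonassessable,
                  prop_positive = .data$positive / .data$n,
                  prop_negative = .data$negative / .data$n,
                  prop_nonassessable = .data$nonassessable / .data$n) |>
    dplyr::select("assay", "cutoff", "n", "positive", "negative",
                  "nonassessable", dplyr::starts_with("prop_")) |>
    dplyr::arrange(.data$assay, dplyr::desc(.data$cutoff))
}

#' Paired NGS/MFC concordance with Cohen's kappa
#'
#' Partitions the cohort's paired calls at one cut-off into five disjoint
#' classes: concordant positive, concordant negative, discordant with NGS
#' positive, discordant with MFC positive, and pairs where either call is
#' nonassessable because the sample's LOD undercuts the cut-off
#' (`lod_discordant`). Overall concordance is (concordant positive +
#' concordant negative) / all pairs. Cohen's kappa is computed on the 2x2
#' table of the assessable pairs only, i.e. excluding the `lod_discordant`
#' class; `kappa_n` makes that exclusion explicit.
#'
#' Patients lacking either assay are excluded with a warning.
#'
#' @inheritParams sweep_cutoffs
#' @param cutoff A single MRD cut-off (fraction).
#'
#' @return A list of class `mrd_concordance`: `n_total`, `counts` (named
#'   integer vector over the five classes), `proportions`, `table` (the 2x2
#'   assessable-pair table, NGS in rows), `kappa`, `kappa_n`, `cutoff` and
#'   `n_excluded` (patients without both assays).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 60, seed = 7))
#' mrd_concordance(cohort$measurements, cutoff = 1e-5)
mrd_concordance <- function(measurements, cutoff = 1e-5,
                            constants = assay_constants()) {
  calls <- mrd_call(measurements, cutoff = cutoff, constants = constants)
  pairs <- calls |>
    dplyr::select("patient_id", "assay", "status") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "status")
  for (a in .mrd_assays) if (!a %in% names(pairs)) pairs[[a]] <- NA_character_
  incomplete <- is.na(pairs$NGS) | is.na(pairs$MFC)
  if (any(incomplete)) {
    warning(sum(incomplete),
            " patient(s) lack one of the two assays and were excluded ",
            "from the concordance analysis", call. = FALSE)
    pairs <- pairs[!incomplete, ]
  }
  n_total <- nrow(pairs)
  if (n_total == 0) stop("no complete NGS/MFC pairs", call. = FALSE)

  nonass <- pairs$NGS == "nonassessable" | pairs$MFC == "nonassessable"
  counts <- c(
    concordant_pos = sum(!nonass & pairs$NGS == "positive" &
                           pairs$MFC == "positive"),
    concordant_neg = sum(!nonass & pairs$NGS == "negative" &
                           pairs$MFC == "negative"),
    discordant_ngs_pos = sum(!nonass & pairs$NGS == "positive" &
                               pairs$MFC == "negative"),
    discordant_mfc_pos = sum(!nonass & pairs$NGS == "negative" &
                               pairs$MFC == "positive"),
    lod_discordant = sum(nonass)
  )
  tab <- matrix(counts[c("concordant_pos", "discordant_ngs_pos",
                         "discordant_mfc_pos", "concordant_neg")],
                nrow = 2, byrow = TRUE,
                dimnames = list(NGS = c("positive", "negative"),
                                MFC = c("positive", "negative")))
  structure(
    list(
      n_total = n_total,
      counts = counts,
      proportions = counts / n_total,
      table = tab,
      kappa = cohen_kappa(tab),
      kappa_n = sum(tab),
      cutoff = cutoff,
      n_excluded = sum(incomplete)
    ),
    class = "mrd_concordance"
  )
}

#' @export
print.mrd_concordance <- function(x, ...) {
  cat(sprintf("NGS/MFC MRD concordance at cut-off %g (n = %d pairs)\n",
              x$cutoff, x$n_total))
  cat(sprintf("  concordant: %.1f%% (pos %d, neg %d)\n",
              100 * (x$proportions[["concordant_pos"]] +
                       x$proportions[["concordant_neg"]]),
              x$counts[["concordant_pos"]], x$counts[["concordant_neg"]]))
  cat(sprintf("  discordant: %.1f%% (NGS+ %d, MFC+ %d)\n",
              100 * (x$proportions[["discordant_ngs_pos"]] +
                       x$proportions[["discordant_mfc_pos"]]),
              x$counts[["discordant_ngs_pos"]],
              x$counts[["discordant_mfc_pos"]]))
  cat(sprintf("  LOD-discordant (either nonassessable): %.1f%% (n = %d)\n",
              100 * x$proportions[["lod_discordant"]],
              x$counts[["lod_discordant"]]))
  cat(sprintf("  Cohen's kappa = %.3f (n = %d assessable pairs)\n",
              x$kappa, x$kappa_n))
  invisible(x)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected interrater agreement: `kappa = (po - pe) / (1 - pe)`
#' where `po` is the observed agreement proportion (diagonal mass) and `pe`
#' the expected agreement under independent raters with the observed
#' marginals. Degenerate tables with `pe = 1` (all mass in one row/column
#' combination) return 1 when the observed agreement is also perfect and 0
#' otherwise.
#'
#' @param table A 2x2 matrix of non-negative counts, raters in rows/columns,
#'   or a length-4 vector `(a, b, c, d)` read row-wise.
#'
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohen_kappa(matrix(c(42, 14, 14, 43), 2, byrow = TRUE))  # ~0.504
cohen_kappa <- function(table) {
  if (is.vector(table) && length(table) == 4) {
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(table) || any(dim(table) != 2) || any(table < 0)) {
    stop("table must be a 2x2 matrix of non-negative counts", call. = FALSE)
  }
  n <- sum(table)
  if (n == 0) stop("all-zero agreement table", call. = FALSE)
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Response-stratified MRD rates
#'
#' Cross-tabulates MRD status at one cut-off against the serological
#' response category, per assay, and aggregates the MRD-negativity rate over
#' patients with a response of VGPR or better (CR, nCR and VGPR strata
#' only). Empty strata report `NA` proportions, not 0.
#'
#' @inheritParams mrd_concordance
#'
#' @return A list: `by_response` (tibble with `assay`, `response`, `n`,
#'   status counts and within-stratum proportions) and `vgpr_or_better`
#'   (tibble per assay with the aggregate `n`, `negative` count and
#'   `prop_negative`).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 100, seed = 3))
#' stratify_by_response(cohort$measurements)$vgpr_or_better
stratify_by_response <- function(measurements, cutoff = 1e-5,
                                 constants = assay_constants()) {
  calls <- mrd_call(measurements, cutoff = cutoff, constants = constants)
  if (!"response" %in% names(calls)) {
    stop("measurement table lacks a response column", call. = FALSE)
  }
  grid <- tidyr::expand_grid(assay = sort(unique(calls$assay)),
                             response = .mrd_responses)
  by_response <- calls |>
    dplyr::count(.data$assay, .data$response, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L) |>
    dplyr::right_join(grid, by = c("assay", "response"))
  for (col in .mrd_statuses) {
    if (!col %in% names(by_response)) by_response[[col]] <- 0L
    by_response[[col]][is.na(by_response[[col]])] <- 0L
  }
  by_response <- by_response |>
    dplyr::mutate(
      n = .data$positive + .data$negative + .data$nonassessable,
      prop_positive = ifelse(.data$n > 0, .data$positive / .data$n, NA_real_),
      prop_negative = ifelse(.data$n > 0, .data$negative / .data$n, NA_real_),
      prop_nonassessable = ifelse(.data$n > 0,
                                  .data$nonassessable / .data$n, NA_real_),
      response = factor(.data$response, levels = .mrd_responses)
    ) |>
    dplyr::arrange(.data$assay, .data$response) |>
    dplyr::select("assay", "response", "n", "positive", "negative",
                  "nonassessable", dplyr::starts_with("prop_"))

  vgpr_or_better <- by_response |>
    dplyr::filter(.data$response %in% c("CR", "nCR", "VGPR")) |>
    dplyr::summarise(n = sum(.data$n), negative = sum(.data$negative),
                     .by = "assay") |>
    dplyr::mutate(prop_negative = ifelse(.data$n > 0,
                                         .data$negative / .data$n, NA_real_))

  list(by_response = by_response, vgpr_or_better = vgpr_or_better)
}

#' Compare tumor loads between NGS and MFC among concordant positives
#'
#' Restricts the cohort to pairs where both assays call MRD-positive at the
#' cut-off, then (on a log10 scale by default, since tumor loads span
#' several orders of magnitude) computes Pearson's product-moment
#' correlation between the paired tumor loads, a two-sided paired t-test of
#' the NGS-vs-MFC difference, and a robustified correlation after removing
#' the `n_outliers` pairs with the largest absolute residuals from the
#' least-squares line of MFC on NGS.
#'
#' @inheritParams mrd_concordance
#' @param scale `"log10"` (default) or `"linear"` — the scale on which the
#'   correlation and t-test are computed.
#' @param n_outliers Number of extreme off-line pairs to remove for the
#'   robustified correlation. Default 2.
#'
#' @return A list of class `mrd_tl_comparison`: `n_pairs`, `pearson_r`,
#'   `cor_p_value`, `pearson_r_outliers_removed`, `n_outliers_removed`,
#'   `outlier_patients`, `t_statistic`, `p_value` (paired t-test), `scale`
#'   and `pairs` (tibble of the paired tumor loads used).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 120, seed = 11))
#' compare_tl(cohort$measurements)$pearson_r
compare_tl <- function(measurements, cutoff = 1e-5,
                       constants = assay_constants(),
                       scale = c("log10", "linear"), n_outliers = 2) {
  scale <- match.arg(scale)
  calls <- mrd_call(measurements, cutoff = cutoff, constants = constants)
  pairs <- calls |>
    dplyr::filter(.data$status == "positive") |>
    dplyr::select("patient_id", "assay", "tl") |>
    tidyr::pivot_wider(names_from = "assay", values_from = "tl") |>
    tidyr::drop_na()
  if (nrow(pairs) < 3) {
    stop("need at least 3 concordant MRD-positive pairs (have ",
         nrow(pairs), ")", call. = FALSE)
  }
  x <- pairs$NGS
  y <- pairs$MFC
  if (scale == "log10") {
    x <- log10(x)
    y <- log10(y)
  }

  ct <- cor.test(x, y, method = "pearson")
  if (stats::sd(x - y) == 0) {
    # zero-variance differences (e.g. self-comparison): no evidence of shift
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- t.test(x, y, paired = TRUE)
  }

  n_outliers <- min(n_outliers, nrow(pairs) - 3)
  if (n_outliers > 0) {
    resid <- abs(residuals(lm(y ~ x)))
    drop <- order(resid, decreasing = TRUE)[seq_len(n_outliers)]
    r_clean <- cor.test(x[-drop], y[-drop], method = "pearson")$estimate
    outlier_ids <- pairs$patient_id[drop]
  } else {
    r_clean <- unname(ct$estimate)
    outlier_ids <- character()
  }

  structure(
    list(
      n_pairs = nrow(pairs),
      pearson_r = unname(ct$estimate),
      cor_p_value = ct$p.value,
      pearson_r_outliers_removed = unname(r_clean),
      n_outliers_removed = n_outliers,
      outlier_patients = outlier_ids,
      t_statistic = unname(tt$statistic),
      p_value = tt$p.value,
      scale = scale,
      cutoff = cutoff,
      pairs = pairs
    ),
    class = "mrd_tl_comparison"
  )
}

#' @export
print.mrd_tl_comparison <- function(x, ...) {
  cat(sprintf("Tumor-load comparison (%s scale, %d concordant-positive pairs at cut-off %g)\n",
              x$scale, x$n_pairs, x$cutoff))
  cat(sprintf("  Pearson r = %.3f (p = %.3g); after removing %d outlier(s): r = %.3f\n",
              x$pearson_r, x$cor_p_value, x$n_outliers_removed,
              x$pearson_r_outliers_removed))
  cat(sprintf("  paired t-test: t = %.3f, p = %.3g\n", x$t_statistic,
              x$p_value))
  invisible(x)
}
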