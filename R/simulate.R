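#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a cohort of
#' patients, each with a serological response category, a latent true tumor
#' load, and one NGS plus one MFC bone-marrow measurement of that load.
#'
#' Defaults reproduce the cohort structure of a 125-patient paired NGS/MFC
#' myeloma MRD study: response frequencies CR 54, nCR 31, VGPR 24, PR 7,
#' MR 1, baseline 1 and NA 7 out of 125; NGS cell-equivalent counts spanning
#' 1.8e5–2.3e6 and MFC event counts 1.0e6–1.4e7 (drawn log-uniformly over
#' those printed ranges). The per-response probability of a truly
#' MRD-negative marrow and the per-response mean log10 tumor load are
#' calibration constants chosen so that response-stratified negativity rates
#' at a 1e-5 cut-off land near typical deep-response cohorts (see the
#' package vignette for the calibration); they live in the config, not in
#' code.
#'
#' @param n_patients Number of patients. Default 125.
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   config.
#' @param response_probs Named probability vector over the response tokens
#'   of [mrd_responses()]; must sum to 1.
#' @param p_mrd_negative_by_response Named vector: probability that a
#'   patient of each response category carries no residual clone at all
#'   (true tumor load exactly 0).
#' @param tl_log10_mean_by_response Named vector: mean of log10 true tumor
#'   load for residual-disease patients of each category.
#' @param tl_log10_sd Between-patient SD of log10 true tumor load.
#' @param ngs_cells_range,mfc_events_range Length-2 vectors (min, max) for
#'   the log-uniform draw of assayed cells/events.
#' @param cross_assay_log10_sd Assay-specific log10 noise SD applied
#'   independently to each assay's effective tumor load; controls the
#'   NGS–MFC tumor-load correlation (0 means both assays measure the shared
#'   true load exactly, up to counting noise).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 42)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(
    n_patients = 125,
    seed = 1L,
    response_probs = c(CR = 54, nCR = 31, VGPR = 24, PR = 7, MR = 1,
                       baseline = 1, `NA` = 7) / 125,
    p_mrd_negative_by_response = c(CR = 0.50, nCR = 0.30, VGPR = 0.05,
                                   PR = 0, MR = 0, baseline = 0, `NA` = 0.30),
    tl_log10_mean_by_response = c(CR = -4.7, nCR = -4.5, VGPR = -4.0,
                                  PR = -3.2, MR = -2.8, baseline = -1.5,
                                  `NA` = -4.5),
    tl_log10_sd = 0.8,
    ngs_cells_range = c(1.8e5, 2.3e6),
    mfc_events_range = c(1.0e6, 1.4e7),
    cross_assay_log10_sd = 0.45) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  for (v in list(response_probs, p_mrd_negative_by_response,
                 tl_log10_mean_by_response)) {
    if (!all(.mrd_responses %in% names(v))) {
      stop("response-indexed vectors must name every category of ",
           "mrd_responses()", call. = FALSE)
    }
  }
  if (abs(sum(response_probs) - 1) > 1e-8 || any(response_probs < 0)) {
    stop("response_probs must be a probability vector summing to 1",
         call. = FALSE)
  }
  if (any(p_mrd_negative_by_response < 0 | p_mrd_negative_by_response > 1)) {
    stop("p_mrd_negative_by_response entries must lie in [0, 1]",
         call. = FALSE)
  }
  for (rng in list(ngs_cells_range, mfc_events_range)) {
    if (length(rng) != 2 || rng[1] < 1 || rng[1] > rng[2]) {
      stop("cell/event ranges must be (min, max) with 1 <= min <= max",
           call. = FALSE)
    }
  }
  if (tl_log10_sd <= 0) stop("tl_log10_sd must be positive", call. = FALSE)
  if (cross_assay_log10_sd < 0) {
    stop("cross_assay_log10_sd must be non-negative", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         response_probs = response_probs,
         p_mrd_negative_by_response = p_mrd_negative_by_response,
         tl_log10_mean_by_response = tl_log10_mean_by_response,
         tl_log10_sd = tl_log10_sd,
         ngs_cells_range = ngs_cells_range,
         mfc_events_range = mfc_events_range,
         cross_assay_log10_sd = cross_assay_log10_sd),
    class = "sim_config"
  )
}

# timepoint frequencies used for the cosmetic timepoint column (they play no
# role in the sampling model)
.timepoint_probs <- c(baseline = 1, post_induction = 22,
                      post_mobilization = 1, post_ASCT1 = 57, post_ASCT2 = 2,
                      post_consolidation = 41, `NA` = 1) / 125

#' Simulate a paired NGS/MFC MRD cohort
#'
#' Generates, per patient: a serological response category; a residual-
#' disease indicator (with response-dependent probability of a truly clean
#' marrow); for residual-disease patients a latent true tumor load drawn
#' log-normally (log10-normal, clamped at 5e-2, the plasma-cell-burden
#' ceiling plausible after therapy); assay-specific effective tumor loads
#' obtained by perturbing the shared true load with independent log10-normal
#' noise (`cross_assay_log10_sd`); assayed cell/event counts drawn
#' log-uniformly over the configured ranges; and observed tumor counts drawn
#' `Binomial(cells_assayed, effective TL)` — the rare-cell sampling step
#' that makes small samples insensitive. There is no background or
#' contamination term: a patient with true load 0 always yields count 0.
#'
#' @param cfg A [sim_config()] object.
#'
#' @return A list with `measurements` (the standard measurement table: two
#'   rows per patient, one per assay) and `truth` (tibble with `patient_id`,
#'   `response`, `true_tl`, `eff_tl_ngs`, `eff_tl_mfc`).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 10, seed = 1))
#' cohort$measurements
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  response <- sample(names(cfg$response_probs), n, replace = TRUE,
                     prob = cfg$response_probs)
  timepoint <- sample(names(.timepoint_probs), n, replace = TRUE,
                      prob = .timepoint_probs)

  negative <- runif(n) < cfg$p_mrd_negative_by_response[response]
  log10_tl <- rnorm(n, mean = cfg$tl_log10_mean_by_response[response],
                    sd = cfg$tl_log10_sd)
  log10_tl <- pmin(log10_tl, log10(5e-2))
  true_tl <- ifelse(negative, 0, 10^log10_tl)

  eff <- function(true) {
    e <- true * 10^rnorm(n, 0, cfg$cross_assay_log10_sd)
    pmin(e, 1)  # zero truth stays exactly zero
  }
  eff_ngs <- eff(true_tl)
  eff_mfc <- eff(true_tl)

  draw_cells <- function(rng) {
    round(exp(runif(n, log(rng[1]), log(rng[2]))))
  }
  cells_ngs <- draw_cells(cfg$ngs_cells_range)
  cells_mfc <- draw_cells(cfg$mfc_events_range)

  count_ngs <- rbinom(n, cells_ngs, eff_ngs)
  count_mfc <- rbinom(n, cells_mfc, eff_mfc)

  measurements <- dplyr::bind_rows(
    tibble::tibble(patient_id = ids, assay = "NGS",
                   cells_assayed = cells_ngs, tumor_count = count_ngs,
                   response = response, timepoint = timepoint),
    tibble::tibble(patient_id = ids, assay = "MFC",
                   cells_assayed = cells_mfc, tumor_count = count_mfc,
                   response = response, timepoint = timepoint)
  ) |>
    dplyr::arrange(.data$patient_id, .data$assay)

  truth <- tibble::tibble(patient_id = ids, response = response,
                          true_tl = true_tl, eff_tl_ngs = eff_ngs,
                          eff_tl_mfc = eff_mfc)
  list(measurements = measurements, truth = truth)
}

#' Check how well the pipeline recovers the generator's latent state
#'
#' Test-harness companion to [simulate_cohort()]: joins the observed
#' measurements back onto the latent truth and reports (a) bias and RMSE of
#' the estimated log10 tumor load (count/cells vs the assay's effective
#' load) among quantifiable samples (effective load at or above the
#' sample's LOQ), (b) the empirical detection rate (count > 0) among
#' residual-disease samples together with its Poisson-approximation
#' expectation `1 - exp(-TL * cells)`, and (c) the false-positive count
#' among truly clean patients (always 0: the generator has no background
#' term).
#'
#' @param cohort Output of [simulate_cohort()] (list with `measurements`
#'   and `truth`).
#' @param constants An [assay_constants()] object.
#'
#' @return A list: `quantifiable` (tibble per assay with `n`, `log10_bias`,
#'   `log10_rmse`), `detection` (tibble per assay with `n`, observed and
#'   expected detection rates) and `false_positives` (integer).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 80, seed = 5))
#' recover_parameters(cohort)
recover_parameters <- function(cohort, constants = assay_constants()) {
  truth_long <- cohort$truth |>
    tidyr::pivot_longer(c("eff_tl_ngs", "eff_tl_mfc"),
                        names_to = "assay", values_to = "eff_tl") |>
    dplyr::mutate(assay = ifelse(.data$assay == "eff_tl_ngs", "NGS", "MFC")) |>
    dplyr::select("patient_id", "assay", "eff_tl", "true_tl")

  joined <- mrd_key_metrics(cohort$measurements, constants) |>
    dplyr::inner_join(truth_long, by = c("patient_id", "assay"))

  quantifiable <- joined |>
    dplyr::filter(.data$eff_tl >= .data$loq, .data$tumor_count > 0) |>
    dplyr::summarise(
      n = dplyr::n(),
      log10_bias = mean(log10(.data$tl) - log10(.data$eff_tl)),
      log10_rmse = sqrt(mean((log10(.data$tl) - log10(.data$eff_tl))^2)),
      .by = "assay"
    )

  detection <- joined |>
    dplyr::filter(.data$eff_tl > 0) |>
    dplyr::summarise(
      n = dplyr::n(),
      detection_rate = mean(.data$tumor_count > 0),
      expected_poisson = mean(1 - exp(-.data$eff_tl * .data$cells_assayed)),
      .by = "assay"
    )

  false_positives <- joined |>
    dplyr::filter(.data$true_tl == 0) |>
    dplyr::summarise(fp = sum(.data$tumor_count > 0)) |>
    dplyr::pull("fp")

  list(quantifiable = quantifiable, detection = detection,
       false_positives = as.integer(false_positives))
}
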