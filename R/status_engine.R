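#' Assign MRD status from key metrics at a cut-off
#'
#' Implements the two-step decision algorithm for a sample's MRD status given
#' its tumor load (TL), limit of detection (LOD) and a study-wide MRD
#' cut-off. The six mutually exclusive rules are:
#'
#' * **B1** — TL at or above the cut-off: the sample is MRD-positive provided
#'   the TL also reaches the LOD (`B1a` if TL >= LOQ, `B1b` if TL < LOQ);
#'   if the TL falls below the LOD the case is `nonassessable` (`B1c`).
#' * **B2** — TL below the cut-off: the sample is MRD-negative provided the
#'   LOD does not exceed the cut-off (`B2a` if the LOQ is also at or below
#'   the cut-off, `B2b` otherwise); if the LOD exceeds the cut-off no
#'   negative call is valid and the case is `nonassessable` (`B2c`).
#'
#' Ties are resolved inclusively on the favorable side (TL equal to the
#' cut-off is positive; LOD equal to the cut-off is assessable) after a
#' relative floating-point tolerance of `tol` is applied, so quotients such
#' as `30/3e6` compare cleanly against literal cut-offs.
#'
#' @param tl,lod,loq Numeric vectors of key metrics (fractions); recycled to
#'   a common length. `loq` is only used to distinguish the a/b sub-rules.
#' @param cutoff A single MRD cut-off (fraction in (0, 1]).
#' @param tol Relative comparison tolerance. Default 1e-9.
#'
#' @return A tibble with columns `status` (`positive`/`negative`/
#'   `nonassessable`) and `rule_fired` (`B1a`..`B2c`).
#' @seealso [assess_tl_quantifiability()], [mrd_call()]
#' @export
#' @examples
#' assign_status(tl = 4.1e-5, lod = 1.7e-6, loq = 2.2e-6, cutoff = 1e-5)
#' assign_status(tl = 0, lod = 3.0e-5, loq = 5.0e-5, cutoff = 1e-5)
assign_status <- function(tl, lod, loq, cutoff, tol = 1e-9) {
  check_cutoff(cutoff)
  n <- max(length(tl), length(lod), length(loq))
  tl <- rep_len(tl, n); lod <- rep_len(lod, n); loq <- rep_len(loq, n)
  if (any(lod > loq * (1 + tol))) {
    stop("LOD must not exceed LOQ", call. = FALSE)
  }

  above_cut <- .ge(tl, cutoff, tol)
  rule <- ifelse(
    above_cut,
    ifelse(.ge(tl, lod, tol),
           ifelse(.ge(tl, loq, tol), "B1a", "B1b"),
           "B1c"),
    ifelse(.le(lod, cutoff, tol),
           ifelse(.le(loq, cutoff, tol), "B2a", "B2b"),
           "B2c")
  )
  status <- c(B1a = "positive", B1b = "positive", B1c = "nonassessable",
              B2a = "negative", B2b = "negative", B2c = "nonassessable")[rule]
  tibble::tibble(status = unname(status), rule_fired = rule)
}

#' Quantifiability of the tumor load for a positive call
#'
#' Second evaluation step: in an MRD-positive sample the tumor load can be
#' numerically stated only when it reaches the limit of quantification.
#' Positives with TL below the LOQ remain positive but `nonquantifiable`;
#' non-positive calls receive `not_applicable`.
#'
#' @param status Character vector of statuses from [assign_status()].
#' @param tl,loq Numeric vectors of tumor load and limit of quantification.
#' @param tol Relative comparison tolerance. Default 1e-9.
#'
#' @return Character vector: `quantifiable`, `nonquantifiable` or
#'   `not_applicable`.
#' @export
#' @examples
#' assess_tl_quantifiability("positive", tl = 1.5e-4, loq = 2.2e-6)
assess_tl_quantifiability <- function(status, tl, loq, tol = 1e-9) {
  ifelse(status != "positive", "not_applicable",
         ifelse(.ge(tl, loq, tol), "quantifiable", "nonquantifiable"))
}

#' Call MRD status for a measurement table
#'
#' Full per-sample evaluation: compute key metrics ([mrd_key_metrics()]),
#' assign the MRD status at the cut-off ([assign_status()]), and assess
#' tumor-load quantifiability for positives
#' ([assess_tl_quantifiability()]).
#'
#' @param measurements Measurement table (see [read_measurements()]).
#' @param cutoff A single MRD cut-off (fraction), e.g. `1e-5`.
#' @param constants An [assay_constants()] object.
#' @param tol Relative comparison tolerance for the decision rules.
#'
#' @return A tibble: the input plus `tl`, `lod`, `loq`, `cutoff`, `status`,
#'   `rule_fired` and `tl_quantifiable`.
#' @export
#' @examples
#' m <- tibble::tibble(patient_id = "P1", assay = "NGS",
#'                     cells_assayed = 1.1e6, tumor_count = 45)
#' mrd_call(m, cutoff = 1e-5)
mrd_call <- function(measurements, cutoff = 1e-5,
                     constants = assay_constants(), tol = 1e-9) {
  metrics <- mrd_key_metrics(measurements, constants)
  call <- assign_status(metrics$tl, metrics$lod, metrics$loq, cutoff, tol)
  dplyr::mutate(
    metrics,
    cutoff = cutoff,
    status = call$status,
    rule_fired = call$rule_fired,
    tl_quantifiable = assess_tl_quantifiability(call$status, .data$tl,
                                                .data$loq, tol)
  )
}

check_cutoff <- function(cutoff) {
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must be a single fraction in (0, 1]", call. = FALSE)
  }
  invisible(cutoff)
}
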