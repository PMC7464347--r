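#' Assay-specific constants for LOD and LOQ
#'
#' Bundles the constants from which per-sample detection and quantification
#' limits are derived. For the NGS assay the limit of detection is
#' `ngs_lod_factor / cells_assayed` (the frequency at which the probability
#' of falsely claiming absence of disease is 5%) and the limit of
#' quantification is `ngs_loq_factor / cells_assayed`. For MFC the consensus
#' event-count rules apply: LOD = `mfc_lod_events` / events acquired and
#' LOQ = `mfc_loq_events` / events acquired.
#'
#' The factors are exposed rather than hard-coded so that an
#' assay-revalidation (for instance a rearrangement-uniqueness correction
#' supplied by a sequencing vendor) can be applied as a configured
#' multiplier without touching the formulas.
#'
#' @param ngs_lod_factor Dimensionless NGS LOD factor. Default 1.9.
#' @param ngs_loq_factor Dimensionless NGS LOQ factor. Default 2.39.
#' @param mfc_lod_events Event count defining the MFC LOD. Default 30.
#' @param mfc_loq_events Event count defining the MFC LOQ. Default 50.
#'
#' @return A list of class `assay_constants`.
#' @export
#' @examples
#' const <- assay_constants()
#' const$ngs_lod_factor / 1.1e6  # per-sample NGS LOD at 1.1 million cells
assay_constants <- function(ngs_lod_factor = 1.9, ngs_loq_factor = 2.39,
                            mfc_lod_events = 30, mfc_loq_events = 50) {
  vals <- c(ngs_lod_factor, ngs_loq_factor, mfc_lod_events, mfc_loq_events)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("assay constants must all be finite and strictly positive",
         call. = FALSE)
  }
  if (ngs_loq_factor < ngs_lod_factor || mfc_loq_events < mfc_lod_events) {
    stop("LOQ constant must be >= LOD constant for each assay", call. = FALSE)
  }
  structure(
    list(ngs_lod_factor = ngs_lod_factor, ngs_loq_factor = ngs_loq_factor,
         mfc_lod_events = mfc_lod_events, mfc_loq_events = mfc_loq_events),
    class = "assay_constants"
  )
}

#' Consensus MRD cut-offs
#'
#' The study-wide tumor-load thresholds commonly considered when dichotomizing
#' MRD results: 1e-4, 2e-5, 1e-5 and 1e-6. A cut-off is a fraction of tumor
#' cells among assayed cells; a sample whose tumor load reaches the cut-off is
#' a candidate MRD-positive.
#'
#' @return A tibble with columns `value` (fraction) and `label`.
#' @export
#' @examples
#' mrd_cutoffs()
mrd_cutoffs <- function() {
  tibble::tibble(
    value = c(1e-4, 2e-5, 1e-5, 1e-6),
    label = c("1e-4", "2e-5", "1e-5", "1e-6")
  )
}

# tolerance-aware comparisons used wherever a quotient such as 30/3e6 must
# compare cleanly against a literal cut-off; relative tolerance on the larger
# magnitude, ties resolved towards "greater or equal"
.ge <- function(a, b, tol = 1e-9) a >= b - tol * pmax(abs(a), abs(b))
.le <- function(a, b, tol = 1e-9) .ge(b, a, tol)
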