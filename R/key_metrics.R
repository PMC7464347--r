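#' Per-sample limit of detection
#'
#' The LOD is the lowest tumor load at which disease presence can be claimed
#' with controlled false-negative risk. It is sample-specific and inversely
#' proportional to the number of cells (NGS: cell equivalents from DNA input)
#' or nucleated events (MFC) assayed: `1.9 / cells` for NGS and
#' `30 / events` for MFC with the default constants. Values that would exceed
#' 1 (pathologically small samples) are clamped to 1 with a warning.
#'
#' @param assay Character vector, `"NGS"` or `"MFC"` per sample.
#' @param cells_assayed Positive numeric vector: cell equivalents (NGS) or
#'   total nucleated events acquired (MFC).
#' @param constants An [assay_constants()] object.
#'
#' @return Numeric vector of LOD fractions in (0, 1].
#' @export
#' @examples
#' mrd_lod("NGS", 1.1e6)  # 1.7e-6 after rounding to 2 significant figures
#' mrd_lod("MFC", 5.0e6)  # 6.0e-6
mrd_lod <- function(assay, cells_assayed, constants = assay_constants()) {
  assay <- check_assay(assay)
  check_cells(cells_assayed)
  factor <- ifelse(assay == "NGS", constants$ngs_lod_factor,
                   constants$mfc_lod_events)
  clamp_fraction(factor / cells_assayed, "LOD")
}

#' Per-sample limit of quantification
#'
#' The LOQ is the lowest tumor load that can be numerically quantified to the
#' assay's stated accuracy: `2.39 / cells` for NGS and `50 / events` for MFC
#' with the default constants. Always at least as large as the LOD for the
#' same sample.
#'
#' @inheritParams mrd_lod
#' @return Numeric vector of LOQ fractions in (0, 1].
#' @export
#' @examples
#' mrd_loq("NGS", 1.1e6)  # 2.2e-6 after rounding to 2 significant figures
#' mrd_loq("MFC", 5.0e6)  # 1.0e-5
mrd_loq <- function(assay, cells_assayed, constants = assay_constants()) {
  assay <- check_assay(assay)
  check_cells(cells_assayed)
  factor <- ifelse(assay == "NGS", constants$ngs_loq_factor,
                   constants$mfc_loq_events)
  clamp_fraction(factor / cells_assayed, "LOQ")
}

#' Per-sample tumor load
#'
#' The tumor load (TL) is the fraction of tumor cells among assayed cells:
#' clonal sequence count over tested cell equivalents for NGS, aberrant
#' plasma-cell events over total nucleated events for MFC. A zero count is a
#' legitimate TL of 0 (no clone detected), not a missing value. When a source
#' reports the TL directly rather than counts, pass it as
#' `tumor_load_override` and it takes precedence.
#'
#' @param tumor_count Non-negative integer vector of detected tumor cells or
#'   clonal sequences; may be `NA` where an override is supplied.
#' @param cells_assayed Positive numeric vector of assayed cells/events.
#' @param tumor_load_override Optional numeric vector in \[0, 1\]; where
#'   non-`NA` it is returned as the TL.
#'
#' @return Numeric vector of tumor-load fractions in \[0, 1\].
#' @export
#' @examples
#' mrd_tl(45, 1e6)       # 4.5e-5
#' mrd_tl(0, 1e6)        # 0: no clone detected
#' mrd_tl(NA, 1e6, 2e-5) # override wins
mrd_tl <- function(tumor_count, cells_assayed, tumor_load_override = NULL) {
  check_cells(cells_assayed)
  n <- max(length(tumor_count), length(cells_assayed))
  tumor_count <- rep_len(as.numeric(tumor_count), n)
  cells_assayed <- rep_len(as.numeric(cells_assayed), n)
  override <- if (is.null(tumor_load_override)) rep(NA_real_, n) else
    rep_len(as.numeric(tumor_load_override), n)

  if (any(!is.na(override) & (override < 0 | override > 1))) {
    stop("tumor_load_override must lie in [0, 1]", call. = FALSE)
  }
  missing_both <- is.na(override) & is.na(tumor_count)
  if (any(missing_both)) {
    stop("tumor_count and tumor_load_override both absent for ",
         sum(missing_both), " sample(s)", call. = FALSE)
  }
  bad <- !is.na(tumor_count) & (tumor_count < 0 | tumor_count > cells_assayed)
  if (any(bad)) {
    stop("tumor_count must satisfy 0 <= tumor_count <= cells_assayed",
         call. = FALSE)
  }
  ifelse(!is.na(override), override, tumor_count / cells_assayed)
}

#' Compute MRD key metrics for a measurement table
#'
#' Appends the three sample-specific MRD key metrics — tumor load (`tl`),
#' limit of detection (`lod`) and limit of quantification (`loq`), all
#' unitless fractions — to a measurement table. These metrics are the inputs
#' to the MRD status decision ([mrd_call()]).
#'
#' @param measurements A data frame with columns `assay`, `cells_assayed`,
#'   `tumor_count` and optionally `tumor_load` (a direct-TL override); see
#'   [read_measurements()] for the full table contract.
#' @param constants An [assay_constants()] object.
#'
#' @return The input as a tibble with `tl`, `lod` and `loq` columns added.
#' @export
#' @examples
#' m <- tibble::tibble(patient_id = "P1", assay = "NGS",
#'                     cells_assayed = 1.1e6, tumor_count = 45)
#' mrd_key_metrics(m)
mrd_key_metrics <- function(measurements, constants = assay_constants()) {
  measurements <- tibble::as_tibble(measurements)
  need <- c("assay", "cells_assayed", "tumor_count")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  override <- if ("tumor_load" %in% names(measurements))
    measurements$tumor_load else NULL
  dplyr::mutate(
    measurements,
    tl  = mrd_tl(.data$tumor_count, .data$cells_assayed, override),
    lod = mrd_lod(.data$assay, .data$cells_assayed, constants),
    loq = mrd_loq(.data$assay, .data$cells_assayed, constants)
  )
}

# ---- internal validators ---------------------------------------------------

check_assay <- function(assay) {
  assay <- toupper(as.character(assay))
  bad <- !assay %in% .mrd_assays
  if (any(bad)) {
    stop("unknown assay token(s): ",
         paste(unique(assay[bad]), collapse = ", "),
         " (expected NGS or MFC)", call. = FALSE)
  }
  assay
}

check_cells <- function(cells_assayed) {
  if (any(!is.finite(cells_assayed) | cells_assayed < 1)) {
    stop("cells_assayed must be >= 1 for every sample", call. = FALSE)
  }
  invisible(cells_assayed)
}

clamp_fraction <- function(x, what) {
  if (any(x > 1)) {
    warning(sum(x > 1), " ", what,
            " value(s) exceeded 1 and were clamped (very small sample)",
            call. = FALSE)
    x <- pmin(x, 1)
  }
  x
}
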