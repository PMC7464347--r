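# Fixture builders and independent oracles shared across the suite.
# All fixtures are constructed in code from the published cohort structure
# (125 paired NGS/MFC bone-marrow samples); no data files are read.

meas <- function(patient_id, assay, cells, count, response = "NA",
                 timepoint = "NA") {
  tibble::tibble(patient_id = patient_id, assay = assay,
                 cells_assayed = cells, tumor_count = count,
                 response = response, timepoint = timepoint)
}

# paired rows for one patient; status controlled through the tumor counts
pair_rows <- function(ids, ngs_cells, ngs_count, mfc_cells, mfc_count,
                      response = "NA") {
  dplyr::bind_rows(
    meas(ids, "NGS", ngs_cells, ngs_count, response),
    meas(ids, "MFC", mfc_cells, mfc_count, response)
  )
}

# 125-patient paired cohort matching the published concordance partition at
# cut-off 1e-5: 42 concordant positive, 43 concordant negative, 14 discordant
# in each direction, 2 NGS-nonassessable and 10 MFC-nonassessable pairs.
# Cell counts are taken from the printed medians/ranges: positives carry a
# tumor load of 1e-4; nonassessable samples sit at the small end of the
# printed cell-count range so their LOD undercuts the cut-off.
concordance_fixture <- function() {
  id <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))
  dplyr::bind_rows(
    pair_rows(id("cp", 42), 1.1e6, 110, 5.0e6, 500),  # both positive
    pair_rows(id("cn", 43), 1.1e6, 0,   5.0e6, 0),    # both negative
    pair_rows(id("dn", 14), 1.1e6, 110, 5.0e6, 0),    # NGS+ / MFC-
    pair_rows(id("dm", 14), 1.1e6, 0,   5.0e6, 500),  # NGS- / MFC+
    pair_rows(id("xn", 2),  1.8e5, 0,   5.0e6, 0),    # NGS LOD > cut-off
    pair_rows(id("xm", 10), 1.1e6, 0,   2.0e6, 0)     # MFC LOD > cut-off
  )
}

# 125-patient cohort matching the published response-stratified negativity
# counts at cut-off 1e-5: NGS-negative 37/54 CR, 19/31 nCR, 4/24 VGPR;
# MFC-negative 37 CR, 12 nCR, 5 VGPR; no negatives at PR/MR/baseline/NA.
stratified_fixture <- function() {
  build <- function(prefix, response, n, ngs_neg, mfc_neg, both_neg) {
    ngs_only <- ngs_neg - both_neg
    mfc_only <- mfc_neg - both_neg
    pattern <- c(rep("nn", both_neg), rep("np", ngs_only),
                 rep("pn", mfc_only),
                 rep("pp", n - both_neg - ngs_only - mfc_only))
    ids <- sprintf("%s%02d", prefix, seq_len(n))
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      ngs_count <- if (substr(pattern[i], 1, 1) == "n") 0 else 110
      mfc_count <- if (substr(pattern[i], 2, 2) == "n") 0 else 500
      pair_rows(ids[i], 1.1e6, ngs_count, 5.0e6, mfc_count, response)
    }))
  }
  dplyr::bind_rows(
    build("cr", "CR", 54, 37, 37, both_neg = 37),
    build("nc", "nCR", 31, 19, 12, both_neg = 12),
    build("vg", "VGPR", 24, 4, 5, both_neg = 4),
    build("pr", "PR", 7, 0, 0, 0),
    build("mr", "MR", 1, 0, 0, 0),
    build("bl", "baseline", 1, 0, 0, 0),
    build("na", "NA", 7, 0, 0, 0)
  )
}

# 125 NGS samples of which 44 have an LOD above 1e-6 (too few cell
# equivalents) and no detectable clone, so they become nonassessable once the
# cut-off drops to 1e-6.
sweep_fixture <- function() {
  dplyr::bind_rows(
    meas(sprintf("lo%02d", 1:44), "NGS", 1.0e6, 0),  # LOD 1.9e-6 > 1e-6
    meas(sprintf("hi%02d", 1:81), "NGS", 2.0e6, 0)   # LOD 9.5e-7 <= 1e-6
  )
}

# Independent scalar re-statement of the six-rule decision diagram, written
# directly from its verbal description with plain comparisons.
oracle_rule <- function(tl, lod, loq, cutoff) {
  if (tl >= cutoff) {
    if (tl >= lod) {
      if (tl >= loq) "B1a" else "B1b"
    } else "B1c"
  } else {
    if (lod <= cutoff) {
      if (loq <= cutoff) "B2a" else "B2b"
    } else "B2c"
  }
}

oracle_status <- function(rule) {
  switch(rule, B1a = , B1b = "positive", B2a = , B2b = "negative",
         "nonassessable")
}

# Definition-level kappa: expand the 2x2 table into two rater label vectors
# and apply observed/expected agreement directly.
kappa_bruteforce <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- c(rep("pos", a + b), rep("neg", c + d))
  r2 <- c(rep("pos", a), rep("neg", b), rep("pos", c), rep("neg", d))
  po <- mean(r1 == r2)
  pe <- sum(vapply(c("pos", "neg"),
                   function(k) mean(r1 == k) * mean(r2 == k), numeric(1)))
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# random metric/cut-off combinations with LOD <= LOQ, spanning the scales
# seen in practice (limits 1e-7..1e-3, loads 0..1e-2, consensus cut-offs)
random_metric_grid <- function(n, seed) {
  set.seed(seed)
  lod <- 10^runif(n, -7, -3)
  loq <- lod * runif(n, 1, 3)
  tl <- ifelse(runif(n) < 0.3, 0, 10^runif(n, -7, -2))
  cutoff <- sample(c(1e-4, 2e-5, 1e-5, 1e-6), n, replace = TRUE)
  tibble::tibble(tl = tl, lod = lod, loq = loq, cutoff = cutoff)
}
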