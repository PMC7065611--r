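#' Classify an ATP reading against the hygiene guideline
#'
#' ATP bioluminescence estimates total organic soil. A surface is called
#' dirty at or above 1 RLU per cm2 (derived from the common 100 RLU/surface
#' limit); the boundary is inclusive.
#'
#' @param atp Numeric vector of ATP readings, RLU/cm2, >= 0.
#' @return Character vector, `"dirty"` or `"clean"`.
#' @export
classify_atp <- function(atp) {
  if (any(is.na(atp)) || any(atp < 0)) {
    stop("input error: ATP must be non-negative and non-missing",
         call. = FALSE)
  }
  ifelse(atp >= 1.0, "dirty", "clean")
}

#' Classify a total plate count against the hygiene benchmark
#'
#' The common hospital surface-hygiene benchmark is 2.5 CFU/cm2; surfaces at
#' or above 40 CFU/cm2 fall in the heavy-growth (very dirty) category. Both
#' boundaries are inclusive, and values above 100 CFU/cm2 remain
#' heavy growth (no more-severe category is defined). The ordering
#' pass < exceeds_benchmark < heavy_growth is monotone in CFU.
#'
#' @param tpc Numeric vector of total plate counts, CFU/cm2, >= 0.
#' @return Ordered factor with levels `pass`, `exceeds_benchmark`,
#'   `heavy_growth`.
#' @export
classify_tpc <- function(tpc) {
  if (any(is.na(tpc)) || any(tpc < 0)) {
    stop("input error: TPC must be non-negative and non-missing",
         call. = FALSE)
  }
  factor(ifelse(tpc >= 40, "heavy_growth",
                ifelse(tpc >= 2.5, "exceeds_benchmark", "pass")),
         levels = c("pass", "exceeds_benchmark", "heavy_growth"),
         ordered = TRUE)
}

#' Read per-sample hygiene measurements from CSV
#'
#' Expected header: `location, surface_area_cm2, atp_rlu_cm2,
#' atp_rlu_surface, tpc_cfu_cm2, s_aureus, enterococci, gram_negatives`.
#' Indicator flags are 0/1; blanks mean not measured. Each sample must carry
#' at least one of ATP or TPC; when both per-cm2 and per-surface ATP are
#' present they must agree with the surface area within 10% relative
#' tolerance.
#'
#' @param path CSV path.
#' @return Validated data frame of samples.
#' @export
read_hygiene_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("location", "surface_area_cm2", "atp_rlu_cm2",
              "atp_rlu_surface", "tpc_cfu_cm2", "s_aureus", "enterococci",
              "gram_negatives")
  if (!all(needed %in% names(df))) {
    stop("samples CSV missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$atp_rlu_cm2) & is.na(df$tpc_cfu_cm2))) {
    stop("input error: every sample needs at least one of ATP or TPC",
         call. = FALSE)
  }
  num <- c("surface_area_cm2", "atp_rlu_cm2", "atp_rlu_surface",
           "tpc_cfu_cm2")
  if (any(vapply(df[num], function(v) any(v < 0, na.rm = TRUE),
                 logical(1)))) {
    stop("input error: measurements must be non-negative", call. = FALSE)
  }
  both <- !is.na(df$atp_rlu_cm2) & !is.na(df$atp_rlu_surface) &
    !is.na(df$surface_area_cm2)
  implied <- df$atp_rlu_surface[both] / df$surface_area_cm2[both]
  bad <- abs(implied - df$atp_rlu_cm2[both]) > 0.1 * pmax(implied, 1e-12)
  if (any(bad)) {
    warning(sum(bad), " sample(s) with inconsistent per-cm2 vs per-surface ATP (>10% off)",
            call. = FALSE)
  }
  df
}

#' Per-sample hygiene verdicts
#'
#' @param samples Data frame from [read_hygiene_samples()].
#' @return The samples with `atp_status` (`clean`/`dirty`/`n/a`) and
#'   `tpc_status` (`pass`/`exceeds_benchmark`/`heavy_growth`/`n/a`) columns.
#' @export
hygiene_verdicts <- function(samples) {
  samples$atp_status <- "n/a"
  ok <- !is.na(samples$atp_rlu_cm2)
  samples$atp_status[ok] <- classify_atp(samples$atp_rlu_cm2[ok])
  samples$tpc_status <- "n/a"
  ok <- !is.na(samples$tpc_cfu_cm2)
  samples$tpc_status[ok] <- as.character(classify_tpc(samples$tpc_cfu_cm2[ok]))
  samples
}

sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)

#' Summarize hygiene samples per location plus a pooled total row
#'
#' Mean/SD/min/max/N per assay and percent positive per indicator, per
#' sampling location, with an overall row pooling all samples (sample-pooled,
#' not location-averaged). A location with a single measurement gets SD 0
#' with `sd_degenerate = TRUE`.
#'
#' @param samples Data frame from [read_hygiene_samples()].
#' @return Data frame, one row per location plus a `Total` row.
#' @export
summarize_hygiene <- function(samples) {
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  one <- function(df, loc) {
    atp <- df$atp_rlu_cm2[!is.na(df$atp_rlu_cm2)]
    tpc <- df$tpc_cfu_cm2[!is.na(df$tpc_cfu_cm2)]
    pct <- function(flag) {
      v <- flag[!is.na(flag)]
      if (length(v) == 0) NA_real_ else 100 * sum(v) / length(v)
    }
    data.frame(
      location = loc,
      n_atp = length(atp),
      atp_mean = if (length(atp)) mean(atp) else NA_real_,
      atp_sd = if (length(atp)) sd0(atp) else NA_real_,
      atp_min = if (length(atp)) min(atp) else NA_real_,
      atp_max = if (length(atp)) max(atp) else NA_real_,
      n_tpc = length(tpc),
      tpc_mean = if (length(tpc)) mean(tpc) else NA_real_,
      tpc_sd = if (length(tpc)) sd0(tpc) else NA_real_,
      tpc_min = if (length(tpc)) min(tpc) else NA_real_,
      tpc_max = if (length(tpc)) max(tpc) else NA_real_,
      s_aureus_pct = pct(df$s_aureus),
      enterococci_pct = pct(df$enterococci),
      gram_negatives_pct = pct(df$gram_negatives),
      sd_degenerate = length(atp) == 1 || length(tpc) == 1
    )
  }
  per_loc <- do.call(rbind, lapply(split(samples, samples$location),
                                   function(df) one(df, df$location[1])))
  out <- rbind(per_loc, one(samples, "Total"))
  rownames(out) <- NULL
  out
}

#' Pool per-location positive rates into an overall percentage
#'
#' Reconstructs integer positive counts from each location's printed percent
#' and sample count (`count = round(percent x n / 100)`), then pools:
#' `100 x sum(counts) / sum(n)`. Emits a data-quality warning when a
#' reconstructed count sits further than 0.5 from an integer.
#'
#' @param percent Numeric vector of per-location percentages in \[0, 100\].
#' @param n Positive integer vector of per-location sample counts.
#' @return Overall percentage.
#' @examples
#' overall_positive_rate(c(7.1, 8.3, 2.9, 33.3, 20, 35.7),
#'                       c(14, 24, 34, 6, 10, 14))  # 11.6
#' @export
overall_positive_rate <- function(percent, n) {
  if (any(n <= 0)) stop("all n must be positive", call. = FALSE)
  if (any(percent < 0 | percent > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  raw <- percent * n / 100
  if (any(abs(raw - round(raw)) > 0.5)) {
    warning("data-quality: reconstructed counts not near integers",
            call. = FALSE)
  }
  100 * sum(round(raw)) / sum(n)
}

#' Read a per-location hygiene survey summary table
#'
#' TSV with one row per sampling location carrying the published summary
#' statistics: `location, surface_area_cm2, atp_mean, atp_sd, atp_min,
#' atp_max, n_atp, tpc_mean, tpc_sd, tpc_min, tpc_max, n_tpc,
#' s_aureus_pct, enterococci_pct, gram_negatives_pct`. Blank cells mean the
#' assay was not run at that location. The packaged example
#' (`hospital_survey_locations.tsv`) holds the six touch-surface locations of
#' a real-life hospital survey.
#'
#' @param path TSV path; default the packaged survey table.
#' @return Data frame of location rows.
#' @export
read_location_summary <- function(path = system.file(
  "extdata", "hospital_survey_locations.tsv", package = "surfstain")) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Roll a per-location survey summary up into its totals
#'
#' Recomputes the survey's roll-ups from the per-location rows: total sample
#' counts per assay, the grand total across both assays, and overall
#' indicator-positive rates whose positive counts are reconstructed from each
#' location's percent and N. When the table carries its own printed `Total`
#' row (as the packaged hospital survey does), that row's sample counts are
#' taken as the denominators the survey itself used, and a data-quality
#' warning is raised if the per-location counts do not sum to them — the
#' packaged survey's per-location N(TPC) sum to 102 against a printed total
#' of 112, an inconsistency in the source that the warning surfaces rather
#' than hides.
#'
#' @param summary Data frame from [read_location_summary()]; an optional row
#'   with `location == "Total"` is treated as the printed total row, not a
#'   location.
#' @return List with `n_atp_total`, `n_tpc_total`, `n_samples_total`
#'   (printed totals when available, else per-location sums),
#'   `n_atp_location_sum`, `n_tpc_location_sum`, and
#'   `<indicator>_overall_pct` for the three indicator bacteria.
#' @export
survey_totals <- function(summary) {
  printed <- summary[summary$location == "Total", , drop = FALSE]
  locs <- summary[summary$location != "Total", , drop = FALSE]
  sum_atp <- sum(locs$n_atp, na.rm = TRUE)
  sum_tpc <- sum(locs$n_tpc, na.rm = TRUE)
  n_atp <- sum_atp
  n_tpc <- sum_tpc
  if (nrow(printed) == 1) {
    if (!is.na(printed$n_atp)) n_atp <- printed$n_atp
    if (!is.na(printed$n_tpc)) n_tpc <- printed$n_tpc
    if (n_atp != sum_atp || n_tpc != sum_tpc) {
      warning(sprintf(
        "data-quality: per-location sample counts (ATP %d, TPC %d) do not match the printed totals (ATP %d, TPC %d)",
        sum_atp, sum_tpc, n_atp, n_tpc), call. = FALSE)
    }
  }
  rate <- function(col) {
    ok <- !is.na(locs[[col]]) & !is.na(locs$n_tpc) & locs$n_tpc > 0
    positives <- sum(round(locs[[col]][ok] * locs$n_tpc[ok] / 100))
    100 * positives / n_tpc
  }
  list(
    n_atp_total = as.integer(n_atp),
    n_tpc_total = as.integer(n_tpc),
    n_samples_total = as.integer(n_atp + n_tpc),
    n_atp_location_sum = as.integer(sum_atp),
    n_tpc_location_sum = as.integer(sum_tpc),
    s_aureus_overall_pct = rate("s_aureus_pct"),
    enterococci_overall_pct = rate("enterococci_pct"),
    gram_negatives_overall_pct = rate("gram_negatives_pct")
  )
}
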