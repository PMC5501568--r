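#' Microbial biomass from chloroform fumigation
#'
#' Biomass C or N is the fumigated-minus-nonfumigated extractable pool
#' divided by an extraction-efficiency calibration factor: 0.45 for
#' biomass C (MBC) and 0.54 for biomass N (MBN).  Negative differences
#' (extraction noise) are physically impossible for a biomass pool and
#' are floored at zero with a warning; callers who need the raw
#' difference can inspect the `flagged` attribute.
#'
#' @param fumigated,nonfumigated extractable C or N, ug per g dry soil.
#' @param calibration extraction efficiency in (0, 1]; use 0.45 for MBC,
#'   0.54 for MBN.
#' @return Biomass in ug per g dry soil (vectorized); attribute
#'   `flagged` marks records whose raw difference was negative.
#' @export
microbial_biomass <- function(fumigated, nonfumigated, calibration) {
  if (!is.numeric(calibration) || length(calibration) != 1L ||
      calibration <= 0 || calibration > 1)
    stop("calibration must be a single value in (0, 1]", call. = FALSE)
  diff <- fumigated - nonfumigated
  neg <- is.finite(diff) & diff < 0
  if (any(neg))
    warning(sum(neg), " negative fumigation difference(s) floored at 0")
  diff[neg] <- 0
  structure(diff / calibration, flagged = neg)
}

#' Carbon mineralization rate from a CO2 incubation series
#'
#' Headspace CO2 is measured on a few days (typically 1, 3, 7, 10) with
#' the flask vented after each measurement, so each reading is the
#' production since the previous venting.  The rate is the ordinary
#' least-squares slope of cumulative CO2 (the running sum of
#' post-venting increments) against day: concentration per day.
#'
#' @param day sampling days, strictly increasing, at least two.
#' @param co2 CO2 concentration measured at each sampling (one
#'   post-venting increment per day).
#' @return The OLS slope (concentration per day).
#' @export
c_mineralization_rate <- function(day, co2) {
  if (length(day) < 2L || length(co2) != length(day))
    stop("need at least two (day, co2) measurements", call. = FALSE)
  if (any(diff(day) <= 0))
    stop("days must be strictly increasing", call. = FALSE)
  cumulative <- cumsum(co2)
  unname(coef(lm(cumulative ~ day))[2L])
}

#' Net nitrogen mineralization over an incubation
#'
#' The change in extractable inorganic N over the 28-day incubation;
#' negative values (net immobilization) are passed through.
#'
#' @param initial,final extractable inorganic N, ug N per g dry soil, at
#'   day 0 and day 28.
#' @return ug N per g dry soil per 28 days (vectorized).
#' @export
n_mineralization <- function(initial, final) {
  final - initial
}

#' Mass-specific microbial rate
#'
#' A mineralization rate per unit of microbial biomass C; undefined for
#' non-positive MBC (returned as `NA` with a `flagged` attribute so
#' those records drop out of specific-rate statistics).
#'
#' @param rate a mineralization rate.
#' @param mbc microbial biomass C, ug C per g dry soil.
#' @return `rate / mbc` (vectorized).
#' @export
specific_rate <- function(rate, mbc) {
  bad <- !is.finite(mbc) | mbc <= 0
  out <- rate / mbc
  out[bad] <- NA_real_
  structure(out, flagged = bad)
}

#' Derive the indicator set from raw assay records
#'
#' Applies [microbial_biomass()], [c_mineralization_rate()],
#' [n_mineralization()] and [specific_rate()] to a data frame of raw
#' assay values (one row per sample) and returns the per-sample
#' indicator table.  Extractable organic C (EOC) is taken as the
#' non-fumigated extract's dissolved organic C.
#'
#' @param assay data frame with columns `sample_id`, `fumigated_doc`,
#'   `nonfumigated_doc`, `fumigated_tn`, `nonfumigated_tn`,
#'   `inorganic_n_initial`, `inorganic_n_final`, and CO2 columns
#'   `co2_day<d>` for each sampling day `d`.
#' @param mbc_calibration,mbn_calibration calibration factors (defaults
#'   0.45 and 0.54).
#' @return data frame with `sample_id`, `eoc`, `mbc`, `mbn`,
#'   `c_min_rate`, `n_min`, `specific_c_min`, `specific_n_min`.
#' @export
derive_indicators <- function(assay, mbc_calibration = 0.45,
                              mbn_calibration = 0.54) {
  need <- c("sample_id", "fumigated_doc", "nonfumigated_doc",
            "fumigated_tn", "nonfumigated_tn",
            "inorganic_n_initial", "inorganic_n_final")
  miss <- setdiff(need, names(assay))
  if (length(miss))
    stop("assay table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  co2_cols <- grep("^co2_day", names(assay), value = TRUE)
  if (length(co2_cols) < 2L)
    stop("assay table needs at least two co2_day<d> columns", call. = FALSE)
  days <- as.numeric(sub("^co2_day", "", co2_cols))
  ord <- order(days); days <- days[ord]; co2_cols <- co2_cols[ord]

  mbc <- suppressWarnings(
    microbial_biomass(assay$fumigated_doc, assay$nonfumigated_doc,
                      mbc_calibration))
  mbn <- suppressWarnings(
    microbial_biomass(assay$fumigated_tn, assay$nonfumigated_tn,
                      mbn_calibration))
  c_rate <- vapply(seq_len(nrow(assay)), function(i)
    c_mineralization_rate(days, as.numeric(assay[i, co2_cols])),
    numeric(1))
  n_min <- n_mineralization(assay$inorganic_n_initial,
                            assay$inorganic_n_final)
  data.frame(
    sample_id = assay$sample_id,
    eoc = assay$nonfumigated_doc,
    mbc = as.numeric(mbc), mbn = as.numeric(mbn),
    c_min_rate = c_rate, n_min = n_min,
    specific_c_min = as.numeric(specific_rate(c_rate, mbc)),
    specific_n_min = as.numeric(specific_rate(n_min / 28, mbc)))
}
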