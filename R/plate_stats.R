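#' Z'-factor of a screening plate
#'
#' `Z' = 1 - 3 * (SD_sample + SD_negative) / |mean_sample - mean_negative|`.
#' The absolute value in the denominator makes the statistic independent of
#' which group is listed first. Z' between 0.5 and 1.0 indicates an
#' excellent assay; 0 to 0.5 a suboptimal one; below 0 an unsuccessful one.
#'
#' @param sample_values Numeric vector (>= 2 values) of the sample
#'   (stimulator-control) group.
#' @param negative_values Numeric vector (>= 2 values) of the negative
#'   (neutral-control) group.
#' @return Z' (<= 1), with the qualitative band as attribute `"band"`.
#' @export
#' @examples
#' z_prime(c(95, 100, 105), c(-5, 0, 5))  # 0.7
z_prime <- function(sample_values, negative_values) {
  stopifnot(length(sample_values) >= 2, length(negative_values) >= 2)
  sep <- mean(sample_values) - mean(negative_values)
  if (sep == 0)
    stop("control groups have equal means: Z' undefined (division by zero)",
         call. = FALSE)
  z <- 1 - 3 * (stats::sd(sample_values) + stats::sd(negative_values)) /
    abs(sep)
  band <- if (z >= 0.5) "excellent" else if (z >= 0) "suboptimal"
  else "unsuccessful"
  structure(z, band = band)
}

#' Robust Z'-factor (median / scaled MAD)
#'
#' Same separation statistic as [z_prime()] with medians in place of means
#' and `1.4826 * MAD` in place of SDs, so single outlier wells perturb it
#' far less.
#'
#' @inheritParams z_prime
#' @return Robust Z' (<= 1).
#' @export
robust_z_prime <- function(sample_values, negative_values) {
  stopifnot(length(sample_values) >= 2, length(negative_values) >= 2)
  sep <- stats::median(sample_values) - stats::median(negative_values)
  if (sep == 0)
    stop("control groups have equal medians: robust Z' undefined",
         call. = FALSE)
  1 - 3 * (stats::mad(sample_values) + stats::mad(negative_values)) /
    abs(sep)
}

#' Percent inhibition of a well value
#'
#' `100 * (value - AVEneg) / (AVEpos - AVEneg)`, where the positive
#' control is the neutral (fully inhibited, no lipid induction) mean and
#' the negative control is the stimulator (maximal lipid) mean. 0 at the
#' stimulator mean, 100 at the neutral mean.
#'
#' @param value Well value(s) (vectorized).
#' @param ave_pos Mean of the positive (neutral) control wells.
#' @param ave_neg Mean of the negative (stimulator) control wells.
#' @return Percent inhibition.
#' @export
#' @examples
#' percent_inhibition(c(10, 5, 0), ave_pos = 0, ave_neg = 10)  # 0 50 100
percent_inhibition <- function(value, ave_pos, ave_neg) {
  if (ave_pos == ave_neg)
    stop("control means are equal: percent inhibition undefined",
         call. = FALSE)
  100 * (value - ave_neg) / (ave_pos - ave_neg)
}

# Extract the control-well values of one readout, with checks.
control_values <- function(wells, layout, readout) {
  stim <- wells[[readout]][match(layout$well[layout$role == "stimulator"],
                                 wells$well)]
  neut <- wells[[readout]][match(layout$well[layout$role == "neutral"],
                                 wells$well)]
  stim <- stim[!is.na(stim)]
  neut <- neut[!is.na(neut)]
  if (length(stim) < 2)
    stop("missing or underpopulated stimulator control column", call. = FALSE)
  if (length(neut) < 2)
    stop("missing or underpopulated neutral control column", call. = FALSE)
  list(stim = stim, neut = neut)
}

#' Plate quality control from control wells
#'
#' Computes Z', robust Z', signal-to-background and the per-group percent
#' CV of the primary readout (well mean integrated spot signal), using
#' control wells only.
#'
#' @param wells Well-summary data frame with at least `well` and
#'   `mean_iss` columns (e.g. from [generate_plate()] or
#'   [quantify_plate_images()]).
#' @param layout Layout data frame with `well` and `role` columns (e.g.
#'   `plate_spec()$layout`).
#' @param readout Column name of the readout (default `"mean_iss"`).
#' @return One-row data frame of class `"plate_qc"`: `z_prime`,
#'   `robust_z_prime`, `s_b`, `cv_stim`, `cv_neutral`, `n_stim`,
#'   `n_neutral`.
#' @export
qc_plate <- function(wells, layout, readout = "mean_iss") {
  cv <- control_values(wells, layout, readout)
  pct_cv <- function(x) 100 * stats::sd(x) / mean(x)
  structure(data.frame(
    z_prime = as.numeric(z_prime(cv$stim, cv$neut)),
    robust_z_prime = robust_z_prime(cv$stim, cv$neut),
    s_b = mean(cv$stim) / mean(cv$neut),
    cv_stim = pct_cv(cv$stim), cv_neutral = pct_cv(cv$neut),
    n_stim = length(cv$stim), n_neutral = length(cv$neut)),
    class = c("plate_qc", "data.frame"))
}

#' Hit-calling thresholds
#'
#' Defaults follow the screen's printed criteria: a hit reduces the
#' integrated spot signal by at least 50 percent (and, when
#' `require_spot_inh` is on, the spot count too) while retaining more than
#' 60 percent of the control-well average cell count; wells at or below 40
#' percent cell count are cytotoxic, and cytotoxicity takes precedence.
#' `require_spot_inh` is provided because the primary-screen text uses the
#' ISS criterion alone while the screen-summary figure also requires the
#' spot-count reduction; both readings are supported.
#'
#' @param hit_iss_inh Minimum ISS percent inhibition for a hit (50).
#' @param hit_spot_inh Minimum spot-count percent inhibition (50).
#' @param require_spot_inh Also require the spot-count criterion (default
#'   TRUE, matching the screen-summary figure).
#' @param min_cell_pct Minimum relative valid cell count (% of control
#'   average) for a hit, exclusive (60).
#' @param tox_cell_pct Relative cell count at or below which a well is
#'   cytotoxic (40).
#' @return List of class `"hit_thresholds"`.
#' @export
hit_thresholds <- function(hit_iss_inh = 50, hit_spot_inh = 50,
                           require_spot_inh = TRUE, min_cell_pct = 60,
                           tox_cell_pct = 40) {
  stopifnot(tox_cell_pct <= min_cell_pct)
  structure(list(hit_iss_inh = hit_iss_inh, hit_spot_inh = hit_spot_inh,
                 require_spot_inh = isTRUE(require_spot_inh),
                 min_cell_pct = min_cell_pct, tox_cell_pct = tox_cell_pct),
            class = "hit_thresholds")
}

#' Normalize wells and call hits and cytotoxic wells
#'
#' Every compound well receives exactly one call: `"cytotoxic"` if its
#' relative valid cell count is at or below the toxicity threshold (this
#' takes precedence), `"hit"` if it clears the inhibition and cell-count
#' criteria, otherwise `"no-effect"`. Control wells are labeled
#' `"control"`. Relative cell count is expressed against the average cell
#' count of all control wells.
#'
#' @param wells Well-summary data frame (`well`, `mean_iss`, `mean_spots`,
#'   `n_cells`).
#' @param layout Layout data frame (`well`, `role`).
#' @param thresholds A [hit_thresholds()] object.
#' @return Data frame of well calls: `well`, `iss_inh`, `spot_inh`,
#'   `cell_pct`, `call`.
#' @export
call_wells <- function(wells, layout, thresholds = hit_thresholds()) {
  th <- thresholds
  stopifnot(inherits(th, "hit_thresholds"))
  iss <- control_values(wells, layout, "mean_iss")
  spot <- control_values(wells, layout, "mean_spots")
  ctrl_wells <- layout$well[layout$role %in% c("stimulator", "neutral")]
  ctrl_cells <- wells$n_cells[wells$well %in% ctrl_wells]
  out <- data.frame(
    well = wells$well,
    iss_inh = percent_inhibition(wells$mean_iss, mean(iss$neut),
                                 mean(iss$stim)),
    spot_inh = percent_inhibition(wells$mean_spots, mean(spot$neut),
                                  mean(spot$stim)),
    cell_pct = 100 * wells$n_cells / mean(ctrl_cells))
  role <- layout$role[match(wells$well, layout$well)]
  is_hit <- out$iss_inh >= th$hit_iss_inh &
    (!th$require_spot_inh | out$spot_inh >= th$hit_spot_inh) &
    out$cell_pct > th$min_cell_pct
  call <- ifelse(out$cell_pct <= th$tox_cell_pct, "cytotoxic",
                 ifelse(is_hit, "hit", "no-effect"))
  call[role != "compound"] <- "control"
  out$call <- call
  out
}
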