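#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x/ic50)^hill)`
#' to all replicate points jointly (unweighted by default), by
#' Levenberg-Marquardt in log10(IC50) space with a deterministic
#' initialization: asymptotes from the response extremes, IC50 from the
#' concentration bracketing the half response, Hill slope +/-1 by trend
#' sign. IC50 is bounded within `[min(conc)/100, max(conc)*100]`.
#'
#' Parameters are canonicalized so that `bottom <= top` and an inhibition
#' curve reports a positive Hill slope (`hill_raw` keeps the fitted sign).
#' A fit whose IC50 lands above the highest tested concentration is
#' reported as right-censored (`ic50_censored`, with `ic50` the fitted
#' value and `ic50_bound` the top tested concentration), matching the
#' "> max tested" reporting convention. Degenerate data (e.g. constant
#' responses) yield a flagged non-converged fit, not an error.
#'
#' @param concentrations Molar concentrations (>= 4 distinct values).
#' @param responses Responses, same length.
#' @param weights Optional per-point weights.
#' @return One-row data frame of class `"dose_response_fit"`: `top`,
#'   `bottom`, `ic50`, `hill`, `hill_raw`, `pic50`, `rss`, `converged`,
#'   `ic50_censored`, `ic50_bound`, `conc_min`, `conc_max`.
#' @export
#' @examples
#' d <- generate_dose_series(dose_series_spec(ic50 = 1e-6, cv = 0, seed = 1))
#' fit_4pl(d$concentration, d$response)$ic50
fit_4pl <- function(concentrations, responses, weights = NULL) {
  if (length(unique(concentrations)) < 4)
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  stopifnot(length(concentrations) == length(responses),
            all(is.finite(concentrations)), all(concentrations > 0),
            all(is.finite(responses)))
  x <- concentrations
  y <- responses
  w <- weights %||% rep(1, length(y))

  out <- data.frame(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                    hill = NA_real_, hill_raw = NA_real_, pic50 = NA_real_,
                    rss = NA_real_, converged = FALSE,
                    ic50_censored = FALSE, ic50_bound = max(x),
                    conc_min = min(x), conc_max = max(x))
  class(out) <- c("dose_response_fit", "data.frame")
  if (stats::sd(y) == 0) return(out)  # flat data: flagged, IC50 undefined

  # deterministic initialization
  my <- tapply(y, x, mean)
  xs <- sort(unique(x))
  top0 <- max(my); bot0 <- min(my)
  half <- (top0 + bot0) / 2
  decreasing <- my[[length(xs)]] < my[[1]]
  hill0 <- if (decreasing) 1 else -1
  cross <- which(diff(sign(my - half)) != 0)
  lic0 <- if (length(cross)) {
    mean(log10(xs[cross[1] + 0:1]))
  } else log10(stats::median(xs))
  lo <- c(-Inf, -Inf, log10(min(x)) - 2, -10)
  hi <- c(Inf, Inf, log10(max(x)) + 2, 10)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(x) - lic50))),
      start = list(top = top0, bottom = bot0, lic50 = lic0, hill = hill0),
      lower = lo, upper = hi, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)

  cf <- stats::coef(fit)
  top <- cf[["top"]]; bottom <- cf[["bottom"]]
  ic50 <- 10^cf[["lic50"]]; hill <- cf[["hill"]]
  # canonical orientation: bottom <= top, inhibition slope positive
  if (bottom > top) {
    tmp <- top; top <- bottom; bottom <- tmp
    hill_canon <- -hill
  } else hill_canon <- hill
  out$top <- top; out$bottom <- bottom
  out$ic50 <- ic50; out$hill <- hill_canon; out$hill_raw <- hill
  out$pic50 <- pic50(ic50)
  out$rss <- sum(w * stats::residuals(fit)^2)
  out$converged <- TRUE
  out$ic50_censored <- ic50 > max(x)
  out
}

#' pIC50 from a molar IC50
#'
#' `-log10(IC50 in molar)`; an IC50 of 0.63 uM gives 6.2 at one decimal.
#'
#' @param ic50_molar IC50 in molar (> 0; vectorized).
#' @param digits Optional rounding.
#' @return pIC50.
#' @export
#' @examples
#' pic50(0.63e-6, digits = 1)  # 6.2
pic50 <- function(ic50_molar, digits = NULL) {
  if (any(!is.finite(ic50_molar) | ic50_molar <= 0))
    stop("ic50 must be positive and finite", call. = FALSE)
  p <- -log10(ic50_molar)
  if (is.null(digits)) p else round(p, digits)
}

#' Classify a compound by potency and selectivity
#'
#' A compound is active when its activity IC50 is at or below the
#' activity threshold (10 uM by default; a stricter 5 uM mode matches the
#' confirmation-screen criterion). Selectivity is the ratio of viability
#' to activity IC50; at least `selectivity` (5-fold by default) flags the
#' compound selective. A right-censored viability fit ("> max tested")
#' uses its censoring bound as a conservative lower bound of the ratio,
#' and a missing viability fit (no cytotoxicity observed in range) is
#' treated the same way.
#'
#' @param activity_fit,viability_fit `"dose_response_fit"` rows; the
#'   viability fit may be `NULL`.
#' @param active_ic50 Activity threshold in molar (default `10e-6`).
#' @param selectivity Minimum viability/activity IC50 ratio (default 5).
#' @return One-row data frame: `active`, `selective`,
#'   `selectivity_ratio`, `ratio_censored`, plus the activity and
#'   viability IC50s and censor flags.
#' @export
triage <- function(activity_fit, viability_fit = NULL,
                   active_ic50 = 10e-6, selectivity = 5) {
  a <- activity_fit
  stopifnot(inherits(a, "dose_response_fit"))
  act_ic50 <- a$ic50
  active <- isTRUE(a$converged) && !is.na(act_ic50) &&
    act_ic50 <= active_ic50
  if (is.null(viability_fit) || !isTRUE(viability_fit$converged)) {
    viab_ic50 <- NA_real_
    viab_cens <- TRUE
    bound <- if (is.null(viability_fit)) a$conc_max
    else viability_fit$ic50_bound
    ratio <- bound / act_ic50
  } else {
    viab_ic50 <- viability_fit$ic50
    viab_cens <- viability_fit$ic50_censored
    ratio <- (if (viab_cens) viability_fit$ic50_bound else viab_ic50) /
      act_ic50
  }
  data.frame(active = active,
             selective = is.finite(ratio) && ratio >= selectivity,
             selectivity_ratio = ratio, ratio_censored = viab_cens,
             activity_ic50 = act_ic50,
             activity_censored = a$ic50_censored,
             viability_ic50 = viab_ic50, viability_censored = viab_cens)
}

#' Fit activity and viability curves for a table of compounds
#'
#' @param data Data frame with columns `compound`, `concentration`
#'   (molar), `response`, `assay` (`"activity"` or `"viability"`).
#' @param active_ic50,selectivity Triage thresholds, see [triage()].
#' @return Data frame, one row per compound, with activity-fit columns and
#'   the triage columns.
#' @export
fit_compound_table <- function(data, active_ic50 = 10e-6, selectivity = 5) {
  need <- c("compound", "concentration", "response", "assay")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  do.call(rbind, lapply(split(data, data$compound), function(d) {
    act <- d[d$assay == "activity", ]
    via <- d[d$assay == "viability", ]
    af <- fit_4pl(act$concentration, act$response)
    vf <- if (nrow(via)) fit_4pl(via$concentration, via$response) else NULL
    cbind(compound = d$compound[1], af,
          triage(af, vf, active_ic50, selectivity))
  }))
}
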