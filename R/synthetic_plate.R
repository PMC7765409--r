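#' Specification of a 384-well screening plate layout with planted effects
#'
#' Encodes the plate layout used throughout the screen: one full column of
#' stimulator-control wells (maximal lipid accumulation, fractional
#' inhibition 0) and one full column of neutral-control wells (no lipid
#' induction, inhibition 1), with every other well a compound well carrying
#' a known fractional inhibition of the lipid signal and a known fractional
#' cell loss. Control placement is configuration, never hard-coded
#' downstream.
#'
#' @param n_rows,n_cols Plate dimensions (default 16 x 24).
#' @param stim_col Column of stimulator-control wells (default 11).
#' @param neutral_col Column of neutral-control wells (default 12).
#' @param inhibition Named numeric vector (names are well ids such as
#'   "B03") of fractional lipid-signal inhibition in `[0, 1]` for compound
#'   wells; unnamed wells default to 0.
#' @param cell_loss Named numeric vector of fractional cell loss in
#'   `[0, 1]` for compound wells; default 0.
#' @param empty_wells Character vector of well ids left empty.
#' @return A list of class `"plate_spec"` with a per-well `layout` data
#'   frame (`well`, `row`, `col`, `role`, `inhibition`, `cell_loss`).
#' @export
#' @examples
#' ps <- plate_spec(inhibition = c(B03 = 0.8), cell_loss = c(C05 = 0.7))
#' table(ps$layout$role)
plate_spec <- function(n_rows = 16L, n_cols = 24L,
                       stim_col = 11L, neutral_col = 12L,
                       inhibition = NULL, cell_loss = NULL,
                       empty_wells = character()) {
  stopifnot(stim_col != neutral_col,
            stim_col >= 1, stim_col <= n_cols,
            neutral_col >= 1, neutral_col <= n_cols)
  wells <- well_ids(n_rows, n_cols)
  layout <- data.frame(well = wells, row = well_row(wells),
                       col = well_col(wells), role = "compound",
                       inhibition = 0, cell_loss = 0,
                       stringsAsFactors = FALSE)
  layout$role[layout$col == stim_col] <- "stimulator"
  layout$role[layout$col == neutral_col] <- "neutral"
  layout$role[layout$well %in% empty_wells] <- "empty"
  # control wells carry their role-defined effect by construction
  layout$inhibition[layout$role == "neutral"] <- 1
  for (nm in names(inhibition)) {
    i <- match(nm, layout$well)
    if (is.na(i)) stop(sprintf("unknown well id '%s'", nm), call. = FALSE)
    if (layout$role[i] != "compound")
      stop(sprintf("well %s is a %s well; effects can only be planted in ",
                   nm, layout$role[i]), call. = FALSE)
    stopifnot(inhibition[[nm]] >= 0, inhibition[[nm]] <= 1)
    layout$inhibition[i] <- inhibition[[nm]]
  }
  for (nm in names(cell_loss)) {
    i <- match(nm, layout$well)
    if (is.na(i)) stop(sprintf("unknown well id '%s'", nm), call. = FALSE)
    stopifnot(cell_loss[[nm]] >= 0, cell_loss[[nm]] <= 1)
    layout$cell_loss[i] <- cell_loss[[nm]]
  }
  structure(list(layout = layout, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 stim_col = as.integer(stim_col),
                 neutral_col = as.integer(neutral_col)),
            class = "plate_spec")
}

# Expected discrete rendered area/signal of a droplet under `field_params`,
# averaging over the radius distribution and sub-pixel center placement.
# Keeps summary-level plate generation consistent with what image-level
# rendering plus exact quantification would measure.
expected_droplet_stats <- function(fp) {
  radii <- seq(fp$droplet_radius[1], fp$droplet_radius[2], length.out = 25)
  offs <- seq(0.05, 0.95, by = 0.1)
  area_r <- vapply(radii, function(r) {
    R <- ceiling(r)
    g <- -R:(R + 1)
    mean(vapply(offs, function(ox) mean(vapply(offs, function(oy) {
      sum(outer((g - ox)^2, (g - oy)^2, "+") <= r^2)
    }, 0)), 0))
  }, 0)
  mean_area <- mean(area_r)
  mean_peak <- mean(fp$droplet_peak)
  list(mean_area = mean_area, mean_peak = mean_peak,
       mean_signal = mean_area * mean_peak)
}

#' Generate a screening plate (summary level or image level)
#'
#' In summary mode (the default) each well's `WellSummary` row is drawn
#' directly from the generative means implied by `field`: per-cell mean
#' integrated spot signal scales linearly with the well's effective lipid
#' load, and the valid cell count scales with `(1 - cell_loss)`. In image
#' mode every well is rendered as `n_fields` full synthetic fields (use
#' small plates only). Both modes share the same generative means.
#'
#' The effective lipid load of a well is
#' `s = s0 + (1 - s0) * (1 - inhibition)`, where `s0` (`baseline_load`) is
#' the small residual load of neutral-control wells; stimulator wells
#' (inhibition 0) sit at load 1 and neutral wells (inhibition 1) at `s0`.
#'
#' @param spec A [plate_spec()].
#' @param seed Integer seed.
#' @param image_level If `TRUE`, return rendered fields per well.
#' @param field A [field_params()] object defining the per-field cell count
#'   and droplet statistics shared by both modes.
#' @param n_fields Fields imaged per well (default 6).
#' @param baseline_load Residual lipid load of neutral wells (default 0.05).
#' @param iss_cv,cells_cv Well-to-well lognormal CVs of the mean integrated
#'   spot signal and of the valid cell count (summary mode noise; set 0 for
#'   noiseless plates).
#' @param cell_target Cell-count target per well used for the low-count
#'   flag (default 600).
#' @return A list of class `"synthetic_plate"` with `wells` (one row per
#'   non-empty well: `well`, `role`, `n_fields`, `n_cells`, `mean_iss`,
#'   `mean_spots`, `mean_spot_area`, `low_cell_flag`), `truth` (planted
#'   effects and generative means), and `spec`. In image mode also
#'   `fields`, a per-well list of [generate_field()] outputs.
#' @export
generate_plate <- function(spec, seed, image_level = FALSE,
                           field = field_params(), n_fields = 6L,
                           baseline_load = 0.05,
                           iss_cv = 0.08, cells_cv = 0.06,
                           cell_target = 600) {
  stopifnot(inherits(spec, "plate_spec"))
  layout <- spec$layout
  known <- c("stimulator", "neutral", "compound", "empty")
  bad <- setdiff(unique(layout$role), known)
  if (length(bad))
    stop(sprintf("unknown well role '%s'", bad[1]), call. = FALSE)
  active <- layout[layout$role != "empty", , drop = FALSE]

  ds <- expected_droplet_stats(field)
  lambda <- field$droplets_per_cell
  s_eff <- baseline_load + (1 - baseline_load) * (1 - active$inhibition)
  mu_iss <- s_eff * lambda * ds$mean_signal      # per-cell mean ISS
  mu_spots <- s_eff * lambda                     # per-cell mean spot count
  mu_cells <- n_fields * field$n_nuclei * (1 - active$cell_loss)

  truth <- data.frame(active[, c("well", "role", "inhibition", "cell_loss")],
                      load = s_eff, mean_iss = mu_iss,
                      mean_spots = mu_spots, mean_cells = mu_cells)

  if (!image_level) {
    wells <- with_seed(seed, {
      ln <- function(cv, n) {
        if (cv <= 0) return(rep(1, n))
        sdl <- sqrt(log(1 + cv^2))
        stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
      }
      n <- nrow(active)
      e_iss <- ln(iss_cv, n)
      e_spots <- ln(iss_cv, n)
      e_cells <- ln(cells_cv, n)
      data.frame(well = active$well, role = active$role,
                 n_fields = n_fields,
                 n_cells = round(mu_cells * e_cells),
                 mean_iss = mu_iss * e_iss,
                 mean_spots = mu_spots * e_spots,
                 mean_spot_area = ds$mean_area * mu_spots * e_spots,
                 stringsAsFactors = FALSE)
    })
    wells$low_cell_flag <- wells$n_cells < cell_target
    return(structure(list(wells = wells, truth = truth, spec = spec,
                          mode = "summary"),
                     class = "synthetic_plate"))
  }

  # image mode: render fields well by well and leave quantification to the
  # imaging module
  fields <- vector("list", nrow(active))
  names(fields) <- active$well
  for (i in seq_len(nrow(active))) {
    fp <- field
    fp$steatosis <- s_eff[i] * field$steatosis
    fp$n_nuclei <- as.integer(round(field$n_nuclei *
                                      (1 - active$cell_loss[i])))
    fields[[i]] <- lapply(seq_len(n_fields), function(k) {
      generate_field(fp, child_seed(seed, (i - 1L) * n_fields + k))
    })
  }
  structure(list(fields = fields, truth = truth, spec = spec,
                 mode = "image", n_fields = n_fields),
            class = "synthetic_plate")
}
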