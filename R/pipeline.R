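#' Quantify an image-level synthetic plate
#'
#' Runs the imaging chain over every well of an image-mode
#' [generate_plate()] result and aggregates per-well summaries.
#'
#' @param plate An image-mode `"synthetic_plate"`.
#' @param params An [imaging_params()].
#' @param criteria A [validity_criteria()].
#' @param cell_target Cell-count target for the low-count flag.
#' @return Well-summary data frame comparable to summary-mode `wells`.
#' @export
quantify_plate_images <- function(plate, params = imaging_params(),
                                  criteria = validity_criteria(),
                                  cell_target = 600) {
  stopifnot(inherits(plate, "synthetic_plate"), plate$mode == "image")
  rows <- lapply(names(plate$fields), function(w) {
    cells <- lapply(plate$fields[[w]], function(f)
      quantify_field(f$nuclear, f$lipid, params, criteria)$cells)
    cbind(well = w,
          role = plate$truth$role[match(w, plate$truth$well)],
          aggregate_well(cells, cell_target))
  })
  do.call(rbind, rows)
}

#' Default configuration of a synthetic screening campaign
#'
#' All stage parameters of [run_screen()] in one object; unknown keys in
#' `...` are rejected so typos cannot silently fall back to defaults.
#'
#' @param seed Global seed.
#' @param out_dir Output directory for stage CSVs and the manifest.
#' @param ... Overrides of the default blocks (`n_plates`, `plate`,
#'   `effects`, `noise`, `hits`, `retest`, `dose`, `cluster`, `profile`).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("screen_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    n_plates = 4L,
    plate = list(n_rows = 16L, n_cols = 24L, stim_col = 11L,
                 neutral_col = 12L),
    effects = list(active_rate = 0.012, tox_rate = 0.008,
                   active_imax = 0.95,
                   active_ic50_range = c(0.1e-6, 2e-6), hill = 1,
                   tox_cell_loss = 0.7),
    noise = list(iss_cv = 0.08, cells_cv = 0.06),
    hits = list(hit_iss_inh = 50, hit_spot_inh = 50,
                require_spot_inh = TRUE, min_cell_pct = 60,
                tox_cell_pct = 40),
    retest = list(concentrations = c(10e-6, 1e-6), replicates = 3L,
                  cv = 0.1, conf_frac = 2 / 3, min_inh_high = 50,
                  min_inh_low = 20),
    dose = list(layout = "10pt", replicates = 3L, cv = 0.1,
                active_ic50 = 10e-6, selectivity = 5),
    cluster = list(n_families = 3L, bits = 512L),
    profile = list(cutoff = 7.0))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      bad2 <- setdiff(names(ov[[nm]]), names(cfg[[nm]]))
      if (length(bad2))
        stop(sprintf("unknown config key(s) in '%s': %s", nm,
                     paste(bad2, collapse = ", ")), call. = FALSE)
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Retest primary hits at two concentrations
#'
#' Simulates the two-concentration confirmation screen: each primary hit
#' is measured in `replicates` wells at each concentration, with percent
#' inhibition derived from the compound's true dose-response and
#' multiplicative noise on the remaining signal. A hit is confirmed iff
#' it clears the primary inhibition threshold at the high concentration
#' in at least `conf_frac` of replicates and shows at least
#' `min_inh_low` percent inhibition (replicate mean) at the low one.
#'
#' @param hits Data frame with columns `compound`, `ic50` (molar), `imax`
#'   (fractional maximal inhibition) and `hill`; non-active compounds can
#'   be encoded with `imax = 0`.
#' @param concentrations Two molar concentrations, high then low.
#' @param replicates Replicates per concentration.
#' @param cv Multiplicative noise CV on the remaining (uninhibited)
#'   signal fraction.
#' @param conf_frac Required fraction of high-concentration replicates
#'   clearing `min_inh_high`.
#' @param min_inh_high,min_inh_low Percent-inhibition thresholds.
#' @param seed Integer seed.
#' @return Data frame: `compound`, `inh_high` (replicate mean),
#'   `n_pass_high`, `inh_low`, `confirmed`.
#' @export
retest_stage <- function(hits, concentrations = c(10e-6, 1e-6),
                         replicates = 3L, cv = 0.1, conf_frac = 2 / 3,
                         min_inh_high = 50, min_inh_low = 20, seed = 1L) {
  if (is.null(hits) || nrow(hits) == 0)
    stop("empty primary hit list: nothing to retest", call. = FALSE)
  stopifnot(length(concentrations) == 2,
            concentrations[1] > concentrations[2])
  sdl <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  with_seed(seed, {
    out <- lapply(seq_len(nrow(hits)), function(i) {
      h <- hits[i, ]
      inh <- function(d) h$imax / (1 + (h$ic50 / d)^h$hill)
      meas <- function(d) {
        e <- if (cv > 0) stats::rlnorm(replicates, -sdl^2 / 2, sdl)
        else rep(1, replicates)
        100 * (1 - (1 - inh(d)) * e)
      }
      hi <- meas(concentrations[1])
      lo <- meas(concentrations[2])
      data.frame(compound = h$compound, inh_high = mean(hi),
                 n_pass_high = sum(hi >= min_inh_high),
                 inh_low = mean(lo),
                 confirmed = sum(hi >= min_inh_high) >=
                   ceiling(conf_frac * replicates) &
                   mean(lo) >= min_inh_low)
    })
    do.call(rbind, out)
  })
}

#' Run the synthetic screening campaign end to end
#'
#' Stages: simulate summary-mode plates with planted actives and
#' cytotoxic wells; per-plate QC; normalization and hit calling;
#' two-concentration retest; dose-response confirmation with triage;
#' fingerprint Ward clustering of confirmed compounds; target pXC50
#' profiling. Each stage writes a CSV under `out_dir` and contributes
#' counts to the returned manifest; a re-run with the identical config
#' reproduces identical file checksums.
#'
#' @param config A [run_config()].
#' @return The run manifest (list of class `"run_manifest"`): config
#'   echo, per-stage counts, file checksums and package version. Also
#'   written to `manifest.json` in `out_dir`.
#' @export
run_screen <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  files <- character()
  fp_small <- field_params(dim = c(256L, 256L), n_nuclei = 120L)

  ## --- simulate -------------------------------------------------------
  plates <- list()
  truth_all <- list()
  wells_all <- list()
  compound_meta <- list()
  for (p in seq_len(cfg$n_plates)) {
    plate_id <- sprintf("P%02d", p)
    base <- plate_spec(n_rows = cfg$plate$n_rows, n_cols = cfg$plate$n_cols,
                       stim_col = cfg$plate$stim_col,
                       neutral_col = cfg$plate$neutral_col)
    cpd_wells <- base$layout$well[base$layout$role == "compound"]
    eff <- with_seed(child_seed(cfg$seed, 100L + p), {
      n <- length(cpd_wells)
      n_act <- round(cfg$effects$active_rate * n)
      n_tox <- round(cfg$effects$tox_rate * n)
      pick <- sample(cpd_wells, n_act + n_tox)
      act <- pick[seq_len(n_act)]
      tox <- setdiff(pick, act)
      ic50 <- exp(stats::runif(n_act, log(cfg$effects$active_ic50_range[1]),
                               log(cfg$effects$active_ic50_range[2])))
      imax <- rep(cfg$effects$active_imax, n_act)
      # primary screen runs at the high retest concentration
      d0 <- cfg$retest$concentrations[1]
      inh0 <- imax / (1 + (ic50 / d0)^cfg$effects$hill)
      list(act = act, tox = tox, ic50 = ic50, imax = imax, inh0 = inh0)
    })
    spec <- plate_spec(n_rows = cfg$plate$n_rows, n_cols = cfg$plate$n_cols,
                       stim_col = cfg$plate$stim_col,
                       neutral_col = cfg$plate$neutral_col,
                       inhibition = stats::setNames(eff$inh0, eff$act),
                       cell_loss = stats::setNames(
                         rep(cfg$effects$tox_cell_loss, length(eff$tox)),
                         eff$tox))
    plate <- generate_plate(spec, seed = child_seed(cfg$seed, p),
                            field = fp_small, n_fields = 6L,
                            iss_cv = cfg$noise$iss_cv,
                            cells_cv = cfg$noise$cells_cv)
    plates[[plate_id]] <- plate
    truth_all[[plate_id]] <- cbind(plate = plate_id, plate$truth)
    wells_all[[plate_id]] <- cbind(plate = plate_id, plate$wells)
    compound_meta[[plate_id]] <- data.frame(
      plate = plate_id, well = eff$act,
      compound = paste(plate_id, eff$act, sep = "_"),
      ic50 = eff$ic50, imax = eff$imax, hill = cfg$effects$hill)
    files <- c(files, write_well_csv(plate$wells,
                                     file.path(cfg$out_dir,
                                               paste0(plate_id, "_wells.csv")),
                                     plate = plate_id))
  }
  truth <- do.call(rbind, truth_all)
  utils::write.csv(truth, file.path(cfg$out_dir, "truth.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(cfg$out_dir, "truth.csv"))
  counts$wells <- sum(vapply(wells_all, nrow, 0L))
  counts$planted_actives <- sum(vapply(compound_meta, nrow, 0L))
  counts$planted_cytotoxic <- sum(truth$cell_loss > 0)

  ## --- qc + hit calling ----------------------------------------------
  qc <- do.call(rbind, lapply(names(plates), function(pid) {
    cbind(plate = pid, qc_plate(plates[[pid]]$wells,
                                plates[[pid]]$spec$layout))
  }))
  utils::write.csv(qc, file.path(cfg$out_dir, "plate_qc.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(cfg$out_dir, "plate_qc.csv"))

  th <- do.call(hit_thresholds, cfg$hits)
  calls <- do.call(rbind, lapply(names(plates), function(pid) {
    cbind(plate = pid, call_wells(plates[[pid]]$wells,
                                  plates[[pid]]$spec$layout, th))
  }))
  utils::write.csv(calls, file.path(cfg$out_dir, "well_calls.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(cfg$out_dir, "well_calls.csv"))
  counts$hits <- sum(calls$call == "hit")
  counts$cytotoxic <- sum(calls$call == "cytotoxic")

  ## --- retest ---------------------------------------------------------
  meta <- do.call(rbind, compound_meta)
  hit_wells <- calls[calls$call == "hit", c("plate", "well")]
  hit_ids <- paste(hit_wells$plate, hit_wells$well, sep = "_")
  hits <- meta[match(hit_ids, meta$compound), ]
  # called hits that were not planted (false positives) carry no effect
  miss <- is.na(hits$compound)
  hits$compound[miss] <- hit_ids[miss]
  hits$ic50[miss] <- Inf
  hits$imax[miss] <- 0
  hits$hill[miss] <- 1
  confirmed <- if (nrow(hits)) {
    rt <- retest_stage(hits,
                       concentrations = cfg$retest$concentrations,
                       replicates = cfg$retest$replicates,
                       cv = cfg$retest$cv, conf_frac = cfg$retest$conf_frac,
                       min_inh_high = cfg$retest$min_inh_high,
                       min_inh_low = cfg$retest$min_inh_low,
                       seed = child_seed(cfg$seed, 900L))
    utils::write.csv(rt, file.path(cfg$out_dir, "retest.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(cfg$out_dir, "retest.csv"))
    rt$compound[rt$confirmed]
  } else character()
  counts$confirmed <- length(confirmed)

  ## --- dose-response confirmation -------------------------------------
  conf_meta <- meta[match(confirmed, meta$compound), ]
  dr <- if (nrow(conf_meta)) {
    do.call(rbind, lapply(seq_len(nrow(conf_meta)), function(i) {
      cm <- conf_meta[i, ]
      ds <- dose_series_spec(top = 100, bottom = 100 * (1 - cm$imax),
                             ic50 = cm$ic50, hill = cm$hill,
                             concentrations = conc_series(cfg$dose$layout),
                             n_replicates = cfg$dose$replicates,
                             cv = cfg$dose$cv,
                             seed = child_seed(cfg$seed, 2000L + i))
      d <- generate_dose_series(ds)
      fit <- fit_4pl(d$concentration, d$response)
      cbind(compound = cm$compound, fit,
            triage(fit, NULL, active_ic50 = cfg$dose$active_ic50,
                   selectivity = cfg$dose$selectivity))
    }))
  } else NULL
  if (!is.null(dr)) {
    utils::write.csv(dr, file.path(cfg$out_dir, "dose_response.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(cfg$out_dir, "dose_response.csv"))
  }
  counts$dose_dependent <- if (is.null(dr)) 0L else sum(dr$active)

  ## --- clustering + profiling -----------------------------------------
  n_conf <- length(confirmed)
  counts$clusters <- 0L
  if (n_conf >= 2) {
    cs <- generate_compound_set(n_conf, seed = child_seed(cfg$seed, 3000L),
                                n_families = min(cfg$cluster$n_families,
                                                 n_conf),
                                bits = cfg$cluster$bits)
    rownames(cs$fingerprints) <- confirmed
    cs$activities$compound <-
      confirmed[match(cs$activities$compound,
                      sprintf("C%02d", seq_len(n_conf)))]
    lk <- ward_cluster(tanimoto_matrix(cs$fingerprints))
    cl <- cut_clusters(lk, k = min(cfg$cluster$n_families, n_conf))
    counts$clusters <- length(unique(cl))
    clusters <- data.frame(compound = names(cl), cluster = as.integer(cl),
                           family_truth = cs$families)
    utils::write.csv(clusters, file.path(cfg$out_dir, "clusters.csv"),
                     row.names = FALSE)
    writeLines(linkage_newick(lk),
               file.path(cfg$out_dir, "dendrogram.nwk"))
    am <- build_activity_matrix(cs$activities,
                                cutoff = cfg$profile$cutoff)
    utils::write.csv(rank_target_classes(am, cs$class_map),
                     file.path(cfg$out_dir, "target_classes.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(cfg$out_dir,
                                c("clusters.csv", "dendrogram.nwk",
                                  "target_classes.csv")))
  }

  manifest <- structure(list(
    config = unclass(cfg),
    counts = counts,
    checksums = as.list(tools::md5sum(sort(files))),
    version = as.character(utils::packageVersion("steatoscreen"))),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
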