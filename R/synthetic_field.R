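#' Parameters for a synthetic two-channel microscopy field
#'
#' Describes one simulated imaging field of hepatocyte-like cells: bright,
#' Gaussian-tapered nuclear blobs in the nuclear channel and small uniform
#' lipid-droplet spots in the lipid channel, placed in an annulus around
#' their owner nucleus so that a cytoplasm ring of width `ring_width`
#' captures them by construction.
#'
#' `steatosis` scales the expected droplet load per cell between 0 (no
#' lipid induction, the neutral-control condition) and 1 (maximal ER-stress
#' induced accumulation, the stimulator-control condition).
#'
#' @param dim Image size in pixels, `c(rows, cols)`; each >= 64.
#' @param n_nuclei Number of valid nuclei to place.
#' @param n_invalid Number of additional deliberately invalid nuclei
#'   (rendered as sub-threshold fragments, area below any sensible minimum).
#' @param nucleus_radius Range (min, max) of nucleus radii in px.
#' @param nucleus_peak Range of nucleus peak intensities (AU).
#' @param steatosis Lipid-load level in `[0, 1]`.
#' @param droplets_per_cell Mean droplet count per cell at `steatosis = 1`
#'   (Poisson).
#' @param droplet_radius Range of droplet radii in px (uniform disks).
#' @param droplet_peak Range of droplet intensities (AU).
#' @param ring_width Width in px of the perinuclear annulus in which
#'   droplets are placed (matches the cytoplasm ring used downstream).
#' @param background Per-channel background level (nuclear, lipid), AU.
#' @param noise_sd Per-channel additive Gaussian noise SD, AU.
#' @param poisson_noise If `TRUE`, apply shot noise (Poisson resampling of
#'   pixel intensities) before the Gaussian read noise.
#' @param min_sep Minimum center-to-center distance between nuclei; the
#'   default guarantees unambiguous droplet ownership.
#' @return A list of class `"field_params"`.
#' @export
field_params <- function(dim = c(1080L, 1080L),
                         n_nuclei = 150L,
                         n_invalid = 0L,
                         nucleus_radius = c(8, 13),
                         nucleus_peak = c(2000, 3500),
                         steatosis = 1,
                         droplets_per_cell = 8,
                         droplet_radius = c(1.5, 3),
                         droplet_peak = c(1500, 3000),
                         ring_width = 15,
                         background = c(100, 100),
                         noise_sd = c(0, 0),
                         poisson_noise = FALSE,
                         min_sep = NULL) {
  stopifnot(length(dim) == 2, all(dim >= 64))
  assert_scalar(n_nuclei, "n_nuclei", nonneg = TRUE)
  assert_scalar(n_invalid, "n_invalid", nonneg = TRUE)
  assert_scalar(steatosis, "steatosis", nonneg = TRUE)
  assert_scalar(droplets_per_cell, "droplets_per_cell", nonneg = TRUE)
  assert_scalar(ring_width, "ring_width", nonneg = TRUE)
  stopifnot(length(background) == 2, all(background >= 0),
            length(noise_sd) == 2, all(noise_sd >= 0),
            diff(nucleus_radius) >= 0, nucleus_radius[1] > 0,
            diff(droplet_radius) >= 0, droplet_radius[1] > 0)
  if (is.null(min_sep))  # keeps droplet annuli of neighbouring cells disjoint
    min_sep <- 2 * (max(nucleus_radius) + ring_width + max(droplet_radius)) + 2
  structure(list(dim = as.integer(dim), n_nuclei = as.integer(n_nuclei),
                 n_invalid = as.integer(n_invalid),
                 nucleus_radius = nucleus_radius,
                 nucleus_peak = nucleus_peak, steatosis = steatosis,
                 droplets_per_cell = droplets_per_cell,
                 droplet_radius = droplet_radius,
                 droplet_peak = droplet_peak, ring_width = ring_width,
                 background = background, noise_sd = noise_sd,
                 poisson_noise = poisson_noise, min_sep = min_sep),
            class = "field_params")
}

# Additively render a disk (optionally Gaussian-tapered) into a matrix;
# returns the updated matrix plus the rendered integral and pixel area.
render_disk <- function(mat, r0, c0, radius, peak, taper = TRUE) {
  R <- ceiling(radius)
  rows <- max(1L, floor(r0 - R)):min(nrow(mat), ceiling(r0 + R))
  cols <- max(1L, floor(c0 - R)):min(ncol(mat), ceiling(c0 + R))
  d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
  inside <- d2 <= radius^2
  add <- if (taper) {
    sigma <- radius / 2
    peak * exp(-d2 / (2 * sigma^2)) * inside
  } else peak * inside
  mat[rows, cols] <- mat[rows, cols] + add
  list(mat = mat, sum = sum(add), area = sum(inside))
}

# Dart-throwing placement of n centers with minimum separation; errors when
# the requested density exceeds the packing limit.
place_centers <- function(n, dim, margin, min_sep, max_tries = 400L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(stats::runif(1, 1 + margin, dim[1] - margin),
                stats::runif(1, 1 + margin, dim[2] - margin))
      if (i == 1 ||
          min((centers[seq_len(i - 1), 1] - cand[1])^2 +
              (centers[seq_len(i - 1), 2] - cand[2])^2) >= min_sep^2) {
        centers[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("cannot place %d nuclei with min separation ",
                          "%.1f px in a %dx%d field: packing limit ",
                          "exceeded"), n, min_sep, dim[1], dim[2]),
           call. = FALSE)
  }
  centers
}

#' Generate one synthetic field with ground truth
#'
#' Renders a two-channel field according to `params` and returns both the
#' rasters and a `field_truth` object recording every planted nucleus and
#' droplet, so downstream segmentation and spot detection can be scored
#' against known truth. Output is bit-identical for identical
#' `(params, seed)`.
#'
#' @param params A [field_params()] object.
#' @param seed Integer seed.
#' @return A list with elements `nuclear` and `lipid` (numeric matrices,
#'   AU) and `truth`, a list of class `"field_truth"` with data frames
#'   `nuclei` (row, col, radius, peak, valid) and `droplets` (row, col,
#'   radius, peak, owner, area, signal), plus the background, noise and
#'   size settings.
#' @export
#' @examples
#' fp <- field_params(dim = c(128, 128), n_nuclei = 4, droplets_per_cell = 3)
#' f <- generate_field(fp, seed = 1)
#' nrow(f$truth$nuclei)
generate_field <- function(params, seed) {
  stopifnot(inherits(params, "field_params"))
  p <- params
  ntot <- p$n_nuclei + p$n_invalid
  ch1 <- matrix(p$background[1], p$dim[1], p$dim[2])
  ch2 <- matrix(p$background[2], p$dim[1], p$dim[2])

  margin <- max(p$nucleus_radius) + p$ring_width + max(p$droplet_radius) + 1
  if (2 * margin >= min(p$dim) - 2)
    stop("field too small for the configured nucleus and ring sizes",
         call. = FALSE)
  centers <- with_seed(child_seed(seed, 0L),
                       place_centers(ntot, p$dim, margin, p$min_sep))

  nuclei <- data.frame(row = numeric(0), col = numeric(0),
                       radius = numeric(0), peak = numeric(0),
                       valid = logical(0))
  droplets <- data.frame(row = numeric(0), col = numeric(0),
                         radius = numeric(0), peak = numeric(0),
                         owner = integer(0), area = numeric(0),
                         signal = numeric(0))

  if (ntot > 0) {
    valid <- c(rep(TRUE, p$n_nuclei), rep(FALSE, p$n_invalid))
    # Per-nucleus attribute draws and droplet loads live on independent
    # substreams so that raising `steatosis` only appends droplets and
    # never perturbs what is already planted (load monotonicity).
    for (i in seq_len(ntot)) {
      res <- with_seed(child_seed(seed, i), {
        rad <- if (valid[i])
          stats::runif(1, p$nucleus_radius[1], p$nucleus_radius[2])
        else stats::runif(1, 2.0, 2.8)  # sub-threshold fragment
        pk <- stats::runif(1, p$nucleus_peak[1], p$nucleus_peak[2])
        k <- 0L
        drops <- NULL
        if (valid[i]) {
          lambda <- p$steatosis * p$droplets_per_cell
          k <- stats::qpois(stats::runif(1), lambda)
          if (k > 0) {
            # droplets are kept mutually separated so that each renders as
            # its own connected spot, and are held >= 1.5 px inside the
            # outer ring edge so discretization cannot push a pixel out
            drops <- list()
            for (j in seq_len(k)) {
              drad <- stats::runif(1, p$droplet_radius[1],
                                   p$droplet_radius[2])
              dpk <- stats::runif(1, p$droplet_peak[1], p$droplet_peak[2])
              for (try in 1:50) {
                dmin <- rad + drad + 0.5
                dmax <- max(dmin, rad + p$ring_width - drad - 1.5)
                dist <- stats::runif(1, dmin, dmax)
                ang <- stats::runif(1, 0, 2 * pi)
                pos <- centers[i, ] + dist * c(sin(ang), cos(ang))
                sep_ok <- all(vapply(drops, function(d)
                  sqrt(sum((d[1:2] - pos)^2)) >= d[3] + drad + 2.2, TRUE))
                if (sep_ok) {
                  drops[[length(drops) + 1L]] <- c(pos, drad, dpk)
                  break
                }
              }
            }
          }
        }
        list(rad = rad, pk = pk, drops = drops)
      })
      rn <- render_disk(ch1, centers[i, 1], centers[i, 2],
                        res$rad, res$pk, taper = TRUE)
      ch1 <- rn$mat
      nuclei <- rbind(nuclei, data.frame(
        row = centers[i, 1], col = centers[i, 2],
        radius = res$rad, peak = res$pk, valid = valid[i]))
      for (d in res$drops) {
        rd <- render_disk(ch2, d[1], d[2], d[3], d[4], taper = FALSE)
        ch2 <- rd$mat
        droplets <- rbind(droplets, data.frame(
          row = d[1], col = d[2], radius = d[3], peak = d[4],
          owner = i, area = rd$area, signal = rd$sum))
      }
    }
  }

  with_seed(child_seed(seed, ntot + 1L), {
    if (p$poisson_noise) {
      ch1 <- matrix(stats::rpois(length(ch1), pmax(ch1, 0)), nrow(ch1))
      ch2 <- matrix(stats::rpois(length(ch2), pmax(ch2, 0)), nrow(ch2))
    }
    if (p$noise_sd[1] > 0)
      ch1 <- ch1 + matrix(stats::rnorm(length(ch1), 0, p$noise_sd[1]),
                          nrow(ch1))
    if (p$noise_sd[2] > 0)
      ch2 <- ch2 + matrix(stats::rnorm(length(ch2), 0, p$noise_sd[2]),
                          nrow(ch2))
  })

  truth <- structure(list(nuclei = nuclei, droplets = droplets,
                          background = p$background, noise_sd = p$noise_sd,
                          dim = p$dim, ring_width = p$ring_width),
                     class = "field_truth")
  list(nuclear = ch1, lipid = ch2, truth = truth)
}

#' Ground-truth per-cell droplet load of a synthetic field
#'
#' @param truth A `field_truth` object from [generate_field()].
#' @return Data frame with one row per planted nucleus: `nucleus` index,
#'   `valid`, `n_droplets`, `droplet_area`, `droplet_signal`.
#' @export
truth_cell_table <- function(truth) {
  stopifnot(inherits(truth, "field_truth"))
  n <- nrow(truth$nuclei)
  out <- data.frame(nucleus = seq_len(n), valid = truth$nuclei$valid,
                    n_droplets = 0L, droplet_area = 0,
                    droplet_signal = 0)
  if (nrow(truth$droplets)) {
    agg <- stats::aggregate(cbind(area, signal) ~ owner,
                            data = truth$droplets, FUN = sum)
    cnt <- table(truth$droplets$owner)
    out$n_droplets[agg$owner] <- as.integer(cnt[as.character(agg$owner)])
    out$droplet_area[agg$owner] <- agg$area
    out$droplet_signal[agg$owner] <- agg$signal
  }
  out
}
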