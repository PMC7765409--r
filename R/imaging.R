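#' Imaging-analysis parameters
#'
#' All tunable thresholds of the field-quantification chain live here; no
#' hidden magic numbers downstream.
#'
#' @param smooth_sigma Gaussian smoothing SD (px) before nucleus seeding.
#' @param seed_k Seed threshold in robust noise SDs above background: the
#'   seed mask is `smoothed > median + seed_k * mad(smoothed)`. In the
#'   noiseless limit this reduces to "above background", so detection is
#'   exact there.
#' @param watershed_tol Watershed tolerance used to split touching nuclei.
#' @param rel_thresh Per-nucleus refinement threshold as a fraction of the
#'   object's background-subtracted peak intensity; the refined mask is the
#'   connected set of raw pixels above it.
#' @param min_area Detection floor (px^2); smaller components are discarded
#'   as debris before validity filtering.
#' @param ring_width Cytoplasm ring width in px (default 15).
#' @param spot_bg_radius Half-width (px) of the square structuring element
#'   of the white top-hat used to flatten the lipid-channel background;
#'   must exceed the largest droplet radius.
#' @param spot_k Spot threshold in robust noise SDs of the top-hat image
#'   (MAD-based, cytoplasm-restricted).
#' @param spot_min_area Minimum spot area (px^2).
#' @param spot_merge_dist Spots with centers closer than this (px,
#'   Euclidean) are merged into one before reporting (default 2).
#' @return List of class `"imaging_params"`.
#' @export
imaging_params <- function(smooth_sigma = 2, seed_k = 6,
                           watershed_tol = 1,
                           rel_thresh = 0.1, min_area = 8,
                           ring_width = 15, spot_bg_radius = 7,
                           spot_k = 6, spot_min_area = 2,
                           spot_merge_dist = 2) {
  stopifnot(smooth_sigma > 0, rel_thresh > 0, rel_thresh < 1,
            min_area >= 1, ring_width >= 0, spot_bg_radius >= 1,
            spot_k >= 0, spot_min_area >= 1, spot_merge_dist >= 0)
  structure(list(smooth_sigma = smooth_sigma, seed_k = seed_k,
                 watershed_tol = watershed_tol, rel_thresh = rel_thresh,
                 min_area = min_area, ring_width = ring_width,
                 spot_bg_radius = spot_bg_radius, spot_k = spot_k,
                 spot_min_area = spot_min_area,
                 spot_merge_dist = spot_merge_dist),
            class = "imaging_params")
}

#' Validity criteria for segmented nuclei
#'
#' Size, shape and brightness intervals a nucleus must satisfy to count as
#' a valid cell, plus optional exclusion of border-touching nuclei (on by
#' default, to avoid truncated cytoplasm rings). The defaults are declared
#' package defaults, tuned to the synthetic data scale.
#'
#' @param min_area,max_area Nucleus area interval (px^2).
#' @param min_roundness Minimum roundness, `4 * pi * area / perimeter^2`.
#' @param min_mean_int,max_mean_int Mean nuclear-intensity interval (AU).
#' @param exclude_border Drop nuclei touching the field border.
#' @return List of class `"validity_criteria"`.
#' @export
validity_criteria <- function(min_area = 40, max_area = 3000,
                              min_roundness = 0.5, min_mean_int = 0,
                              max_mean_int = Inf, exclude_border = TRUE) {
  stopifnot(min_area < max_area, min_mean_int < max_mean_int,
            min_roundness >= 0)
  structure(list(min_area = min_area, max_area = max_area,
                 min_roundness = min_roundness,
                 min_mean_int = min_mean_int,
                 max_mean_int = max_mean_int,
                 exclude_border = isTRUE(exclude_border)),
            class = "validity_criteria")
}

# Grayscale erosion/dilation by a (2r+1)-square structuring element,
# computed separably (rows then columns) with +/-Inf edge padding so the
# flat image border is left untouched. EBImage's morphology is binary
# only, hence these.
gray_filter <- function(mat, r, op) {
  pad <- if (identical(op, pmin)) Inf else -Inf
  run1d <- function(m) {            # along rows (first index)
    out <- m
    n <- nrow(m)
    for (off in seq_len(r)) {
      up <- rbind(m[-seq_len(off), , drop = FALSE],
                  matrix(pad, off, ncol(m)))
      dn <- rbind(matrix(pad, off, ncol(m)),
                  m[seq_len(n - off), , drop = FALSE])
      out <- op(out, up, dn)
    }
    out
  }
  t(run1d(t(run1d(mat))))
}

gray_opening <- function(mat, r) {
  gray_filter(gray_filter(mat, r, pmin), r, pmax)
}

# Perimeter by the two-direction Cauchy-Crofton estimate: pi/4 times the
# count of object/background pixel faces. Exact in the limit for smooth
# convex boundaries (a discrete disk of radius r gives ~2*pi*r).
crofton_perimeter <- function(mask) {
  m <- cbind(FALSE, rbind(FALSE, mask, FALSE), FALSE)  # pad
  faces <- sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
  faces * pi / 4
}

# Measure one labelled object within its bounding-box crop.
measure_object <- function(mask, raster, r_off, c_off, full_dim) {
  idx <- which(mask, arr.ind = TRUE)
  rows <- idx[, 1] + r_off
  cols <- idx[, 2] + c_off
  vals <- raster[cbind(rows, cols)]
  perim <- crofton_perimeter(mask)
  area <- nrow(idx)
  data.frame(row = mean(rows), col = mean(cols), area = area,
             perimeter = perim,
             roundness = min(4 * pi * area / perim^2, 1.05),
             mean_int = mean(vals), total_int = sum(vals),
             border = any(rows == 1L | cols == 1L | rows == full_dim[1] |
                            cols == full_dim[2]))
}

#' Detect nuclei in a nuclear-channel raster
#'
#' Seeds nuclei by Gaussian smoothing, a robust noise-floor threshold
#' (`seed_k` MADs above the background median, which degrades gracefully
#' to "above background" on noiseless input) and a distance-transform
#' watershed to split touching objects, then refines
#' each object's mask by a per-object relative intensity threshold on the
#' raw raster (connected pixels above `rel_thresh` of the object's
#' background-subtracted peak). The refinement recovers the full extent of
#' radially tapered nuclei that a single global threshold truncates.
#' Deterministic for fixed input and parameters.
#'
#' @param raster 2-D non-negative numeric matrix (nuclear channel, AU).
#' @param params An [imaging_params()] object.
#' @return Object of class `"nuclei_set"`: list with `records` (data frame:
#'   `label`, `row`, `col`, `area`, `perimeter`, `roundness`, `mean_int`,
#'   `total_int`, `border`, `valid` (NA until filtered)), `labels` (integer
#'   matrix of refined nucleus masks) and `flags` (character; e.g.
#'   `"constant_raster"`).
#' @export
find_nuclei <- function(raster, params = imaging_params()) {
  if (is.null(raster) || length(raster) == 0)
    stop("empty raster", call. = FALSE)
  stopifnot(is.matrix(raster), is.numeric(raster))
  empty <- function(flags = character()) {
    structure(list(records = data.frame(
      label = integer(0), row = numeric(0), col = numeric(0),
      area = numeric(0), perimeter = numeric(0), roundness = numeric(0),
      mean_int = numeric(0), total_int = numeric(0), border = logical(0),
      valid = logical(0)),
      labels = matrix(0L, nrow(raster), ncol(raster)),
      dim = dim(raster), flags = flags), class = "nuclei_set")
  }
  rng <- range(raster)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant raster: no nuclei detected")
    return(empty("constant_raster"))
  }

  bg <- stats::median(raster)
  sm <- EBImage::gblur(raster, sigma = params$smooth_sigma)
  sm_bg <- stats::median(sm)
  seed_mask <- sm > sm_bg + params$seed_k * stats::mad(sm)
  if (!any(seed_mask)) return(empty("no_objects"))
  seeds <- EBImage::watershed(EBImage::distmap(seed_mask),
                              tolerance = params$watershed_tol)
  seeds <- as.matrix(EBImage::imageData(seeds))

  nlab <- max(seeds)
  labels <- matrix(0L, nrow(raster), ncol(raster))
  recs <- vector("list", nlab)
  out_lab <- 0L
  for (i in seq_len(nlab)) {
    pix <- which(seeds == i, arr.ind = TRUE)
    if (nrow(pix) == 0) next
    peak <- max(raster[pix])
    if (peak <= bg) next
    t_i <- bg + params$rel_thresh * (peak - bg)
    pad <- 4L
    r1 <- max(1L, min(pix[, 1]) - pad); r2 <- min(nrow(raster), max(pix[, 1]) + pad)
    c1 <- max(1L, min(pix[, 2]) - pad); c2 <- min(ncol(raster), max(pix[, 2]) + pad)
    crop <- raster[r1:r2, c1:c2] > t_i
    cc <- EBImage::bwlabel(crop)
    # component containing the object's peak pixel
    pk <- pix[which.max(raster[pix]), ]
    comp <- cc[pk[1] - r1 + 1L, pk[2] - c1 + 1L]
    if (comp == 0) next
    mask <- cc == comp
    # regularize ragged noisy boundaries: binary opening + closing with a
    # small disc (scaled down for tiny objects so they are not erased),
    # then fill interior holes and keep the peak's component
    r_open <- min(2L, floor(sqrt(sum(mask)) / 4))
    if (r_open >= 1) {
      br <- EBImage::makeBrush(2L * r_open + 1L, shape = "disc")
      m2 <- EBImage::closing(EBImage::opening(mask, br), br)
      m2 <- EBImage::fillHull(m2) > 0
      cc2 <- EBImage::bwlabel(m2)
      comp2 <- cc2[pk[1] - r1 + 1L, pk[2] - c1 + 1L]
      if (comp2 > 0) mask <- cc2 == comp2
    }
    # keep first-come assignment where refined masks would overlap
    taken <- labels[r1:r2, c1:c2] != 0L
    mask <- mask & !taken
    if (sum(mask) < params$min_area) next
    out_lab <- out_lab + 1L
    labels[r1:r2, c1:c2][mask] <- out_lab
    recs[[out_lab]] <- cbind(label = out_lab,
                             measure_object(mask, raster, r1 - 1L, c1 - 1L,
                                            dim(raster)))
  }
  records <- if (out_lab > 0) do.call(rbind, recs[seq_len(out_lab)])
  else empty()$records[, -match("valid", names(empty()$records))]
  records$valid <- NA
  structure(list(records = records, labels = labels, dim = dim(raster),
                 flags = character()), class = "nuclei_set")
}

#' Flag valid nuclei by size, shape, brightness and border criteria
#'
#' A nucleus is valid iff it satisfies every interval of `criteria` and,
#' when border exclusion is on, does not touch the field border.
#'
#' @param nuclei A `"nuclei_set"` from [find_nuclei()].
#' @param criteria A [validity_criteria()] object.
#' @return The `"nuclei_set"` with `records$valid` filled in.
#' @export
filter_valid_nuclei <- function(nuclei, criteria = validity_criteria()) {
  stopifnot(inherits(nuclei, "nuclei_set"),
            inherits(criteria, "validity_criteria"))
  r <- nuclei$records
  r$valid <- r$area >= criteria$min_area & r$area <= criteria$max_area &
    r$roundness >= criteria$min_roundness &
    r$mean_int >= criteria$min_mean_int &
    r$mean_int <= criteria$max_mean_int &
    (!criteria$exclude_border | !r$border)
  nuclei$records <- r
  nuclei
}

#' Build cytoplasm ring regions around valid nuclei
#'
#' Assigns every pixel that lies outside all nuclei and within `ring_width`
#' (Euclidean distance) of at least one valid nucleus to its nearest valid
#' nucleus; distance ties go to the lower label id.
#'
#' @param nuclei A `"nuclei_set"` whose `valid` flags are set (all nuclei
#'   are used if the flags are still `NA`).
#' @param ring_width Ring width in px (>= 0; 0 gives empty regions).
#' @return Integer matrix of cytoplasm labels (0 = none).
#' @export
select_cell_region <- function(nuclei, ring_width = 15) {
  stopifnot(inherits(nuclei, "nuclei_set"), ring_width >= 0)
  labels <- nuclei$labels
  use <- nuclei$records$label[is.na(nuclei$records$valid) |
                                nuclei$records$valid]
  cyto <- matrix(0L, nrow(labels), ncol(labels))
  if (ring_width == 0 || length(use) == 0) return(cyto)
  best_d <- matrix(Inf, nrow(labels), ncol(labels))
  pad <- as.integer(ceiling(ring_width)) + 1L
  for (i in sort(use)) {
    pix <- which(labels == i, arr.ind = TRUE)
    if (nrow(pix) == 0) next
    r1 <- max(1L, min(pix[, 1]) - pad); r2 <- min(nrow(labels), max(pix[, 1]) + pad)
    c1 <- max(1L, min(pix[, 2]) - pad); c2 <- min(ncol(labels), max(pix[, 2]) + pad)
    m <- labels[r1:r2, c1:c2] == i
    d <- as.matrix(EBImage::imageData(EBImage::distmap(!m)))
    sel <- which(d > 0 & d <= ring_width, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    gr <- sel[, 1] + r1 - 1L
    gc <- sel[, 2] + c1 - 1L
    ij <- cbind(gr, gc)
    better <- d[sel] < best_d[ij] - 1e-9   # strict: ties keep lower label
    if (any(better)) {
      ij <- ij[better, , drop = FALSE]
      best_d[ij] <- d[sel][better]
      cyto[ij] <- i
    }
  }
  cyto[labels > 0L] <- 0L
  cyto
}

#' Detect lipid-droplet spots within cytoplasm regions
#'
#' Flattens the lipid-channel background with a grayscale white top-hat
#' (square structuring element of half-width `spot_bg_radius`, larger than
#' any droplet), thresholds the top-hat
#' response at `spot_k` robust noise SDs (cytoplasm-restricted MAD), labels
#' connected components inside cytoplasm regions, and merges spots whose
#' centers are closer than `spot_merge_dist` px. Spot integrated intensity
#' is the background-corrected (top-hat) signal summed over the spot's
#' pixels.
#'
#' @param lipid Lipid-channel raster (matrix, same shape as `cyto`).
#' @param cyto Cytoplasm label matrix from [select_cell_region()].
#' @param params An [imaging_params()] object.
#' @return Data frame of spot records: `row`, `col`, `area`,
#'   `total_int`, `owner` (cytoplasm label).
#' @export
find_spots <- function(lipid, cyto, params = imaging_params()) {
  stopifnot(is.matrix(lipid), all(dim(lipid) == dim(cyto)))
  none <- data.frame(row = numeric(0), col = numeric(0), area = numeric(0),
                     total_int = numeric(0), owner = integer(0))
  if (!any(cyto > 0)) return(none)
  th <- lipid - gray_opening(lipid, as.integer(params$spot_bg_radius))
  sigma <- stats::mad(th[cyto > 0])
  mask <- th > params$spot_k * sigma & th > 0 & cyto > 0
  if (!any(mask)) return(none)
  cc <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
  cc[!mask] <- 0L
  n <- max(cc)
  spots <- vector("list", n)
  kept <- 0L
  for (i in seq_len(n)) {
    pix <- which(cc == i, arr.ind = TRUE)
    if (nrow(pix) < params$spot_min_area) next
    w <- th[pix]
    ctr_r <- sum(pix[, 1] * w) / sum(w)
    ctr_c <- sum(pix[, 2] * w) / sum(w)
    own <- cyto[round(ctr_r), round(ctr_c)]
    if (own == 0L) {  # weighted center fell between regions: majority vote
      tab <- table(cyto[pix][cyto[pix] > 0])
      if (length(tab) == 0) next
      own <- as.integer(names(tab)[which.max(tab)])
    }
    kept <- kept + 1L
    spots[[kept]] <- data.frame(row = ctr_r, col = ctr_c,
                                area = nrow(pix), total_int = sum(w),
                                owner = as.integer(own))
  }
  if (kept == 0L) return(none)
  sp <- do.call(rbind, spots[seq_len(kept)])

  # merge spots whose centers are < spot_merge_dist apart (union of pixels
  # -> summed area/intensity, intensity-weighted center, dominant owner)
  if (nrow(sp) > 1 && params$spot_merge_dist > 0) {
    d <- as.matrix(stats::dist(sp[, c("row", "col")]))
    grp <- seq_len(nrow(sp))
    find <- function(x) { while (grp[x] != x) x <- grp[x]; x }
    close <- which(d < params$spot_merge_dist & upper.tri(d),
                   arr.ind = TRUE)
    for (k in seq_len(nrow(close)))
      grp[find(close[k, 2])] <- find(close[k, 1])
    roots <- vapply(seq_along(grp), find, 0L)
    sp <- do.call(rbind, lapply(unique(roots), function(g) {
      s <- sp[roots == g, , drop = FALSE]
      data.frame(row = sum(s$row * s$total_int) / sum(s$total_int),
                 col = sum(s$col * s$total_int) / sum(s$total_int),
                 area = sum(s$area), total_int = sum(s$total_int),
                 owner = s$owner[which.max(s$total_int)])
    }))
  }
  rownames(sp) <- NULL
  sp
}

#' Aggregate spots into per-cell feature records
#'
#' @param nuclei A filtered `"nuclei_set"` (valid flags set).
#' @param spots Spot data frame from [find_spots()].
#' @return Data frame of cell records (valid cells only): nucleus features
#'   plus `n_spots`, `spot_signal` (sum of spot integrated intensities) and
#'   `spot_area`.
#' @export
per_cell_features <- function(nuclei, spots) {
  stopifnot(inherits(nuclei, "nuclei_set"))
  cells <- nuclei$records[which(nuclei$records$valid), , drop = FALSE]
  orphan <- setdiff(unique(spots$owner), cells$label)
  if (length(orphan))
    stop(sprintf("spot(s) owned by unknown or invalid cell label(s): %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  cells$n_spots <- 0L
  cells$spot_signal <- 0
  cells$spot_area <- 0
  if (nrow(spots)) {
    cnt <- table(spots$owner)
    i <- match(as.integer(names(cnt)), cells$label)
    cells$n_spots[i] <- as.integer(cnt)
    sig <- tapply(spots$total_int, spots$owner, sum)
    are <- tapply(spots$area, spots$owner, sum)
    cells$spot_signal[i] <- as.numeric(sig)
    cells$spot_area[i] <- as.numeric(are)
  }
  rownames(cells) <- NULL
  cells
}

#' Quantify one field end to end
#'
#' Convenience wrapper: [find_nuclei()] then [filter_valid_nuclei()],
#' [select_cell_region()], [find_spots()] and [per_cell_features()].
#'
#' @param nuclear,lipid Channel rasters (matrices of equal shape).
#' @param params An [imaging_params()] object.
#' @param criteria A [validity_criteria()] object.
#' @return List with `cells` (per-cell features), `nuclei` (the
#'   `"nuclei_set"`), `spots`, and `cyto` (ring label matrix).
#' @export
quantify_field <- function(nuclear, lipid, params = imaging_params(),
                           criteria = validity_criteria()) {
  nuc <- filter_valid_nuclei(find_nuclei(nuclear, params), criteria)
  cyto <- select_cell_region(nuc, params$ring_width)
  spots <- find_spots(lipid, cyto, params)
  list(cells = per_cell_features(nuc, spots), nuclei = nuc,
       spots = spots, cyto = cyto)
}

#' Aggregate per-cell records across fields into a well summary
#'
#' Valid cell counts are summed over fields and features are averaged over
#' the pooled valid cells (not over field means). Wells below the
#' cell-count target are flagged; a well with zero valid cells gets `NA`
#' averages and the flag, not an error.
#'
#' @param cell_tables List of per-field cell data frames (from
#'   [per_cell_features()] or `quantify_field()$cells`); at least one.
#' @param cell_target Cell-count target per well (default 600).
#' @return One-row data frame: `n_fields`, `n_cells`, `mean_iss`,
#'   `mean_spots`, `mean_spot_area`, `mean_nuc_area`, `low_cell_flag`.
#' @export
aggregate_well <- function(cell_tables, cell_target = 600) {
  stopifnot(is.list(cell_tables), length(cell_tables) >= 1)
  pooled <- do.call(rbind, cell_tables)
  n <- if (is.null(pooled)) 0L else nrow(pooled)
  avg <- function(x) if (n > 0) mean(x) else NA_real_
  data.frame(n_fields = length(cell_tables), n_cells = n,
             mean_iss = avg(pooled$spot_signal),
             mean_spots = avg(pooled$n_spots),
             mean_spot_area = avg(pooled$spot_area),
             mean_nuc_area = avg(pooled$area),
             low_cell_flag = n < cell_target)
}
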