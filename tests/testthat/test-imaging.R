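test_that("find_nuclei handles empty, constant and single-disk rasters", {
  expect_error(find_nuclei(matrix(numeric(0), 0, 0)), "empty")
  expect_warning(res <- find_nuclei(matrix(5, 64, 64)), "constant")
  expect_identical(nrow(res$records), 0L)
  expect_true("constant_raster" %in% res$flags)

  # one noiseless tapered disk of radius 10: one nucleus, area ~ pi*100
  img <- matrix(100, 96, 96)
  d2 <- outer((1:96 - 48)^2, (1:96 - 48)^2, "+")
  img <- img + 3000 * exp(-d2 / (2 * 25)) * (d2 <= 100)
  res <- find_nuclei(img)
  expect_identical(nrow(res$records), 1L)
  expect_lt(abs(res$records$area - pi * 100) / (pi * 100), 0.15)
  expect_lt(abs(res$records$row - 48), 1)
  expect_gt(res$records$roundness, 0.9)
})

test_that("synthetic nuclei are recovered with sub-2px centroids", {
  f <- generate_field(field_params(dim = c(680, 680), n_nuclei = 30,
                                   noise_sd = c(10, 0)), seed = 4)
  res <- find_nuclei(f$nuclear)
  expect_identical(nrow(res$records), 30L)
  m <- match_detections(res$records, f$truth$nuclei, max_dist = 2)
  expect_false(anyNA(m))
})

test_that("validity filtering isolates planted sub-threshold fragments", {
  f <- test_field(seed = 6, n = 8, n_invalid = 4)
  nuc <- filter_valid_nuclei(find_nuclei(f$nuclear))
  expect_identical(nrow(nuc$records), 12L)
  expect_identical(sum(nuc$records$valid), 8L)
  # detected-invalid match the planted fragments
  m <- match_detections(nuc$records[!nuc$records$valid, ],
                        f$truth$nuclei[!f$truth$nuclei$valid, ], 3)
  expect_false(anyNA(m))
  # infinite intervals + border off: everything valid
  loose <- validity_criteria(min_area = 0.5, max_area = Inf,
                             min_roundness = 0, min_mean_int = -Inf,
                             max_mean_int = Inf, exclude_border = FALSE)
  expect_true(all(filter_valid_nuclei(find_nuclei(f$nuclear),
                                      loose)$records$valid))
  # empty input stays empty
  empty <- suppressWarnings(find_nuclei(matrix(1, 64, 64)))
  expect_identical(nrow(filter_valid_nuclei(empty)$records), 0L)
})

test_that("cytoplasm rings match the brute-force nearest-nucleus oracle", {
  # hand-built disk annulus: pixel count equals the brute-force count
  lab <- matrix(0L, 80, 80)
  d2 <- outer((1:80 - 40)^2, (1:80 - 40)^2, "+")
  lab[d2 <= 64] <- 1L
  ns <- structure(list(records = data.frame(label = 1L, valid = TRUE),
                       labels = lab, dim = c(80L, 80L),
                       flags = character()), class = "nuclei_set")
  ring <- select_cell_region(ns, ring_width = 10)
  expect_identical(ring, brute_ring(lab, 10))
  expect_true(all(select_cell_region(ns, ring_width = 0) == 0L))

  # two close nuclei: disjoint regions, union = dilation minus nuclei
  lab2 <- matrix(0L, 70, 90)
  d2a <- outer((1:70 - 35)^2, (1:90 - 35)^2, "+")
  d2b <- outer((1:70 - 35)^2, (1:90 - 55)^2, "+")
  lab2[d2a <= 25] <- 1L
  lab2[d2b <= 25] <- 2L
  ns2 <- structure(list(records = data.frame(label = 1:2,
                                             valid = c(TRUE, TRUE)),
                        labels = lab2, dim = dim(lab2),
                        flags = character()), class = "nuclei_set")
  ring2 <- select_cell_region(ns2, ring_width = 15)
  oracle2 <- brute_ring(lab2, 15)
  expect_identical(ring2, oracle2)

  # randomized fields against the oracle
  set.seed(20)
  for (rep in 1:20) {
    lab <- matrix(0L, 64, 64)
    k <- sample(2:4, 1)
    ctr <- cbind(runif(k, 10, 54), runif(k, 10, 54))
    rad <- runif(k, 3, 7)
    for (i in seq_len(k)) {
      d2 <- outer((1:64 - ctr[i, 1])^2, (1:64 - ctr[i, 2])^2, "+")
      lab[d2 <= rad[i]^2 & lab == 0L] <- i
    }
    present <- sort(unique(lab[lab > 0]))
    ns <- structure(list(records = data.frame(label = present,
                                              valid = TRUE),
                         labels = lab, dim = c(64L, 64L),
                         flags = character()), class = "nuclei_set")
    w <- sample(c(5, 10, 15), 1)
    expect_identical(select_cell_region(ns, w), brute_ring(lab, w))
  }
})

test_that("find_spots is empty on uniform input and merges close spots", {
  cyto <- matrix(1L, 40, 40)
  expect_identical(nrow(find_spots(matrix(7, 40, 40), cyto)), 0L)

  # two planted droplets with centers 1 px apart: one spot, summed signal
  lip <- matrix(100, 40, 40)
  d2a <- outer((1:40 - 20)^2, (1:40 - 20)^2, "+")
  d2b <- outer((1:40 - 20)^2, (1:40 - 21)^2, "+")
  lip <- lip + 500 * (d2a <= 4) + 700 * (d2b <= 4)
  sp <- find_spots(lip, cyto)
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$total_int, sum(500 * (d2a <= 4) + 700 * (d2b <= 4)))

  # disconnected single-pixel spots within the merge radius are unified
  lip2 <- matrix(0, 40, 40)
  lip2[20, 20] <- 900
  lip2[20, 22] <- 400
  p <- imaging_params(spot_merge_dist = 3, spot_min_area = 1)
  sp2 <- find_spots(lip2, cyto, p)
  expect_identical(nrow(sp2), 1L)
  expect_equal(sp2$total_int, 1300)
  expect_equal(sp2$area, 2)

  expect_error(find_spots(matrix(0, 10, 10), matrix(1L, 9, 9)))
})

test_that("planted spots are recovered inside rings at 10x noise", {
  found <- planted <- outside <- 0
  for (s in 1:5) {
    f <- test_field(seed = s, noise = c(0, 150), n = 8, n_invalid = 0)
    q <- quantify_field(f$nuclear, f$lipid)
    planted <- planted + nrow(f$truth$droplets)
    found <- found + nrow(q$spots)
    outside <- outside + sum(q$cyto[cbind(round(q$spots$row),
                                          round(q$spots$col))] == 0)
  }
  expect_gte(found / planted, 0.95)
  expect_equal(outside, 0)
})

test_that("per-cell features aggregate spots and reject orphans", {
  f <- test_field(seed = 2)
  q <- quantify_field(f$nuclear, f$lipid)
  # spotless cell: all-zero features
  nuc <- q$nuclei
  cells0 <- per_cell_features(nuc, q$spots[0, ])
  expect_true(all(cells0$n_spots == 0L & cells0$spot_signal == 0 &
                    cells0$spot_area == 0))
  # orphan spot errors with the offending label
  bad <- q$spots
  bad$owner[1] <- 9999L
  expect_error(per_cell_features(nuc, bad), "9999")
  # uniform droplet: integrated signal = area x intensity (construction)
  expect_equal(f$truth$droplets$signal,
               f$truth$droplets$area * f$truth$droplets$peak)
})

test_that("well aggregation pools cells across fields", {
  mk <- function(sig) data.frame(spot_signal = sig,
                                 n_spots = seq_along(sig),
                                 spot_area = sig / 2,
                                 area = rep(100, length(sig)))
  w <- aggregate_well(list(mk(c(2, 2)), mk(c(4, 4, 4))), cell_target = 600)
  expect_equal(w$mean_iss, 3.2)  # pooled mean over 5 cells
  expect_identical(w$n_cells, 5L)
  expect_true(w$low_cell_flag)
  # single cell: averages equal that cell
  w1 <- aggregate_well(list(mk(7)), cell_target = 1)
  expect_equal(w1$mean_iss, 7)
  expect_false(w1$low_cell_flag)
  # empty fields: flagged, not an error
  we <- aggregate_well(list(mk(numeric(0))), cell_target = 600)
  expect_identical(we$n_cells, 0L)
  expect_true(is.na(we$mean_iss) && we$low_cell_flag)
})

test_that("quantification is deterministic and scales linearly in the
           lipid channel", {
  f <- test_field(seed = 13, noise = c(150, 120), n = 6, n_invalid = 1)
  q1 <- quantify_field(f$nuclear, f$lipid)
  q2 <- quantify_field(f$nuclear, f$lipid)
  expect_identical(q1$cells, q2$cells)
  # scaling the lipid channel by c scales every integrated signal by c
  for (c_ in c(0.5, 3)) {
    qs <- quantify_field(f$nuclear, f$lipid * c_)
    expect_identical(qs$cells$n_spots, q1$cells$n_spots)
    expect_equal(qs$cells$spot_signal, q1$cells$spot_signal * c_)
  }
})

test_that("spot signal is conserved against the cytoplasm total", {
  f <- test_field(seed = 3, noise = c(0, 0), n = 8, n_invalid = 0)
  q <- quantify_field(f$nuclear, f$lipid)
  total_cyto <- sum((f$lipid - f$truth$background[2])[q$cyto > 0])
  expect_lte(sum(q$cells$spot_signal), total_cyto + 1e-9)
  expect_equal(sum(q$cells$spot_signal), sum(f$truth$droplets$signal))
})
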