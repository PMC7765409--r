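test_that("Z'-factor reproduces the printed formula", {
  # means 100 and 0, SDs 5 and 5
  expect_equal(as.numeric(z_prime(c(95, 100, 105), c(-5, 0, 5))), 0.7)
  expect_identical(attr(z_prime(c(95, 100, 105), c(-5, 0, 5)), "band"),
                   "excellent")
  # zero spreads, distinct means
  expect_equal(as.numeric(z_prime(c(10, 10, 10), c(2, 2, 2))), 1)
  # boundary: 3*(SD1+SD2) = |mu1-mu2| gives exactly 0
  s <- c(95, 100, 105)                       # sd 5, mean 100
  n <- c(65, 70, 75)                         # sd 5, mean 70
  expect_equal(as.numeric(z_prime(s, n)), 0)
  expect_error(z_prime(c(1, 2, 3), c(3, 2, 1)), "equal means")
  # order of groups does not flip the sign
  expect_equal(as.numeric(z_prime(c(-5, 0, 5), c(95, 100, 105))), 0.7)
})

test_that("Z' is invariant under affine transforms of the readout", {
  set.seed(1)
  s <- rnorm(16, 100, 5); n <- rnorm(16, 10, 2)
  z0 <- as.numeric(z_prime(s, n))
  for (ab in list(c(2, 0), c(0.1, 50), c(-3, 7))) {
    expect_equal(as.numeric(z_prime(ab[1] * s + ab[2], ab[1] * n + ab[2])),
                 z0)
  }
})

test_that("robust Z' shrugs off an outlier that wrecks Z'", {
  # noiseless symmetric groups: both statistics are exactly 1
  expect_equal(robust_z_prime(c(9, 9, 9), c(1, 1, 1)), 1)
  expect_equal(as.numeric(z_prime(c(9, 9, 9), c(1, 1, 1))), 1)
  # constructed 17-value control group with one wild outlier
  set.seed(2)
  s <- rnorm(16, 100, 3)
  n <- rnorm(16, 10, 3)
  z0 <- as.numeric(z_prime(s, n)); r0 <- robust_z_prime(s, n)
  n_out <- c(n, 90)
  expect_lt(abs(robust_z_prime(s, n_out) - r0),
            abs(as.numeric(z_prime(s, n_out)) - z0))
  expect_error(robust_z_prime(c(1, 2, 3), c(2, 1, 3)), "equal medians")
})

test_that("percent inhibition hits its endpoints and is affine", {
  expect_equal(percent_inhibition(10, ave_pos = 0, ave_neg = 10), 0)
  expect_equal(percent_inhibition(0, ave_pos = 0, ave_neg = 10), 100)
  expect_equal(percent_inhibition(5, ave_pos = 0, ave_neg = 10), 50)
  expect_error(percent_inhibition(5, 3, 3), "equal")
  # invariant under common rescaling, affine in the value
  v <- c(2, 4, 8)
  expect_equal(percent_inhibition(10 * v, 10 * 1, 10 * 9),
               percent_inhibition(v, 1, 9))
  p <- percent_inhibition(v, 0, 10)
  expect_equal(diff(p), 100 * diff(v - 10) / (0 - 10) * 1)
})

test_that("plate QC computes control statistics and flags missing columns", {
  ps <- plate_spec()
  noiseless <- generate_plate(ps, seed = 1, iss_cv = 0, cells_cv = 0)
  qc <- qc_plate(noiseless$wells, ps$layout)
  expect_equal(qc$z_prime, 1)
  expect_equal(qc$cv_stim, 0)
  expect_equal(qc$cv_neutral, 0)
  expect_gt(qc$s_b, 1)
  expect_identical(qc$n_stim, 16L)

  # controls-only plate still yields QC
  ctrl_only <- plate_spec(empty_wells = ps$layout$well[
    !ps$layout$col %in% c(11, 12)])
  pc <- generate_plate(ctrl_only, seed = 2)
  expect_s3_class(qc_plate(pc$wells, ctrl_only$layout), "plate_qc")

  broken <- noiseless$wells[!(well_col(noiseless$wells$well) == 12), ]
  expect_error(qc_plate(broken, ps$layout), "neutral")
})

test_that("summary-plate Z' agrees with its generative closed form", {
  # closed form from the lognormal well noise of the generator
  ps <- plate_spec()
  iss_cv <- 0.08; s0 <- 0.05
  zs <- vapply(1:50, function(s) {
    pl <- generate_plate(ps, seed = s, iss_cv = iss_cv, cells_cv = 0.06,
                         baseline_load = s0)
    qc_plate(pl$wells, ps$layout)$z_prime
  }, 0)
  z_closed <- 1 - 3 * (iss_cv + s0 * iss_cv) / (1 - s0)
  se <- stats::sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs) - z_closed), 3 * se + 0.02)
})

test_that("well calls follow the hit and cytotoxicity rules", {
  lay <- plate_spec(n_rows = 2, n_cols = 5, stim_col = 1,
                    neutral_col = 2)$layout
  mk <- function(w, iss, spots, cells)
    data.frame(well = w, mean_iss = iss, mean_spots = spots,
               n_cells = cells)
  wells <- rbind(
    mk(c("A01", "B01"), 100, 10, 1000),   # stimulator
    mk(c("A02", "B02"), 0, 0, 1000),      # neutral
    mk("A03", 40, 4.5, 800),              # 60% ISS, 55% spots, 80% cells
    mk("A04", 20, 2, 350),                # 35% cells: cytotoxic
    mk("A05", 60, 6, 900))                # 40% ISS: no effect
  calls <- call_wells(wells, lay)
  expect_identical(calls$call[calls$well == "A03"], "hit")
  expect_identical(calls$call[calls$well == "A04"], "cytotoxic")
  expect_identical(calls$call[calls$well == "A05"], "no-effect")
  expect_true(all(calls$call[calls$well %in%
                               c("A01", "B01", "A02", "B02")] == "control"))
  expect_equal(calls$iss_inh[calls$well == "A03"], 60)
  expect_equal(calls$spot_inh[calls$well == "A03"], 55)

  # cytotoxicity takes precedence over any inhibition
  wells2 <- rbind(wells[1:4, ], mk("A05", 0, 0, 300))  # 100% inh, 30% cells
  expect_identical(call_wells(wells2, lay)$call[5], "cytotoxic")

  # ISS-only mode accepts a well failing the spot criterion
  wells3 <- rbind(wells[1:4, ], mk("A05", 40, 8, 900))  # spots only 20% inh
  expect_identical(call_wells(wells3, lay)$call[5], "no-effect")
  th <- hit_thresholds(require_spot_inh = FALSE)
  expect_identical(call_wells(wells3, lay, th)$call[5], "hit")
})

test_that("calls survive a CSV round trip exactly", {
  ps <- plate_spec(inhibition = c(B03 = 0.85, C07 = 0.9),
                   cell_loss = c(D09 = 0.75))
  pl <- generate_plate(ps, seed = 3)
  calls1 <- call_wells(pl$wells, ps$layout)
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_csv(pl$wells, path, plate = "P01")
  wells2 <- read_well_csv(path)[, -1]   # drop plate column
  calls2 <- call_wells(wells2, ps$layout)
  expect_identical(calls1, calls2)
})
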