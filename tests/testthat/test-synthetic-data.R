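test_that("field generation is seed-deterministic and honours edge cases", {
  fp <- field_params(dim = c(160, 160), n_nuclei = 3, droplets_per_cell = 4)
  f1 <- generate_field(fp, seed = 42)
  f2 <- generate_field(fp, seed = 42)
  expect_identical(f1$nuclear, f2$nuclear)
  expect_identical(f1$lipid, f2$lipid)
  expect_identical(f1$truth$nuclei, f2$truth$nuclei)

  # empty field: image equals background + noise, truth lists empty
  f0 <- generate_field(field_params(dim = c(96, 96), n_nuclei = 0,
                                    noise_sd = c(0, 0)), seed = 1)
  expect_true(all(f0$nuclear == 100) && all(f0$lipid == 100))
  expect_identical(nrow(f0$truth$nuclei), 0L)
  expect_identical(nrow(f0$truth$droplets), 0L)

  # over-packed request hits the packing limit with an explicit error
  expect_error(generate_field(field_params(dim = c(128, 128),
                                           n_nuclei = 60), seed = 1),
               "packing limit")
})

test_that("noiseless channel-1 components equal the planted nucleus count", {
  fp <- field_params(dim = c(600, 600), n_nuclei = 20, noise_sd = c(0, 0))
  f <- generate_field(fp, seed = 9)
  comp <- EBImage::bwlabel(f$nuclear > f$truth$background[1])
  expect_equal(max(comp), 20)
})

test_that("planted droplets satisfy the ground-truth invariants", {
  for (s in 1:5) {
    f <- test_field(seed = s)
    tr <- f$truth
    expect_true(all(tr$nuclei$radius > 0))
    expect_true(all(tr$droplets$radius > 0))
    expect_true(all(tr$droplets$peak > 0))
    # droplet centers inside the ring-width dilation of the owner nucleus
    own <- tr$nuclei[tr$droplets$owner, ]
    cd <- sqrt((tr$droplets$row - own$row)^2 +
                 (tr$droplets$col - own$col)^2)
    expect_true(all(cd <= own$radius + tr$ring_width))
    expect_true(all(cd > own$radius))
    # uniform droplets: rendered signal equals area x peak
    expect_equal(tr$droplets$signal, tr$droplets$area * tr$droplets$peak)
  }
})

test_that("raising steatosis never decreases total planted droplet signal", {
  fp <- field_params(dim = c(384, 384), n_nuclei = 8)
  for (s in 1:5) {
    sig <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(level) {
      fp$steatosis <- level
      sum(generate_field(fp, seed = s)$truth$droplets$signal)
    }, 0)
    expect_true(all(diff(sig) >= 0))
  }
})

test_that("plate spec encodes roles, control effects and rejects bad wells", {
  ps <- plate_spec(inhibition = c(B03 = 0.8), cell_loss = c(C05 = 0.7))
  lay <- ps$layout
  expect_identical(nrow(lay), 384L)
  expect_true(all(lay$role[lay$col == 11] == "stimulator"))
  expect_true(all(lay$role[lay$col == 12] == "neutral"))
  expect_true(all(lay$inhibition[lay$role == "stimulator"] == 0))
  expect_true(all(lay$inhibition[lay$role == "neutral"] == 1))
  expect_identical(lay$inhibition[lay$well == "B03"], 0.8)
  expect_error(plate_spec(inhibition = c(Z99 = 0.5)), "unknown well")
  expect_error(plate_spec(inhibition = c(A11 = 0.5)), "stimulator")
})

test_that("summary plates are linear in inhibition and seed-stable", {
  ps <- plate_spec(inhibition = c(B03 = 0.5))
  pl <- generate_plate(ps, seed = 1, iss_cv = 0, cells_cv = 0)
  w <- pl$wells
  stim <- mean(w$mean_iss[w$role == "stimulator"])
  neut <- mean(w$mean_iss[w$role == "neutral"])
  expect_true(all(w$mean_iss[w$role == "stimulator"] == stim))
  expect_true(all(w$mean_iss[w$role == "neutral"] == neut))
  expect_lt(neut, stim)
  # inhibition 0.5 sits exactly midway between the control means
  expect_equal(w$mean_iss[w$well == "B03"], (stim + neut) / 2)

  p1 <- generate_plate(ps, seed = 5)
  p2 <- generate_plate(ps, seed = 5)
  expect_identical(p1$wells, p2$wells)
})

test_that("summary-level and image-level plate generation share means", {
  # one compound well at inhibition 0.5, quantified from rendered fields,
  # against the summary-mode generative mean, over 20 seeds
  ps <- plate_spec(n_rows = 1, n_cols = 3, stim_col = 2, neutral_col = 3,
                   inhibition = c(A01 = 0.5))
  fp <- field_params(dim = c(320, 320), n_nuclei = 5)
  iss <- numeric(20)
  mu <- NA
  for (s in 1:20) {
    pl <- generate_plate(ps, seed = s, image_level = TRUE, field = fp,
                         n_fields = 2)
    w <- quantify_plate_images(pl, cell_target = 1)
    iss[s] <- w$mean_iss[w$well == "A01"]
    mu <- pl$truth$mean_iss[pl$truth$well == "A01"]
  }
  se <- stats::sd(iss) / sqrt(length(iss))
  expect_lt(abs(mean(iss) - mu), 3 * se + 0.01 * mu)
})

test_that("dose series honour the 4PL curve, seeding and noise contracts", {
  sp0 <- dose_series_spec(top = 100, bottom = 0, ic50 = 1e-6, hill = 1,
                          cv = 0, seed = 3)
  d0 <- generate_dose_series(sp0)
  expect_equal(d0$response,
               fourpl(d0$concentration, 100, 0, 1e-6, 1))
  # response at x = ic50 is the midpoint
  spm <- dose_series_spec(top = 80, bottom = 20, ic50 = 2e-6, hill = 1.5,
                          concentrations = c(1e-7, 5e-7, 2e-6, 1e-5),
                          cv = 0)
  dm <- generate_dose_series(spm)
  expect_equal(unique(dm$response[dm$concentration == 2e-6]), 50)

  sp <- dose_series_spec(top = 100, bottom = 0, ic50 = 1e-6, hill = 1,
                         cv = 0.1, n_replicates = 3, seed = 7)
  expect_identical(generate_dose_series(sp), generate_dose_series(sp))
  expect_error(dose_series_spec(ic50 = -1), "ic50")
})

test_that("Cq tables encode planted fold changes in cycles", {
  sp <- cq_spec(genes = c("CDK4", "CDK2"), groups = c("TGFA", "TRT"),
                log2fc = matrix(c(1, 0), 2, 1,
                                dimnames = list(c("CDK4", "CDK2"), "TRT")),
                noise_sd = 0)
  cq <- generate_cq_table(sp)
  m <- tapply(cq$cq, list(cq$gene, cq$group), mean)
  # fold change 2 -> exactly one cycle lower in the treated group
  expect_equal(m["CDK4", "TGFA"] - m["CDK4", "TRT"], 1)
  expect_equal(m["CDK2", "TGFA"], m["CDK2", "TRT"])
  # reference genes flat everywhere
  expect_equal(m["HPRT1", "TGFA"], m["HPRT1", "TRT"])
  # seeding contract
  spn <- cq_spec(genes = "CDK4", groups = c("TGFA", "TRT"),
                 noise_sd = 0.1, seed = 11)
  expect_identical(generate_cq_table(spn), generate_cq_table(spn))
})

test_that("compound sets plant recoverable fingerprint families", {
  cs <- generate_compound_set(21, seed = 2, n_families = 3)
  expect_identical(dim(cs$fingerprints), c(21L, 2048L))
  d <- tanimoto_matrix(cs$fingerprints)
  same <- outer(cs$families, cs$families, "==")
  expect_lt(max(d[same & upper.tri(d)]), min(d[!same & upper.tri(d)]))
  expect_identical(generate_compound_set(21, seed = 2)$fingerprints,
                   cs$fingerprints)
})
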