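# Lesion extraction, surface area, sphericity and intensity features.

test_that("connected-component extraction follows 26-connectivity and is deterministic", {
  m <- two_cubes_mask()
  les <- extract_lesions(m, c(1, 1, 1))
  expect_length(les, 2L)
  expect_equal(vapply(les, `[[`, 0L, "n"), c(27L, 27L))
  expect_equal(vapply(les, `[[`, 0, "V"), c(27, 27))
  expect_equal(vapply(les, `[[`, "", "lesion_id"), c("L001", "L002"))

  # two cubes sharing only a corner diagonal are one 26-connected lesion
  m2 <- array(0L, c(10L, 10L, 10L))
  m2[2:4, 2:4, 2:4] <- 1L
  m2[5:7, 5:7, 5:7] <- 1L
  expect_length(extract_lesions(m2), 1L)

  # empty mask -> empty list; non-binary mask -> error
  expect_identical(extract_lesions(array(0L, c(4, 4, 4))), list())
  bad <- array(0L, c(4, 4, 4)); bad[2, 2, 2] <- 2L
  expect_error(extract_lesions(bad), "binary")
})

test_that("minimum-volume filter drops small components when enabled", {
  m <- two_cubes_mask(side = 2L)            # two 8-voxel cubes
  m[18L, 18L, 18L] <- 1L                    # plus a single voxel
  expect_length(extract_lesions(m), 3L)
  expect_length(extract_lesions(m, min_volume = 5), 2L)
  expect_length(extract_lesions(m, min_volume = "3mm"), 0L)  # all < 14.14 mm^3
})

test_that("surface area approaches the analytic sphere area", {
  b15 <- digital_ball(15)
  A <- surface_area(b15)
  expect_lt(abs(A / (4 * pi * 15^2) - 1), 0.03)

  # scaling law: doubling voxel dims quadruples the area
  b8 <- digital_ball(8)
  expect_equal(surface_area(b8, c(2, 2, 2)) / surface_area(b8, c(1, 1, 1)), 4,
               tolerance = 1e-10)

  # invariance to the amount of background padding around the crop
  expect_equal(surface_area(digital_ball(8, pad = 2L)),
               surface_area(digital_ball(8, pad = 6L)), tolerance = 1e-10)
})

test_that("solid-cube surface matches the independent oracle and analytic band", {
  A <- surface_area(solid_cube(20L))
  # band spanned by the inner (19^3) and outer (20^3) analytic cube surfaces
  expect_gt(A, 6 * 19^2 * 0.95)
  expect_lt(A, 6 * 20^2 * 1.05)
  # pinned against an independent iso-surface implementation run on the
  # same smoothed field (frozen oracle value 2192.69 mm^2)
  expect_equal(A, 2192.69, tolerance = 0.02)
})

test_that("sphericity matches analytic values and decreases with elongation", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-14)  # unit sphere
  expect_equal(sphericity(1, 6), (36 * pi)^(1 / 3) / 6)      # unit cube
  expect_equal(sphericity(1, 6), 0.8060, tolerance = 1e-4)
  expect_error(sphericity(0, 1), "positive")
  expect_error(sphericity(1, -1), "positive")

  # equal-volume ellipsoids: higher axis ratio -> strictly lower sphericity
  ball <- rasterize_lesion(4189, 1, c(0, 0, 1), c(24, 24, 24), c(48, 48, 48))
  elong <- rasterize_lesion(4189, 3, c(1, 1, 1), c(24, 24, 24), c(48, 48, 48))
  psi_ball <- extract_lesions(ball)[[1]]$sphericity
  psi_elong <- extract_lesions(elong)[[1]]$sphericity
  expect_lt(psi_elong, psi_ball)
})

test_that("digital-ball sphericity converges to 1 and SVR*V = A", {
  radii <- c(5, 8, 10, 15, 20, 25)
  psi <- vapply(radii, function(r) {
    b <- digital_ball(r)
    sphericity(sum(b), surface_area(b))
  }, 0)
  # converges to 1: each step may wiggle by at most the residual error scale
  expect_true(all(diff(abs(psi - 1)) < 0.005))
  expect_lt(abs(psi[length(psi)] - 1), 0.01)
  expect_true(all(psi[radii >= 10] > 0.93 & psi[radii >= 10] < 1.05))

  les <- extract_lesions(two_cubes_mask(), c(1, 1, 1.5))
  for (l in les) expect_equal(l$SVR * l$V, l$A, tolerance = 1e-12)
})

test_that("feature values are invariant under axis-aligned translation", {
  m1 <- two_cubes_mask(at1 = c(3L, 3L, 3L), at2 = c(12L, 12L, 12L))
  m2 <- two_cubes_mask(at1 = c(5L, 7L, 4L), at2 = c(14L, 16L, 14L))
  f1 <- extract_lesions(m1, c(1, 1, 1.5))
  f2 <- extract_lesions(m2, c(1, 1, 1.5))
  for (k in 1:2) for (fld in c("n", "V", "A", "sphericity", "SVR"))
    expect_equal(f1[[k]][[fld]], f2[[k]][[fld]], tolerance = 1e-10)
})

test_that("intensity features have the stated conventions and bounds", {
  expect_equal(intensity_features(c(1, 1, 5, 5))$skewness, 0)   # symmetry

  # all values in one bin -> 0 bits; uniform fill of 64 bins -> 6 bits
  expect_equal(intensity_features(rep(2, 10))$entropy, 0)
  expect_equal(intensity_features(c(rep(1, 8), rep(2, 8)))$entropy, 1)  # two bins
  centres <- rep((seq_len(64) - 0.5) / 64, each = 3)
  expect_equal(intensity_features(centres)$entropy, 6, tolerance = 1e-12)

  # entropy bounded by log2(bins); kurtosis of a Gaussian near 3
  set.seed(11)
  g <- rnorm(20000)
  feats <- intensity_features(g)
  expect_gte(feats$entropy, 0); expect_lte(feats$entropy, 6)
  expect_equal(feats$kurtosis, 3, tolerance = 0.15)
  expect_equal(feats$skewness, 0, tolerance = 0.1)

  # constant intensity is degenerate: all features 0, flagged
  d <- intensity_features(rep(7, 5))
  expect_true(d$degenerate)
  expect_identical(c(d$skewness, d$kurtosis, d$entropy), c(0, 0, 0))
})

test_that("lesion_features assembles the per-lesion table with intensities", {
  m <- two_cubes_mask()
  img <- array(rnorm(prod(dim(m)), 100, 10), dim(m))
  img[m == 1] <- rnorm(sum(m), 160, 10)
  tab <- lesion_features(m, labeled_volume(img, c(1, 1, 1.5)),
                         patient_id = "P7",
                         locations = c("periventricular", "spinal"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$patient_id, rep("P7", 2))
  expect_equal(tab$V_mm3, rep(27 * 1.5, 2))
  expect_false(anyNA(tab$skewness))
  expect_equal(tab$location, c("periventricular", "spinal"))
  expect_error(lesion_features(m, labeled_volume(img[1:10, , ], c(1, 1, 1))),
               "same grid")
})
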