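# Synthetic cohort generator: determinism, composition, lesion geometry,
# spec validation, and the realised group contrasts.

test_that("cohort composition and determinism follow the spec", {
  spec <- small_spec(seed = 7L)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_length(co1$patients, 16L)
  expect_equal(sum(vapply(co1$patients, `[[`, TRUE, "converted")), 11L)
  # identical spec + seed => bit-identical cohort
  for (i in c(1L, 9L, 16L)) {
    expect_identical(co1$patients[[i]]$mask, co2$patients[[i]]$mask)
    expect_identical(co1$patients[[i]]$intensity$data, co2$patients[[i]]$intensity$data)
  }
  expect_identical(co1$table, co2$table)
})

test_that("masks are binary, boundary-padded, and labelled per lesion", {
  co <- generate_cohort(small_spec(seed = 3L))
  for (p in co$patients) {
    expect_true(all(p$mask %in% c(0L, 1L)))
    gs <- dim(p$mask)
    # no lesion within 2 voxels of the grid boundary
    expect_equal(sum(p$mask[c(1:2, gs[1] - 1:0), , ]), 0L)
    expect_equal(sum(p$mask[, c(1:2, gs[2] - 1:0), ]), 0L)
    expect_equal(sum(p$mask[, , c(1:2, gs[3] - 1:0)]), 0L)
    # one location label per connected lesion
    les <- extract_lesions(p$mask, co$spec$voxel_dims)
    expect_equal(length(les), nrow(p$lesions))
    expect_true(all(p$lesions$location %in%
                      c("periventricular", "juxtacortical", "infratentorial", "spinal")))
  }
})

test_that("rasterized ellipsoids hit their target volume and separate", {
  # digital ball of ~4189 mm^3 (r ~ 10 mm) at 1 mm^3 voxels
  b <- rasterize_lesion(4189, 1, c(0, 0, 1), c(24, 24, 24), c(48, 48, 48))
  expect_lt(abs(sum(b) - 4189) / 4189, 0.05)

  # two lesions at disjoint centers -> 2 connected components
  m <- rasterize_lesion(500, 1.5, c(1, 0, 0), c(12, 12, 12), c(48, 48, 48)) +
       rasterize_lesion(500, 1.5, c(0, 1, 0), c(36, 36, 36), c(48, 48, 48))
  expect_length(extract_lesions(array(as.integer(m > 0), dim(m))), 2L)

  # out-of-bounds center errors, naming the lesion
  expect_error(rasterize_lesion(4189, 1, c(0, 0, 1), c(3, 3, 3), c(48, 48, 48)),
               "does not fit")
})

test_that("lesion volume targets smaller than one voxel reject the spec", {
  expect_error(cohort_spec(volume_range = c(1, 671), voxel_dims = c(1, 1, 1.5)),
               "smaller than one voxel")
  expect_error(cohort_spec(n_converters = 90L), "exceed")
  expect_error(cohort_spec(sphericity_target_converter = 1.2), "sphericity")
})

test_that("group contrasts are realised: volumes near targets, sphericity ordered", {
  co <- generate_cohort(cohort_spec(seed = 11L))
  lt <- cohort_features(co)
  vmeans <- tapply(lt$V_mm3, lt$converted, mean)
  expect_lt(abs(vmeans[["1"]] - 135) / 135, 0.15)
  expect_lt(abs(vmeans[["0"]] - 71) / 71, 0.15)
  smeans <- tapply(lt$sphericity, lt$converted, mean)
  expect_lt(smeans[["1"]], smeans[["0"]])
})

test_that("sphericity ordering holds across several seeded small cohorts", {
  for (s in 1:5) {
    co <- generate_cohort(small_spec(seed = 20L + s))
    lt <- cohort_features(co)
    smeans <- tapply(lt$sphericity, lt$converted, mean)
    expect_lt(smeans[["1"]], smeans[["0"]])
  }
})

test_that("cohort IO round-trips through NIfTI and cohort.csv", {
  dir <- file.path(tempdir(), "cohort-io")
  on.exit(unlink(dir, recursive = TRUE))
  co <- generate_cohort(small_spec(seed = 5L))
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  pats <- read_cohort(dir)
  expect_length(pats, 16L)
  p0 <- co$patients[[4]]; p1 <- pats[[4]]
  expect_equal(p1$patient_id, p0$patient_id)
  expect_equal(p1$mask, p0$mask)
  expect_equal(p1$intensity$voxel_dims, p0$intensity$voxel_dims, tolerance = 1e-6)
  expect_equal(p1$intensity$data, p0$intensity$data, tolerance = 1e-6)
  expect_equal(p1$converted, p0$converted)
  # a missing mask file errors with the patient id
  file.remove(file.path(dir, "P003_mask.nii.gz"))
  expect_error(read_cohort(dir), "P003")
})
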