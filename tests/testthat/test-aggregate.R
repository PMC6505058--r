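# Fixed-length per-patient aggregation of per-lesion features.

fake_lesions <- function(V, patient_id = "P1") {
  k <- length(V)
  data.frame(patient_id = rep(patient_id, k),
             lesion_id = sprintf("L%03d", seq_len(k)),
             n = as.integer(V), V_mm3 = V, A_mm2 = V * 2,
             sphericity = seq(0.5, 0.9, length.out = k),
             SVR = rep(2, k), skewness = rnorm(k), kurtosis = rnorm(k, 3),
             entropy_bits = runif(k, 0, 6), location = rep("periventricular", k),
             stringsAsFactors = FALSE)
}

test_that("single-lesion and multi-lesion aggregation statistics are exact", {
  one <- fake_lesions(27)
  v <- aggregate_patient(one, "shape")
  expect_equal(unname(v[c("volume_min", "volume_max", "volume_mean", "volume_std")]),
               c(27, 27, 27, 0))
  expect_equal(unname(v["total_lesion_volume"]), 27)
  expect_equal(unname(v["lesion_count"]), 1)

  three <- fake_lesions(c(10, 20, 30))
  v3 <- aggregate_patient(three, "shape")
  expect_equal(unname(v3["volume_mean"]), 20)
  expect_equal(unname(v3["total_lesion_volume"]), 60)
  expect_equal(unname(v3["lesion_count"]), 3)
  # population standard deviation
  expect_equal(unname(v3["volume_std"]), sqrt(mean((c(10, 20, 30) - 20)^2)))
})

test_that("vector lengths are 18 / 14 / 30 and min <= mean <= max", {
  set.seed(1)
  les <- fake_lesions(c(12, 40, 7, 90))
  v_shape <- aggregate_patient(les, "shape")
  v_int <- aggregate_patient(les, "intensity")
  v_comb <- aggregate_patient(les, "combined")
  expect_length(v_shape, 18L)
  expect_length(v_int, 14L)
  expect_length(v_comb, 30L)
  for (f in c("volume", "surface_area", "sphericity", "svr")) {
    expect_lte(v_shape[paste0(f, "_min")], v_shape[paste0(f, "_mean")])
    expect_lte(v_shape[paste0(f, "_mean")], v_shape[paste0(f, "_max")])
  }
  # combined = shape stats + intensity stats with one shared total/count
  expect_identical(v_comb[names(v_shape)], v_shape)
  expect_identical(v_comb[names(v_int)], v_int)
  expect_length(unique(c(names(v_shape), names(v_int))), 30L)
})

test_that("aggregation is permutation-invariant over lesion order", {
  set.seed(2)
  les <- fake_lesions(c(5, 50, 500, 55, 15))
  v1 <- aggregate_patient(les, "combined")
  v2 <- aggregate_patient(les[sample(nrow(les)), ], "combined")
  expect_equal(v1, v2)
})

test_that("zero-lesion patients error unless imputation is enabled", {
  empty <- fake_lesions(numeric(0))
  expect_error(aggregate_patient(empty, "shape"), "no lesions")
  v <- aggregate_patient(empty, "shape", allow_empty = TRUE)
  expect_length(v, 18L)
  expect_true(all(v == 0))
})

test_that("aggregate_cohort keeps requested patient order and imputes absentees", {
  set.seed(3)
  tab <- rbind(fake_lesions(c(10, 20), "Pa"), fake_lesions(30, "Pb"))
  out <- aggregate_cohort(tab, "shape", patient_ids = c("Pb", "Pa", "Pc"))
  expect_equal(out$patient_id, c("Pb", "Pa", "Pc"))
  expect_equal(out$lesion_count, c(1, 2, 0))
  expect_equal(out$total_lesion_volume, c(30, 30, 0))
})
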