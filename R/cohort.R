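# Synthetic lesion cohorts: reproducible stand-ins for a baseline-MRI CIS
# cohort, with group-specific lesion volume and shape distributions so that
# converters carry larger, less spherical lesions than non-converters.

DIS_AREAS <- c("periventricular", "juxtacortical", "infratentorial", "spinal")

#' Specification of a synthetic CIS cohort
#'
#' Defaults emulate the cohort the package's models are aimed at: 84
#' patients of whom 66 convert to MS within three years, converter lesions
#' averaging 135 mm^3 against 71 mm^3 for non-converters (single-lesion
#' volumes truncated to the observed 22-671 mm^3 range), converter lesions
#' markedly less spherical (group sphericity targets 0.78 vs 0.927), on a
#' 96 x 96 x 64 grid at 1 x 1 x 1.5 mm echoing a 3D FLAIR acquisition.
#'
#' Lesions are triaxial ellipsoids with lognormal volumes; elongation is
#' obtained by numerically inverting the prolate-spheroid sphericity to the
#' group target, with lognormal jitter. Intensities are Gaussian: background
#' mean 100, lesion mean 160, common noise SD `intensity_noise_sd`
#' (arbitrary units).
#'
#' @param n_patients,n_converters cohort composition; `0 < n_converters <=
#'   n_patients`.
#' @param volume_mean_converter,volume_mean_nonconverter target group means
#'   of single-lesion volume (mm^3).
#' @param sphericity_target_converter,sphericity_target_nonconverter group
#'   sphericity targets in (0, 1].
#' @param lesion_count_range integer min/max of the per-patient lesion
#'   count (uniform).
#' @param grid_shape voxels per axis.
#' @param voxel_dims mm per axis.
#' @param intensity_noise_sd Gaussian noise SD (arbitrary units).
#' @param volume_range truncation bounds for single-lesion volume (mm^3).
#' @param volume_sdlog lognormal shape parameter of the volume distribution.
#' @param elongation_sdlog lognormal jitter of per-lesion elongation.
#' @param spinal_prob probability that a lesion is labelled spinal
#'   (kept low: brain-MRI realism).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 84L, n_converters = 66L,
                        volume_mean_converter = 135,
                        volume_mean_nonconverter = 71,
                        sphericity_target_converter = 0.78,
                        sphericity_target_nonconverter = 0.927,
                        lesion_count_range = c(1L, 15L),
                        grid_shape = c(96L, 96L, 64L),
                        voxel_dims = c(1, 1, 1.5),
                        intensity_noise_sd = 10,
                        volume_range = c(22, 671),
                        volume_sdlog = 0.6,
                        elongation_sdlog = 0.15,
                        spinal_prob = 0.02,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_converters = as.integer(n_converters),
               volume_mean_converter = as.numeric(volume_mean_converter),
               volume_mean_nonconverter = as.numeric(volume_mean_nonconverter),
               sphericity_target_converter = as.numeric(sphericity_target_converter),
               sphericity_target_nonconverter = as.numeric(sphericity_target_nonconverter),
               lesion_count_range = as.integer(lesion_count_range),
               grid_shape = as.integer(grid_shape),
               voxel_dims = as.numeric(voxel_dims),
               intensity_noise_sd = as.numeric(intensity_noise_sd),
               volume_range = as.numeric(volume_range),
               volume_sdlog = as.numeric(volume_sdlog),
               elongation_sdlog = as.numeric(elongation_sdlog),
               spinal_prob = as.numeric(spinal_prob),
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  stopifnot(s$n_patients >= 1L, s$n_converters >= 1L)
  if (s$n_converters > s$n_patients)
    stop("n_converters must not exceed n_patients")
  if (s$volume_mean_converter <= 0 || s$volume_mean_nonconverter <= 0)
    stop("volume means must be positive")
  for (t in c(s$sphericity_target_converter, s$sphericity_target_nonconverter))
    if (t <= 0 || t > 1) stop("sphericity targets must lie in (0, 1]")
  if (length(s$lesion_count_range) != 2L || s$lesion_count_range[1] < 1L ||
      diff(s$lesion_count_range) < 0L)
    stop("lesion_count_range must be an increasing pair of positive integers")
  if (length(s$grid_shape) != 3L || any(s$grid_shape < 16L))
    stop("grid_shape must be 3 axis lengths of at least 16 voxels")
  if (length(s$voxel_dims) != 3L || any(s$voxel_dims <= 0))
    stop("voxel_dims must be 3 positive lengths (mm)")
  vox <- prod(s$voxel_dims)
  if (min(s$volume_range) < vox)
    stop(sprintf("lesion volume target (%.2f mm^3) is smaller than one voxel (%.2f mm^3)",
                 min(s$volume_range), vox))
  invisible(TRUE)
}

# ---- shape helpers ---------------------------------------------------------

# analytic Wadell sphericity of a prolate spheroid with axis ratio e >= 1
prolate_sphericity <- function(e) {
  if (e <= 1 + 1e-12) return(1)
  a <- 1; c <- e
  ecc <- sqrt(1 - (a / c)^2)
  V <- 4 / 3 * pi * a^2 * c
  A <- 2 * pi * a^2 * (1 + (c / (a * ecc)) * asin(ecc))
  (36 * pi * V^2)^(1 / 3) / A
}

# invert prolate sphericity: target in (0, 1] -> elongation >= 1
elongation_for_sphericity <- function(target) {
  if (target >= 1) return(1)
  stats::uniroot(function(e) prolate_sphericity(e) - target,
                 interval = c(1 + 1e-9, 200), tol = 1e-10)$root
}

# mean of a lognormal(mu, s) truncated to [a, b]
trunc_lnorm_mean <- function(mu, s, a, b) {
  za <- (log(a) - mu) / s
  zb <- (log(b) - mu) / s
  denom <- pnorm(zb) - pnorm(za)
  exp(mu + s^2 / 2) * (pnorm(zb - s) - pnorm(za - s)) / denom
}

# solve for mu so the truncated-lognormal mean equals the target
calibrate_volume_meanlog <- function(target, s, a, b) {
  if (target <= a || target >= b)
    stop("volume mean target must lie strictly inside volume_range")
  stats::uniroot(function(mu) trunc_lnorm_mean(mu, s, a, b) - target,
                 interval = log(target) + c(-4, 4), tol = 1e-9)$root
}

r_trunc_lnorm <- function(n, mu, s, a, b) {
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    x <- rlnorm(n - got, mu, s)
    x <- x[x >= a & x <= b]
    if (length(x)) {
      out[(got + 1L):(got + length(x))] <- x
      got <- got + length(x)
    }
  }
  out
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

# orthonormal basis with u1 = first column
orthobasis <- function(u1) {
  ref <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- ref - sum(ref * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  cbind(u1, u2, u3)
}

# rasterize an ellipsoid into voxel coordinates; returns an n x 3 integer
# matrix of voxel indices (1-based), or errors if out of bounds
rasterize_indices <- function(volume_target, elongation, orientation, center,
                              grid_shape, voxel_dims, jitter = TRUE,
                              lesion_name = "lesion") {
  stopifnot(elongation >= 1, volume_target > 0)
  # semi-axes (r, r, e*r) along the rotated frame, volume preserved
  r <- (3 * volume_target / (4 * pi * elongation))^(1 / 3)
  semi <- c(elongation * r, r, r)  # principal axis first (along orientation)
  R <- orthobasis(orientation / sqrt(sum(orientation^2)))
  # extent along each grid axis: |R row| weighted by semi-axes
  half_mm <- sqrt((R[, 1] * semi[1])^2 + (R[, 2] * semi[2])^2 + (R[, 3] * semi[3])^2)
  half_vox <- ceiling(half_mm / voxel_dims) + 1L
  if (any(center - half_vox < 1L) || any(center + half_vox > grid_shape))
    stop(sprintf("%s does not fit inside the grid at center (%s)",
                 lesion_name, paste(center, collapse = ", ")))
  off <- if (jitter) runif(3, -0.5, 0.5) else c(0, 0, 0)
  center_mm <- (center - 1 + off) * voxel_dims

  ax <- lapply(1:3, function(d) (center[d] - half_vox[d]):(center[d] + half_vox[d]))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  pos <- sweep(g - 1, 2, voxel_dims, "*")
  dxyz <- sweep(pos, 2, center_mm, "-")
  local <- dxyz %*% R  # coordinates in the ellipsoid frame
  q <- (local[, 1] / semi[1])^2 + (local[, 2] / semi[2])^2 + (local[, 3] / semi[3])^2
  inside <- q <= 1
  if (!any(inside)) {
    # degenerate sub-voxel lesion: keep the centre voxel
    return(matrix(as.integer(center), 1, 3))
  }
  matrix(as.integer(g[inside, , drop = FALSE]), ncol = 3)
}

#' Rasterize one ellipsoidal lesion into a binary grid
#'
#' Renders a triaxial ellipsoid of the requested volume and axis ratio
#' (elongation 1 gives a digital ball) into a binary array. The realised
#' voxel volume matches `volume_target` up to voxelization error (about one
#' voxel layer); a random sub-voxel offset of the centre (driven by `seed`)
#' removes systematic quantisation bias.
#'
#' @param volume_target lesion volume in mm^3.
#' @param elongation principal-to-transverse axis ratio, >= 1.
#' @param orientation direction of the principal axis (any nonzero 3-vector).
#' @param center voxel coordinates (1-based) of the lesion centre.
#' @param grid_shape voxels per axis of the output array.
#' @param voxel_dims voxel edge lengths in mm.
#' @param seed optional seed for the sub-voxel jitter; `NULL` leaves the RNG
#'   stream untouched and disables the jitter.
#' @return Binary 3D array of dimension `grid_shape`.
#' @export
rasterize_lesion <- function(volume_target, elongation = 1,
                             orientation = c(0, 0, 1), center,
                             grid_shape, voxel_dims = c(1, 1, 1),
                             seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  center <- as.integer(round(center))
  if (!is.null(seed)) set.seed(as.integer(seed))
  vx <- rasterize_indices(volume_target, elongation, orientation, center,
                          grid_shape, voxel_dims, jitter = !is.null(seed))
  out <- array(0L, grid_shape)
  out[vx] <- 1L
  out
}

# location label from the lesion centre: inferior slab -> infratentorial,
# central box -> periventricular (ventricle proxy), outer shell ->
# juxtacortical; a small fraction is relabelled spinal
region_label <- function(center, grid_shape, spinal_prob) {
  if (runif(1) < spinal_prob) return("spinal")
  if (center[3] <= 0.2 * grid_shape[3]) return("infratentorial")
  cx <- (grid_shape[1] + 1) / 2
  cy <- (grid_shape[2] + 1) / 2
  rho <- max(abs(center[1] - cx) / (grid_shape[1] / 2),
             abs(center[2] - cy) / (grid_shape[2] / 2))
  if (rho <= 0.45) "periventricular" else "juxtacortical"
}

#' Generate a synthetic CIS cohort
#'
#' Draws a full cohort of patients from a [cohort_spec()]: per patient a
#' binary lesion mask, a FLAIR-like intensity volume (lesions hyperintense
#' over a noisy background), per-lesion anatomical location labels for the
#' dissemination-in-space rule, and the conversion outcome. Converter
#' lesions are drawn larger and more elongated than non-converter lesions.
#' Lesions are placed with at least 2 voxels of clearance from the grid
#' boundary and are mutually disjoint (no two components merge).
#'
#' The cohort is a pure function of the spec (which includes the seed):
#' calling twice with the same spec gives bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional override of `spec$seed`.
#' @return An object of class `lesion_cohort`: list with `patients` (each a
#'   `patient_record` with `patient_id`, `intensity` ([labeled_volume()]),
#'   `mask`, `lesions` data.frame of lesion_id/location, `converted`), the
#'   `spec`, and `table` (the cohort CSV as a data.frame: patient_id,
#'   converted, lesion_id, location).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  set.seed(spec$seed)

  a <- spec$volume_range[1]; b <- spec$volume_range[2]; s <- spec$volume_sdlog
  mu_conv <- calibrate_volume_meanlog(spec$volume_mean_converter, s, a, b)
  mu_non <- calibrate_volume_meanlog(spec$volume_mean_nonconverter, s, a, b)
  e_conv <- elongation_for_sphericity(spec$sphericity_target_converter)
  e_non <- elongation_for_sphericity(spec$sphericity_target_nonconverter)

  gs <- spec$grid_shape; vd <- spec$voxel_dims
  n_vox <- prod(gs)
  patients <- vector("list", spec$n_patients)
  rows <- list()

  pick1 <- function(x) x[sample.int(length(x), 1L)]

  for (i in seq_len(spec$n_patients)) {
    converted <- i <= spec$n_converters
    pid <- sprintf("P%03d", i)
    mu <- if (converted) mu_conv else mu_non
    e_base <- if (converted) e_conv else e_non
    n_les <- pick1(seq(spec$lesion_count_range[1], spec$lesion_count_range[2]))

    mask <- array(0L, gs)
    placed_vx <- list()
    placed_loc <- character(0)
    for (k in seq_len(n_les)) {
      V <- r_trunc_lnorm(1L, mu, s, a, b)
      e <- max(1, e_base * exp(rnorm(1, 0, spec$elongation_sdlog)))
      u <- random_unit_vector()
      r <- (3 * V / (4 * pi * e))^(1 / 3)
      half_mm <- e * r
      half_vox <- ceiling(half_mm / vd) + 2L  # >= 2 voxels off the boundary
      if (any(1L + half_vox > gs - half_vox))
        stop(sprintf("%s lesion %d (%.0f mm^3, elongation %.1f) cannot fit inside the grid",
                     pid, k, V, e))
      ok <- FALSE
      for (try in 1:100) {
        center <- vapply(1:3, function(d)
          pick1(seq(1L + half_vox[d], gs[d] - half_vox[d])), 0L)
        vx <- rasterize_indices(V, e, u, center, gs, vd, jitter = TRUE,
                                lesion_name = sprintf("%s lesion %d", pid, k))
        # keep components disjoint: demand an empty 1-voxel margin around
        # the new lesion's bounding box
        lo <- pmax(apply(vx, 2, min) - 1L, 1L)
        hi <- pmin(apply(vx, 2, max) + 1L, gs)
        if (sum(mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) == 0L) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next  # grid too crowded for this lesion; skip it
      mask[vx] <- 1L
      placed_vx[[length(placed_vx) + 1L]] <- vx
      placed_loc <- c(placed_loc, region_label(center, gs, spec$spinal_prob))
    }

    # id lesions in the same (min z, min y, min x) order the extractor uses,
    # so location labels line up with extracted lesion ids
    if (length(placed_vx)) {
      keys <- t(vapply(placed_vx, function(vx)
        c(min(vx[, 3]), min(vx[, 2]), min(vx[, 1])), numeric(3)))
      ord <- order(keys[, 1], keys[, 2], keys[, 3])
      les_rows <- data.frame(
        lesion_id = sprintf("L%03d", seq_along(ord)),
        location = placed_loc[ord],
        stringsAsFactors = FALSE)
    } else {
      les_rows <- data.frame(lesion_id = character(0), location = character(0),
                             stringsAsFactors = FALSE)
    }

    intensity <- array(rnorm(n_vox, 100, spec$intensity_noise_sd), gs)
    in_mask <- which(mask == 1L)
    intensity[in_mask] <- rnorm(length(in_mask), 160, spec$intensity_noise_sd)

    patients[[i]] <- structure(list(
      patient_id = pid,
      intensity = labeled_volume(intensity, vd),
      mask = mask,
      lesions = les_rows,
      converted = converted), class = "patient_record")
    rows[[i]] <- if (nrow(les_rows) > 0) {
      data.frame(patient_id = pid,
                 converted = as.integer(converted),
                 lesion_id = les_rows$lesion_id,
                 location = les_rows$location,
                 stringsAsFactors = FALSE)
    } else {
      # lesion-free patient: keep one row so the patient stays in the table
      data.frame(patient_id = pid, converted = as.integer(converted),
                 lesion_id = NA_character_, location = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }

  structure(list(patients = patients, spec = spec,
                 table = do.call(rbind, rows)),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  conv <- sum(vapply(x$patients, `[[`, TRUE, "converted"))
  cat("<lesion_cohort> ", length(x$patients), " patients (", conv,
      " converters), grid ", paste(x$spec$grid_shape, collapse = "x"),
      " @ ", paste(x$spec$voxel_dims, collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk as NIfTI pairs plus a cohort table
#'
#' Writes `<id>_flair.nii.gz` and `<id>_mask.nii.gz` per patient (voxel
#' dimensions in the NIfTI header) and `cohort.csv` with columns
#' patient_id, converted, lesion_id, location.
#'
#' @param cohort a `lesion_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    img <- RNifti::asNifti(p$intensity$data)
    RNifti::pixdim(img) <- p$intensity$voxel_dims
    RNifti::writeNifti(img, file.path(dir, paste0(p$patient_id, "_flair.nii.gz")))
    msk <- RNifti::asNifti(p$mask)
    RNifti::pixdim(msk) <- p$intensity$voxel_dims
    RNifti::writeNifti(msk, file.path(dir, paste0(p$patient_id, "_mask.nii.gz")))
  }
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `cohort.csv` and per-patient NIfTI pairs.
#' @return A list of patient records (patient_id, intensity, mask,
#'   converted, lesions data.frame), plus the cohort table as attribute
#'   `"table"`.
#' @export
read_cohort <- function(dir) {
  tab_path <- file.path(dir, "cohort.csv")
  if (!file.exists(tab_path)) stop("no cohort.csv in ", dir)
  tab <- read.csv(tab_path, stringsAsFactors = FALSE)
  ids <- unique(tab$patient_id)
  patients <- lapply(ids, function(pid) {
    fpath <- file.path(dir, paste0(pid, "_flair.nii.gz"))
    mpath <- file.path(dir, paste0(pid, "_mask.nii.gz"))
    if (!file.exists(mpath)) stop("missing mask file for patient ", pid)
    if (!file.exists(fpath)) stop("missing image file for patient ", pid)
    img <- RNifti::readNifti(fpath)
    msk <- RNifti::readNifti(mpath)
    vd <- RNifti::pixdim(img)[1:3]
    sub <- tab[tab$patient_id == pid, , drop = FALSE]
    les <- sub[!is.na(sub$lesion_id), , drop = FALSE]
    structure(list(patient_id = pid,
                   intensity = labeled_volume(array(as.numeric(img), dim(img)), vd),
                   mask = array(as.integer(msk != 0), dim(msk)),
                   lesions = data.frame(lesion_id = les$lesion_id,
                                        location = les$location,
                                        stringsAsFactors = FALSE),
                   converted = as.logical(sub$converted[1])),
              class = "patient_record")
  })
  attr(patients, "table") <- tab
  patients
}

#' Per-lesion feature table for a whole cohort
#'
#' Runs the feature extraction over every patient of a cohort (in memory or
#' read from disk) and stitches location labels onto the extracted lesions
#' (both are ordered by the lesion's minimal (z, y, x) corner only when the
#' mask was generated by this package; otherwise labels are joined by
#' lesion_id).
#'
#' @param cohort a `lesion_cohort` or the list returned by [read_cohort()].
#' @inheritParams lesion_features
#' @return A data.frame, one row per lesion, as in [lesion_features()], plus
#'   a `converted` column.
#' @export
cohort_features <- function(cohort, min_volume = 0, bins = 64L) {
  patients <- if (inherits(cohort, "lesion_cohort")) cohort$patients else cohort
  out <- lapply(patients, function(p) {
    df <- lesion_features(p$mask, p$intensity, p$intensity$voxel_dims,
                          patient_id = p$patient_id, min_volume = min_volume,
                          bins = bins)
    if (nrow(df) > 0) {
      df$location <- p$lesions$location[match(df$lesion_id, p$lesions$lesion_id)]
      df$converted <- as.integer(p$converted)
    }
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
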