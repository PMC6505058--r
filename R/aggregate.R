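# Collapse variable-length per-lesion feature lists into the fixed-length
# per-patient vectors the classifier needs. For every base feature the
# minimum, maximum, mean and (population) standard deviation over a
# patient's lesions are kept, so lesion heterogeneity is not averaged away;
# total lesion volume and lesion count are appended to every feature set.

SHAPE_FEATURES <- c(volume = "V_mm3", surface_area = "A_mm2",
                    sphericity = "sphericity", svr = "SVR")
INTENSITY_FEATURES <- c(skewness = "skewness", kurtosis = "kurtosis",
                        entropy = "entropy_bits")

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

feature_set_columns <- function(feature_set) {
  base <- switch(feature_set,
                 shape = SHAPE_FEATURES,
                 intensity = INTENSITY_FEATURES,
                 combined = c(SHAPE_FEATURES, INTENSITY_FEATURES),
                 stop("feature_set must be one of 'shape', 'intensity', 'combined'"))
  stats <- c("min", "max", "mean", "std")
  cols <- as.vector(t(outer(names(base), stats, paste, sep = "_")))
  list(base = base, columns = c(cols, "total_lesion_volume", "lesion_count"))
}

#' Aggregate one patient's lesions into a fixed-length feature vector
#'
#' @param lesions data.frame of per-lesion features for one patient (as
#'   produced by [lesion_features()]); may have zero rows.
#' @param feature_set `"shape"` (volume, surface area, sphericity, SVR; 18
#'   values), `"intensity"` (skewness, kurtosis, entropy; 14 values) or
#'   `"combined"` (30 values). Total lesion volume and lesion count are part
#'   of every set.
#' @param allow_empty if TRUE a patient without lesions yields a zero vector
#'   with `lesion_count = 0`; otherwise an error.
#' @return Named numeric vector; the layout is constant within a feature
#'   set (per base feature: `_min`, `_max`, `_mean`, `_std`, then
#'   `total_lesion_volume` and `lesion_count`).
#' @export
aggregate_patient <- function(lesions,
                              feature_set = c("shape", "intensity", "combined"),
                              allow_empty = FALSE) {
  feature_set <- match.arg(feature_set)
  fs <- feature_set_columns(feature_set)
  if (nrow(lesions) == 0L) {
    if (!allow_empty)
      stop("patient has no lesions; set allow_empty = TRUE to impute zeros")
    out <- stats::setNames(numeric(length(fs$columns)), fs$columns)
    return(out)
  }
  vals <- numeric(0)
  for (nm in names(fs$base)) {
    x <- lesions[[fs$base[[nm]]]]
    if (anyNA(x)) stop("missing values in per-lesion feature ", fs$base[[nm]])
    vals <- c(vals, min(x), max(x), mean(x), pop_sd(x))
  }
  vals <- c(vals, sum(lesions$V_mm3), nrow(lesions))
  stats::setNames(vals, fs$columns)
}

#' Aggregate a per-lesion feature table into a per-patient feature matrix
#'
#' @param lesion_table data.frame of per-lesion features for many patients
#'   (as produced by [cohort_features()]).
#' @param feature_set see [aggregate_patient()].
#' @param patient_ids optional vector of patient ids defining the row order
#'   and including patients without lesions (imputed as zero vectors).
#' @return data.frame with `patient_id` followed by the feature columns.
#' @export
aggregate_cohort <- function(lesion_table,
                             feature_set = c("shape", "intensity", "combined"),
                             patient_ids = NULL) {
  feature_set <- match.arg(feature_set)
  if (is.null(patient_ids)) patient_ids <- unique(lesion_table$patient_id)
  rows <- lapply(patient_ids, function(pid) {
    sub <- lesion_table[lesion_table$patient_id == pid, , drop = FALSE]
    aggregate_patient(sub, feature_set, allow_empty = TRUE)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(patient_id = patient_ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
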