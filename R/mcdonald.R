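# McDonald-2010 dissemination-in-space (DIS) benchmark: at baseline, only
# DIS can be assessed, and a DIS-positive scan is predicted to convert.
# DIS holds when lesions involve at least 2 of the 4 characteristic CNS
# areas: periventricular, juxtacortical, infratentorial, spinal cord.

#' Assess dissemination in space from lesion location labels
#'
#' @param lesion_locations character vector of per-lesion location labels
#'   from the closed vocabulary periventricular / juxtacortical /
#'   infratentorial / spinal; may be empty.
#' @param patient_id optional id carried into the result.
#' @return An object of class `dis_assessment`: `areas_involved` (distinct
#'   areas with at least one lesion), `dis_positive` (>= 2 areas), and
#'   `predicted_label` (`"conversion"` iff DIS-positive).
#' @export
assess_dis <- function(lesion_locations, patient_id = NA_character_) {
  lesion_locations <- lesion_locations[!is.na(lesion_locations)]
  bad <- setdiff(unique(lesion_locations), DIS_AREAS)
  if (length(bad))
    stop("unknown location label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(DIS_AREAS, collapse = ", "))
  areas <- intersect(DIS_AREAS, unique(lesion_locations))
  positive <- length(areas) >= 2L
  structure(list(patient_id = patient_id,
                 areas_involved = areas,
                 dis_positive = positive,
                 predicted_label = if (positive) "conversion" else "non-conversion"),
            class = "dis_assessment")
}

#' @export
print.dis_assessment <- function(x, ...) {
  cat("<dis_assessment> ", if (is.na(x$patient_id)) "" else paste0(x$patient_id, ": "),
      length(x$areas_involved), " area(s) [",
      paste(x$areas_involved, collapse = ", "), "] -> ",
      x$predicted_label, "\n", sep = "")
  invisible(x)
}

#' DIS-rule predictions for a cohort table
#'
#' @param cohort_table data.frame with columns `patient_id` and `location`
#'   (one row per lesion), e.g. the `table` element of [generate_cohort()]
#'   or a read `cohort.csv`.
#' @return data.frame with one row per patient: patient_id, n_areas,
#'   dis_positive, predicted (1 = conversion).
#' @export
dis_predict <- function(cohort_table) {
  ids <- unique(cohort_table$patient_id)
  rows <- lapply(ids, function(pid) {
    locs <- cohort_table$location[cohort_table$patient_id == pid]
    a <- assess_dis(locs, pid)
    data.frame(patient_id = pid, n_areas = length(a$areas_involved),
               dis_positive = a$dis_positive,
               predicted = as.integer(a$dis_positive),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
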