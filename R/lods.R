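# Logistic Organ Dysfunction System (LODS) scoring.
#
# Six organ systems are scored from the worst value observed in the first
# 24 h of the ICU stay; each system contributes the maximum severity
# triggered by any of its variables, and the total is the sum across
# systems (range 0-22).  The neurological component (GCS) can be excluded
# to isolate extracerebral organ dysfunction (range 0-17).

#' Score the neurological system (Glasgow Coma Scale)
#'
#' @param gcs_min Lowest GCS in the first 24 h (integer 3-15).
#' @return Integer points in \{0, 1, 3, 5\}: GCS 3-5 scores 5, 6-8 scores 3,
#'   9-13 scores 1, 14-15 scores 0.
#' @examples
#' score_neurologic(15) # 0
#' score_neurologic(3)  # 5
#' @export
score_neurologic <- function(gcs_min) {
  .check_numeric(gcs_min, "gcs_min")
  if (any(gcs_min < 3 | gcs_min > 15)) {
    stop("gcs_min out of range [3, 15]", call. = FALSE)
  }
  ifelse(gcs_min <= 5, 5L, ifelse(gcs_min <= 8, 3L, ifelse(gcs_min <= 13, 1L, 0L)))
}

#' Score the cardiovascular system (heart rate and systolic blood pressure)
#'
#' The component takes the maximum severity triggered by any extreme:
#' 5 points for heart rate < 30/min or SBP < 40 mmHg; 3 for SBP 40-69 or
#' SBP >= 270; 1 for SBP 70-89, heart rate >= 140 or SBP 240-269; else 0.
#'
#' @param hr_min,hr_max Lowest and highest heart rate (beats/min).
#' @param sbp_min,sbp_max Lowest and highest systolic blood pressure (mmHg).
#' @return Integer points in \{0, 1, 3, 5\}.
#' @export
score_cardiovascular <- function(hr_min, hr_max, sbp_min, sbp_max) {
  .check_numeric(hr_min, "hr_min"); .check_numeric(hr_max, "hr_max")
  .check_numeric(sbp_min, "sbp_min"); .check_numeric(sbp_max, "sbp_max")
  if (any(hr_min < 0) || any(hr_max < 0) || any(sbp_min < 0) || any(sbp_max < 0)) {
    stop("heart rate and blood pressure must be non-negative", call. = FALSE)
  }
  if (any(hr_min > hr_max)) stop("hr_min exceeds hr_max", call. = FALSE)
  if (any(sbp_min > sbp_max)) stop("sbp_min exceeds sbp_max", call. = FALSE)
  pts <- integer(length(hr_min))
  pts <- pmax(pts, ifelse(sbp_min < 90, 1L, 0L))
  pts <- pmax(pts, ifelse(hr_max >= 140, 1L, 0L))
  pts <- pmax(pts, ifelse(sbp_max >= 240 & sbp_max < 270, 1L, 0L))
  pts <- pmax(pts, ifelse(sbp_min < 70, 3L, 0L))
  pts <- pmax(pts, ifelse(sbp_max >= 270, 3L, 0L))
  pts <- pmax(pts, ifelse(hr_min < 30 | sbp_min < 40, 5L, 0L))
  as.integer(pts)
}

#' Score the renal system (urea, creatinine, urine output)
#'
#' Maximum severity over: serum urea nitrogen (mmol/L: >= 20 scores 5,
#' 10-19.9 scores 3, 6-9.9 scores 1), creatinine (mg/dL: >= 1.60 scores 3,
#' 1.20-1.59 scores 1) and 24-h urine output (L: < 0.5 scores 5, 0.5-0.74
#' scores 3, >= 10 scores 3).
#'
#' @param urea_max Highest urea nitrogen (mmol/L).
#' @param creatinine_max Highest creatinine (mg/dL).
#' @param urine_24h 24-hour urine output (L).
#' @return Integer points in \{0, 1, 3, 5\}.
#' @export
score_renal <- function(urea_max, creatinine_max, urine_24h) {
  .check_numeric(urea_max, "urea_max")
  .check_numeric(creatinine_max, "creatinine_max")
  .check_numeric(urine_24h, "urine_24h")
  if (any(urea_max < 0) || any(creatinine_max < 0) || any(urine_24h < 0)) {
    stop("renal variables must be non-negative", call. = FALSE)
  }
  urea_pts <- ifelse(urea_max >= 20, 5L,
              ifelse(urea_max >= 10, 3L,
              ifelse(urea_max >= 6, 1L, 0L)))
  creat_pts <- ifelse(creatinine_max >= 1.60, 3L,
               ifelse(creatinine_max >= 1.20, 1L, 0L))
  urine_pts <- ifelse(urine_24h < 0.5, 5L,
               ifelse(urine_24h < 0.75, 3L,
               ifelse(urine_24h >= 10, 3L, 0L)))
  as.integer(pmax(urea_pts, creat_pts, urine_pts))
}

#' Score the pulmonary system (PaO2/FiO2 under ventilation or CPAP)
#'
#' Patients neither ventilated nor on CPAP score 0.  Ventilated patients
#' score 1 when PaO2/FiO2 >= 150 mmHg (>= 19.9 kPa) and 3 below that.
#'
#' @param ventilated_or_cpap Logical: mechanical ventilation or CPAP in the
#'   first 24 h.
#' @param pao2_fio2 PaO2/FiO2 ratio; required when ventilated.
#' @param unit Unit of the ratio, `"mmHg"` (default) or `"kPa"`.
#' @return Integer points in \{0, 1, 3\}.
#' @export
score_pulmonary <- function(ventilated_or_cpap, pao2_fio2 = NA_real_,
                            unit = "mmHg") {
  if (any(is.na(ventilated_or_cpap))) {
    stop("ventilated_or_cpap must not contain missing values", call. = FALSE)
  }
  vent <- as.logical(ventilated_or_cpap)
  n <- length(vent)
  pao2_fio2 <- rep_len(pao2_fio2, n)
  unit <- rep_len(unit, n)
  if (!all(unit %in% c("mmHg", "kPa"))) {
    stop("pao2_fio2 unit must be 'mmHg' or 'kPa'", call. = FALSE)
  }
  if (any(vent & is.na(pao2_fio2))) {
    stop("pao2_fio2 missing for a ventilated/CPAP patient", call. = FALSE)
  }
  if (any(vent & pao2_fio2 < 0)) {
    stop("pao2_fio2 must be non-negative", call. = FALSE)
  }
  threshold <- ifelse(unit == "kPa", 19.9, 150)
  as.integer(ifelse(!vent, 0L, ifelse(pao2_fio2 >= threshold, 1L, 3L)))
}

#' Score the hematologic system (leucocytes and platelets)
#'
#' Maximum severity over: leucocyte count (x10^9/L: minimum < 1.0 scores 3,
#' minimum 1.0-2.4 scores 1, maximum >= 50 scores 1) and platelet count
#' (x10^9/L: minimum < 50 scores 1).
#'
#' @param wbc_min,wbc_max Lowest and highest leucocyte count (x10^9/L).
#' @param platelets_min Lowest platelet count (x10^9/L).
#' @return Integer points in \{0, 1, 3\}.
#' @export
score_hematologic <- function(wbc_min, wbc_max, platelets_min) {
  .check_numeric(wbc_min, "wbc_min"); .check_numeric(wbc_max, "wbc_max")
  .check_numeric(platelets_min, "platelets_min")
  if (any(wbc_min < 0) || any(wbc_max < 0) || any(platelets_min < 0)) {
    stop("hematologic variables must be non-negative", call. = FALSE)
  }
  if (any(wbc_min > wbc_max)) stop("wbc_min exceeds wbc_max", call. = FALSE)
  wbc_pts <- ifelse(wbc_min < 1.0, 3L,
             ifelse(wbc_min < 2.5, 1L,
             ifelse(wbc_max >= 50, 1L, 0L)))
  plt_pts <- ifelse(platelets_min < 50, 1L, 0L)
  as.integer(pmax(wbc_pts, plt_pts))
}

#' Score the hepatic system (bilirubin and prothrombin time)
#'
#' @param bilirubin_max Highest bilirubin (mg/dL).
#' @param pt_excess_sec Prothrombin time, seconds above control.
#' @return Integer points in \{0, 1\}: 1 when bilirubin >= 2.0 mg/dL or
#'   PT > 3 s above control.
#' @export
score_hepatic <- function(bilirubin_max, pt_excess_sec) {
  .check_numeric(bilirubin_max, "bilirubin_max")
  .check_numeric(pt_excess_sec, "pt_excess_sec")
  if (any(bilirubin_max < 0)) {
    stop("bilirubin_max must be non-negative", call. = FALSE)
  }
  as.integer(ifelse(bilirubin_max >= 2.0 | pt_excess_sec > 3, 1L, 0L))
}

# Observation fields the scorer understands, with the "normal" value a
# missing field is imputed to (missing data are treated as physiologically
# normal but recorded in lods_missing).
.lods_fields <- function() {
  list(
    gcs_min = 15, hr_min = 80, hr_max = 80, sbp_min = 120, sbp_max = 120,
    urea_max = 5, creatinine_max = 1.0, urine_24h = 1.5,
    ventilated_or_cpap = FALSE, pao2_fio2 = NA_real_,
    wbc_min = 8, wbc_max = 8, platelets_min = 250,
    bilirubin_max = 0.5, pt_excess_sec = 0
  )
}

#' Compute the LODS breakdown for one or more patients
#'
#' Scores each of the six organ systems from worst first-24-hour values and
#' returns the per-system points together with the total (0-22) and the
#' total excluding the GCS component (0-17).  A missing variable is treated
#' as normal (contributes 0 points) and its name is recorded in the
#' `lods_missing` column; a patient with every variable missing is an error.
#'
#' @param obs A data frame with (a subset of) the columns `gcs_min`,
#'   `hr_min`, `hr_max`, `sbp_min`, `sbp_max`, `urea_max`, `creatinine_max`,
#'   `urine_24h`, `ventilated_or_cpap`, `pao2_fio2`, `pao2_fio2_unit`,
#'   `wbc_min`, `wbc_max`, `platelets_min`, `bilirubin_max`,
#'   `pt_excess_sec`; or a named list for a single patient.
#' @param include_gcs Logical; when `FALSE` the headline `lods` column is
#'   the GCS-free total, otherwise the full total.
#' @return A data frame with one row per patient: the six system scores,
#'   `lods_total`, `lods_without_gcs`, the headline `lods`, and
#'   `lods_missing` (semicolon-separated names of imputed fields).
#' @examples
#' compute_lods(list(gcs_min = 7, urea_max = 25,
#'                   ventilated_or_cpap = TRUE, pao2_fio2 = 100))
#' @export
compute_lods <- function(obs, include_gcs = TRUE) {
  if (!is.data.frame(obs)) obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  fields <- .lods_fields()
  known <- c(names(fields), "pao2_fio2_unit")
  present <- intersect(names(obs), known)
  if (length(present) == 0) {
    stop("no LODS observation columns found", call. = FALSE)
  }
  n <- nrow(obs)
  # missing map per field (absent column == all missing)
  miss <- sapply(names(fields), function(f) {
    if (f %in% names(obs)) is.na(obs[[f]]) else rep(TRUE, n)
  })
  if (n == 1) miss <- matrix(miss, nrow = 1, dimnames = list(NULL, names(fields)))
  # pao2_fio2 only counts as missing when the patient is ventilated
  vent_known <- if ("ventilated_or_cpap" %in% names(obs)) {
    !is.na(obs$ventilated_or_cpap) & as.logical(obs$ventilated_or_cpap)
  } else rep(FALSE, n)
  miss[, "pao2_fio2"] <- miss[, "pao2_fio2"] & vent_known
  core <- setdiff(names(fields), "pao2_fio2")
  all_missing <- rowSums(!miss[, core, drop = FALSE]) == 0
  if (any(all_missing)) {
    stop("patient row(s) ", paste(which(all_missing), collapse = ", "),
         ": every LODS variable is missing; nothing to score", call. = FALSE)
  }
  # impute normals
  val <- lapply(names(fields), function(f) {
    x <- if (f %in% names(obs)) obs[[f]] else rep(NA, n)
    x[is.na(x)] <- fields[[f]]
    x
  })
  names(val) <- names(fields)
  # an imputed extreme must stay consistent with an observed partner
  for (pair in list(c("hr_min", "hr_max"), c("sbp_min", "sbp_max"),
                    c("wbc_min", "wbc_max"))) {
    lo <- pair[1]; hi <- pair[2]
    val[[lo]] <- ifelse(miss[, lo], pmin(val[[lo]], val[[hi]]), val[[lo]])
    val[[hi]] <- ifelse(miss[, hi], pmax(val[[lo]], val[[hi]]), val[[hi]])
  }
  unit <- if ("pao2_fio2_unit" %in% names(obs)) {
    u <- as.character(obs$pao2_fio2_unit)
    u[is.na(u) | u == ""] <- "mmHg"
    u
  } else "mmHg"
  neurologic <- score_neurologic(val$gcs_min)
  cardiovascular <- score_cardiovascular(val$hr_min, val$hr_max,
                                         val$sbp_min, val$sbp_max)
  renal <- score_renal(val$urea_max, val$creatinine_max, val$urine_24h)
  pulmonary <- score_pulmonary(as.logical(val$ventilated_or_cpap),
                               val$pao2_fio2, unit)
  hematologic <- score_hematologic(val$wbc_min, val$wbc_max, val$platelets_min)
  hepatic <- score_hepatic(val$bilirubin_max, val$pt_excess_sec)
  total <- neurologic + cardiovascular + renal + pulmonary + hematologic + hepatic
  missing_fields <- apply(miss, 1, function(m) {
    paste(names(fields)[m], collapse = ";")
  })
  out <- data.frame(
    neurologic = neurologic, cardiovascular = cardiovascular, renal = renal,
    pulmonary = pulmonary, hematologic = hematologic, hepatic = hepatic,
    lods_total = as.integer(total),
    lods_without_gcs = as.integer(total - neurologic),
    stringsAsFactors = FALSE
  )
  out$lods <- if (include_gcs) out$lods_total else out$lods_without_gcs
  out$lods_missing <- missing_fields
  out
}

.check_numeric <- function(x, name) {
  if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
  if (any(is.na(x))) stop(name, " must not contain missing values", call. = FALSE)
  invisible(TRUE)
}
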