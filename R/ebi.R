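# Composite early-brain-injury (EBI) grading.
#
# The grade (1-5) sums one point for persistent loss of consciousness, one
# point for global cerebral edema, and 1-3 points from the total
# intracranial blood burden: Hijdra cisternal score (0-30) + Le Roux
# intraventricular score (0-16) + intraparenchymal hematoma points (0-3
# from the ABC/2 volume).  Burden 0-19 is low (1 point), 20-29 moderate
# (2 points), 30-49 high (3 points); grade >= 3 is severe EBI.

#' Hijdra cisternal blood score
#'
#' Sum of blood grades over the ten basal cisterns and fissures, each
#' graded 0 (no blood) to 3 (completely filled).
#'
#' @param cistern_grades An integer vector of length 10, or an n x 10
#'   matrix/data frame (one row per patient), values in 0-3.
#' @return Integer score(s) in 0-30.
#' @export
hijdra_cisternal <- function(cistern_grades) {
  .sum_grades(cistern_grades, n_slots = 10, max_grade = 3,
              what = "cisternal grade")
}

#' Le Roux intraventricular blood score
#'
#' Sum of blood grades over the four ventricles, each graded 0 (no blood)
#' to 4 (ventricle filled and expanded).
#'
#' @param ventricle_grades An integer vector of length 4, or an n x 4
#'   matrix/data frame, values in 0-4.
#' @return Integer score(s) in 0-16.
#' @export
leroux <- function(ventricle_grades) {
  .sum_grades(ventricle_grades, n_slots = 4, max_grade = 4,
              what = "ventricular grade")
}

.sum_grades <- function(g, n_slots, max_grade, what) {
  if (is.data.frame(g)) g <- as.matrix(g)
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  if (ncol(g) != n_slots) {
    stop("expected ", n_slots, " ", what, "s, got ", ncol(g), call. = FALSE)
  }
  bad <- which(is.na(g) | g < 0 | g > max_grade | g != round(g), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(what, " out of range {0..", max_grade, "} at position ",
         bad[1, 2], " (row ", bad[1, 1], ")", call. = FALSE)
  }
  as.integer(rowSums(g))
}

#' ABC/2 ellipsoid hematoma volume
#'
#' Approximates an intraparenchymal hematoma as an ellipsoid: the product
#' of its three orthogonal diameters divided by two (cm^3, i.e. mL).
#'
#' @param a_cm,b_cm,c_cm Orthogonal diameters in cm; all must be positive.
#' @return Volume in mL.
#' @examples
#' abc2_volume(5, 4, 3) # 30 mL
#' @export
abc2_volume <- function(a_cm, b_cm, c_cm) {
  .check_numeric(a_cm, "a_cm"); .check_numeric(b_cm, "b_cm")
  .check_numeric(c_cm, "c_cm")
  if (any(a_cm <= 0) || any(b_cm <= 0) || any(c_cm <= 0)) {
    stop("hematoma diameters must be positive", call. = FALSE)
  }
  a_cm * b_cm * c_cm / 2
}

#' Intraparenchymal hematoma points
#'
#' @param volume_ml Hematoma volume in mL; 0 encodes no hematoma.
#' @return Integer points: 0 for no hematoma, 1 for volumes under 10 mL,
#'   2 for 10-30 mL (boundaries inclusive), 3 above 30 mL.
#' @export
ich_points <- function(volume_ml) {
  .check_numeric(volume_ml, "volume_ml")
  if (any(volume_ml < 0)) stop("volume_ml must be non-negative", call. = FALSE)
  as.integer(ifelse(volume_ml == 0, 0L,
             ifelse(volume_ml < 10, 1L,
             ifelse(volume_ml <= 30, 2L, 3L))))
}

#' Total intracranial blood burden
#'
#' @param hijdra Hijdra cisternal score (0-30).
#' @param leroux Le Roux score (0-16).
#' @param ich_points Hematoma points (0-3).
#' @return Integer burden in 0-49.
#' @export
blood_burden <- function(hijdra, leroux, ich_points) {
  .check_range(hijdra, 0, 30, "hijdra")
  .check_range(leroux, 0, 16, "leroux")
  .check_range(ich_points, 0, 3, "ich_points")
  as.integer(hijdra + leroux + ich_points)
}

#' Blood-burden category points
#'
#' @param burden_total Total blood burden (0-49).
#' @return 1 for low burden (0-19), 2 for moderate (20-29), 3 for high
#'   (30-49).
#' @export
burden_category_points <- function(burden_total) {
  .check_range(burden_total, 0, 49, "burden_total")
  as.integer(ifelse(burden_total <= 19, 1L,
             ifelse(burden_total <= 29, 2L, 3L)))
}

#' Composite EBI grade
#'
#' @param loc Logical: persistent loss of consciousness on admission.
#' @param edema Logical: global cerebral edema.
#' @param burden_points Blood-burden category points (1-3).
#' @return Integer grade in 1-5: loc + edema + burden points.
#' @export
ebi_grade <- function(loc, edema, burden_points) {
  if (any(is.na(loc)) || any(is.na(edema))) {
    stop("loc and edema flags must not be missing", call. = FALSE)
  }
  .check_range(burden_points, 1, 3, "burden_points")
  as.integer(as.logical(loc) + as.logical(edema) + burden_points)
}

#' Classify an EBI grade as severe or mild
#'
#' @param grade EBI grade (1-5).
#' @return Logical: `TRUE` (severe) when grade >= 3.
#' @export
classify_ebi <- function(grade) {
  .check_range(grade, 1, 5, "grade")
  grade >= 3
}

#' Compute the full EBI assessment for a patient table
#'
#' Expects columns `cistern_1` ... `cistern_10`, `ventricle_1` ...
#' `ventricle_4`, `hematoma_a`, `hematoma_b`, `hematoma_c` (all three `NA`
#' when no hematoma is present), `loc` and `edema`.
#'
#' @param data A data frame, one row per patient.
#' @return A data frame with columns `hijdra`, `leroux`, `ich_volume_ml`,
#'   `ich_pts`, `burden_total`, `burden_points`, `ebi_grade`, `severe_ebi`.
#' @export
compute_ebi <- function(data) {
  cist_cols <- paste0("cistern_", 1:10)
  vent_cols <- paste0("ventricle_", 1:4)
  need <- c(cist_cols, vent_cols, "hematoma_a", "hematoma_b", "hematoma_c",
            "loc", "edema")
  absent <- setdiff(need, names(data))
  if (length(absent) > 0) {
    stop("missing EBI input column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  hij <- hijdra_cisternal(data[, cist_cols])
  ler <- leroux(data[, vent_cols])
  has_ich <- !is.na(data$hematoma_a)
  partial <- has_ich & (is.na(data$hematoma_b) | is.na(data$hematoma_c))
  if (any(partial | (!has_ich & (!is.na(data$hematoma_b) | !is.na(data$hematoma_c))))) {
    stop("hematoma diameters must be all present or all absent", call. = FALSE)
  }
  vol <- numeric(nrow(data))
  if (any(has_ich)) {
    vol[has_ich] <- abc2_volume(data$hematoma_a[has_ich],
                                data$hematoma_b[has_ich],
                                data$hematoma_c[has_ich])
  }
  ichp <- ich_points(vol)
  burden <- blood_burden(hij, ler, ichp)
  bp <- burden_category_points(burden)
  grade <- ebi_grade(data$loc, data$edema, bp)
  data.frame(
    hijdra = hij, leroux = ler, ich_volume_ml = vol, ich_pts = ichp,
    burden_total = burden, burden_points = bp, ebi_grade = grade,
    severe_ebi = classify_ebi(grade)
  )
}

.check_range <- function(x, lo, hi, name) {
  .check_numeric(x, name)
  if (any(x < lo | x > hi)) {
    stop(name, " out of range [", lo, ", ", hi, "]", call. = FALSE)
  }
  invisible(TRUE)
}
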