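# Charlson comorbidity index, classical (non-age-adjusted) weights.

.charlson_weights <- c(
  cm_mi = 1, cm_chf = 1, cm_pvd = 1, cm_cvd = 1, cm_dementia = 1,
  cm_copd = 1, cm_ctd = 1, cm_ulcer = 1, cm_liver_mild = 1, cm_diabetes = 1,
  cm_hemiplegia = 2, cm_renal = 2, cm_diabetes_end_organ = 2, cm_tumor = 2,
  cm_leukemia = 2, cm_lymphoma = 2,
  cm_liver_mod_severe = 3,
  cm_tumor_metastatic = 6, cm_aids = 6
)

# (mild, severe) condition pairs that cannot both be coded
.charlson_exclusive <- list(
  c("cm_liver_mild", "cm_liver_mod_severe"),
  c("cm_diabetes", "cm_diabetes_end_organ"),
  c("cm_tumor", "cm_tumor_metastatic")
)

#' Charlson condition column names
#'
#' @return Character vector of the 19 comorbidity flag columns understood
#'   by [charlson_index()]: weight-1 conditions (myocardial infarction
#'   `cm_mi`, congestive heart failure `cm_chf`, peripheral vascular
#'   disease `cm_pvd`, cerebrovascular disease `cm_cvd`, `cm_dementia`,
#'   chronic pulmonary disease `cm_copd`, connective-tissue disease
#'   `cm_ctd`, ulcer disease `cm_ulcer`, `cm_liver_mild`, `cm_diabetes`),
#'   weight-2 (`cm_hemiplegia`, moderate/severe renal disease `cm_renal`,
#'   `cm_diabetes_end_organ`, any tumor `cm_tumor`, `cm_leukemia`,
#'   `cm_lymphoma`), weight-3 (`cm_liver_mod_severe`) and weight-6
#'   (`cm_tumor_metastatic`, `cm_aids`).
#' @export
charlson_conditions <- function() names(.charlson_weights)

#' Charlson comorbidity index
#'
#' Weighted sum of chronic-condition flags with the classical weights
#' (1/2/3/6); age is not folded in, so the index can be used alongside age
#' as a separate covariate.
#'
#' @param flags A data frame (or named list/vector for one patient) of
#'   logical/0-1 columns named as in [charlson_conditions()]; absent
#'   columns are treated as all-`FALSE`.
#' @return Integer index, one per patient.
#' @examples
#' charlson_index(list(cm_tumor_metastatic = TRUE, cm_diabetes = TRUE)) # 7
#' @export
charlson_index <- function(flags) {
  if (!is.data.frame(flags)) {
    # a named list/vector describes a single patient; no entries = no
    # coded conditions
    flags <- if (length(flags) == 0) data.frame(row.names = 1)
             else as.data.frame(flags)
  }
  unknown <- setdiff(grep("^cm_", names(flags), value = TRUE),
                     names(.charlson_weights))
  if (length(unknown) > 0) {
    stop("unknown comorbidity column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(flags)
  get <- function(col) {
    if (col %in% names(flags)) {
      x <- flags[[col]]
      if (any(is.na(x))) stop(col, " contains missing values", call. = FALSE)
      as.logical(x)
    } else rep(FALSE, n)
  }
  mat <- vapply(names(.charlson_weights), get, logical(n))
  if (n == 1) mat <- matrix(mat, nrow = 1,
                            dimnames = list(NULL, names(.charlson_weights)))
  for (pair in .charlson_exclusive) {
    both <- mat[, pair[1]] & mat[, pair[2]]
    if (any(both)) {
      stop(pair[1], " and ", pair[2], " are mutually exclusive (row ",
           which(both)[1], ")", call. = FALSE)
    }
  }
  as.integer(mat %*% .charlson_weights)
}
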