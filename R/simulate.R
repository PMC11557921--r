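# Seeded synthetic aSAH cohort generator.
#
# A single latent severity trait z ~ N(0,1) per patient drives everything:
# the LODS total is assigned comonotone with z by inverse CDF on a
# configurable marginal and realized as raw physiology through a
# deterministic witness observation set (so the scorer itself reproduces
# the target); severe EBI is Bernoulli with a logistic link on z whose
# intercept and slope are solved numerically so that the prevalence and
# the tie-aware AUC of LODS against severe EBI match the configuration in
# expectation; the EBI grade, its components and the mRS outcome are drawn
# conditionally so that every scoring stage round-trips exactly.

#' Default LODS marginal distribution
#'
#' Probability vector over totals 0-22 approximating the published
#' frequency column of a 324-patient aSAH cohort (scores 1-16 observed).
#'
#' @return Numeric vector of length 23 summing to 1.
#' @export
default_lods_marginal <- function() {
  counts <- c(0, 3, 10, 26, 30, 49, 55, 48, 17, 24, 8, 39, 3, 5, 4, 0, 3,
              0, 0, 0, 0, 0, 0)
  counts / sum(counts)
}

#' Synthetic cohort configuration
#'
#' Defaults follow the published cohort this generator emulates: severe
#' EBI in 38% of patients, unfavorable outcome (mRS > 2) in 27%,
#' in-hospital mortality 6.8%, age 55.9 +/- 13.6 years, 53% clipping, and
#' a LODS marginal from the published frequency table.
#'
#' @param n Number of patients (>= 10).
#' @param auc_lods_vs_severe_ebi Target discrimination of the LODS total
#'   for severe EBI, in [0.5, 1).
#' @param prevalence_severe_ebi Fraction with EBI grade >= 3, in (0, 1).
#' @param prevalence_unfavorable Fraction with mRS > 2, in (0, 1).
#' @param mortality In-hospital mortality fraction, in (0, 1); must not
#'   exceed `prevalence_unfavorable` (death is mRS 6).
#' @param age_mean,age_sd Age distribution (years), truncated to 18-100.
#' @param female_fraction Fraction of female patients.
#' @param clipping_fraction Fraction treated by microsurgical clipping
#'   (remainder coiled).
#' @param lods_marginal Probability vector of length 23 over LODS totals
#'   0-22, summing to 1.
#' @param ebi_grade_marginal Probability vector of length 5 over EBI
#'   grades 1-5; only its within-class (mild 1-2, severe 3-5) conditional
#'   shape is used, the severe mass itself comes from
#'   `prevalence_severe_ebi`.
#' @param mrs_link_slope Slope of the latent severity trait in the ordinal
#'   mRS model; larger values couple outcome more tightly to severity.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n = 324,
                       auc_lods_vs_severe_ebi = 0.78,
                       prevalence_severe_ebi = 0.38,
                       prevalence_unfavorable = 0.27,
                       mortality = 0.068,
                       age_mean = 55.9, age_sd = 13.6,
                       female_fraction = 0.64,
                       clipping_fraction = 0.53,
                       lods_marginal = default_lods_marginal(),
                       ebi_grade_marginal = c(118, 82, 66, 45, 13) / 324,
                       mrs_link_slope = 1) {
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (auc_lods_vs_severe_ebi < 0.5 || auc_lods_vs_severe_ebi >= 1) {
    stop("auc_lods_vs_severe_ebi must be in [0.5, 1)", call. = FALSE)
  }
  for (f in c("prevalence_severe_ebi", "prevalence_unfavorable", "mortality",
              "female_fraction", "clipping_fraction")) {
    v <- get(f)
    if (v <= 0 || v >= 1) stop(f, " must be in (0, 1)", call. = FALSE)
  }
  if (mortality > prevalence_unfavorable) {
    stop("mortality cannot exceed prevalence_unfavorable", call. = FALSE)
  }
  if (length(lods_marginal) != 23 || any(lods_marginal < 0) ||
      abs(sum(lods_marginal) - 1) > 1e-9) {
    stop("lods_marginal must be 23 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (length(ebi_grade_marginal) != 5 || any(ebi_grade_marginal < 0) ||
      abs(sum(ebi_grade_marginal) - 1) > 1e-9) {
    stop("ebi_grade_marginal must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  if (age_sd <= 0) stop("age_sd must be positive", call. = FALSE)
  structure(list(
    n = as.integer(n),
    auc_lods_vs_severe_ebi = auc_lods_vs_severe_ebi,
    prevalence_severe_ebi = prevalence_severe_ebi,
    prevalence_unfavorable = prevalence_unfavorable,
    mortality = mortality,
    age_mean = age_mean, age_sd = age_sd,
    female_fraction = female_fraction,
    clipping_fraction = clipping_fraction,
    lods_marginal = lods_marginal,
    ebi_grade_marginal = ebi_grade_marginal,
    mrs_link_slope = mrs_link_slope
  ), class = "sim_config")
}

# --- witness observations --------------------------------------------------

# Raw values realizing each attainable point value, per organ system.
.witness_values <- list(
  neurologic = list(
    `0` = list(gcs_min = 15), `1` = list(gcs_min = 10),
    `3` = list(gcs_min = 7), `5` = list(gcs_min = 3)
  ),
  cardiovascular = list(
    `0` = list(hr_min = 80, hr_max = 80, sbp_min = 120, sbp_max = 120),
    `1` = list(hr_min = 80, hr_max = 80, sbp_min = 80, sbp_max = 120),
    `3` = list(hr_min = 80, hr_max = 80, sbp_min = 60, sbp_max = 120),
    `5` = list(hr_min = 80, hr_max = 80, sbp_min = 35, sbp_max = 120)
  ),
  renal = list(
    `0` = list(urea_max = 4, creatinine_max = 0.9, urine_24h = 1.5),
    `1` = list(urea_max = 7, creatinine_max = 0.9, urine_24h = 1.5),
    `3` = list(urea_max = 12, creatinine_max = 0.9, urine_24h = 1.5),
    `5` = list(urea_max = 25, creatinine_max = 0.9, urine_24h = 1.5)
  ),
  pulmonary = list(
    `0` = list(ventilated_or_cpap = FALSE, pao2_fio2 = NA_real_),
    `1` = list(ventilated_or_cpap = TRUE, pao2_fio2 = 200),
    `3` = list(ventilated_or_cpap = TRUE, pao2_fio2 = 100)
  ),
  hematologic = list(
    `0` = list(wbc_min = 8, wbc_max = 8, platelets_min = 250),
    `1` = list(wbc_min = 8, wbc_max = 8, platelets_min = 30),
    `3` = list(wbc_min = 0.5, wbc_max = 8, platelets_min = 250)
  ),
  hepatic = list(
    `0` = list(bilirubin_max = 0.8, pt_excess_sec = 1),
    `1` = list(bilirubin_max = 2.5, pt_excess_sec = 1)
  )
)

# One fixed per-system point decomposition for every total 0..22, chosen
# deterministically (first in lexicographic order over the point grid).
.witness_table <- local({
  grid <- expand.grid(
    neurologic = c(0L, 1L, 3L, 5L), cardiovascular = c(0L, 1L, 3L, 5L),
    renal = c(0L, 1L, 3L, 5L), pulmonary = c(0L, 1L, 3L),
    hematologic = c(0L, 1L, 3L), hepatic = c(0L, 1L),
    KEEP.OUT.ATTRS = FALSE
  )
  total <- rowSums(grid)
  idx <- vapply(0:22, function(k) which(total == k)[1], integer(1))
  grid[idx, , drop = FALSE]
})

#' Construct raw observations that score an exact LODS total
#'
#' For any target total 0-22, returns a full set of first-24-hour values
#' that [compute_lods()] maps back to exactly that total — a constructive
#' proof that every total is attainable, and the mechanism by which the
#' cohort generator keeps the scorer in the loop.
#'
#' @param target_lods Integer total in 0-22.
#' @return Named list of observation values (the `compute_lods` fields).
#' @examples
#' compute_lods(witness_observations(7))$lods_total # 7
#' @export
witness_observations <- function(target_lods) {
  if (length(target_lods) != 1 || is.na(target_lods) ||
      target_lods < 0 || target_lods > 22 || target_lods != round(target_lods)) {
    stop("target_lods must be a single integer in [0, 22]", call. = FALSE)
  }
  pts <- .witness_table[target_lods + 1, ]
  obs <- list()
  for (sys in names(.witness_values)) {
    obs <- c(obs, .witness_values[[sys]][[as.character(pts[[sys]])]])
  }
  obs$pao2_fio2_unit <- "mmHg"
  obs
}

# --- link calibration ------------------------------------------------------

# Solve intercept a and slope b of P(severe | z) = plogis(a + b z) so that
# the marginal prevalence matches `prev` and the tie-aware AUC of the
# (z-comonotone) discrete LODS total against severe matches `auc_target`.
# Quadrature over a fine z grid; errors when the target is infeasible
# given the ties in the LODS marginal.
.calibrate_severe_link <- function(lods_marginal, prev, auc_target,
                                   b_max = 30) {
  zg <- seq(-6, 6, length.out = 4001)
  w <- stats::dnorm(zg); w <- w / sum(w)
  breaks <- cumsum(lods_marginal)
  lev <- findInterval(stats::pnorm(zg), breaks, left.open = TRUE) + 1
  lev <- factor(lev, levels = seq_along(lods_marginal))
  a_for <- function(b) {
    stats::uniroot(function(a) sum(w * stats::plogis(a + b * zg)) - prev,
                   c(-60, 60), tol = 1e-10)$root
  }
  auc_for <- function(b) {
    a <- a_for(b)
    q <- stats::plogis(a + b * zg)
    pk <- tapply(w, lev, sum, default = 0)
    qk_num <- tapply(w * q, lev, sum, default = 0)
    pos <- qk_num / sum(qk_num)
    neg <- (pk - qk_num) / sum(pk - qk_num)
    cn <- cumsum(neg)
    sum(pos * (cn - 0.5 * neg))
  }
  if (auc_target <= 0.5 + 1e-9) {
    return(list(a = stats::qlogis(prev), b = 0))
  }
  top <- auc_for(b_max)
  if (top < auc_target) {
    stop(sprintf(paste0("infeasible calibration: the configured LODS ",
                        "marginal caps AUC at %.3f, below the target %.3f"),
                 top, auc_target), call. = FALSE)
  }
  b <- stats::uniroot(function(b) auc_for(b) - auc_target,
                      c(1e-6, b_max), tol = 1e-8)$root
  list(a = a_for(b), b = b)
}

# --- cohort generation -----------------------------------------------------

#' Generate a seeded synthetic aSAH cohort
#'
#' Produces a full raw patient table (one row per patient) in the schema
#' the scoring pipeline consumes: first-24-hour physiology, imaging blood
#' grades, hematoma diameters, consciousness/edema flags, comorbidity
#' flags, treatment, age/sex, mRS at 3 months and in-hospital death.  The
#' same seed always yields a byte-identical table.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return A data frame with `config$n` rows in the [patient_table_columns()]
#'   schema.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n
  z <- stats::rnorm(n)

  # LODS total: inverse CDF of the marginal, comonotone with z
  breaks <- cumsum(config$lods_marginal)
  lods_target <- findInterval(stats::pnorm(z), breaks, left.open = TRUE)
  wit <- do.call(rbind, lapply(0:22, function(k) {
    as.data.frame(witness_observations(k), stringsAsFactors = FALSE)
  }))
  phys <- wit[lods_target + 1, , drop = FALSE]
  rownames(phys) <- NULL

  # severe EBI via the calibrated logistic link on z
  link <- .calibrate_severe_link(config$lods_marginal,
                                 config$prevalence_severe_ebi,
                                 config$auc_lods_vs_severe_ebi)
  severe <- stats::rbinom(n, 1, stats::plogis(link$a + link$b * z)) == 1

  # EBI grade conditional on class, from the configured marginal shape
  gm <- config$ebi_grade_marginal
  p_mild <- gm[1:2] / sum(gm[1:2])
  p_sev <- gm[3:5] / sum(gm[3:5])
  grade <- integer(n)
  grade[!severe] <- sample(1:2, sum(!severe), replace = TRUE, prob = p_mild)
  grade[severe] <- sample(3:5, sum(severe), replace = TRUE, prob = p_sev)

  # decompose grade into (loc, edema, burden points), uniformly over the
  # valid lattice points
  decomp <- lapply(1:5, function(g) {
    d <- expand.grid(loc = 0:1, edema = 0:1, bp = 1:3)
    d[d$loc + d$edema + d$bp == g, , drop = FALSE]
  })
  pick <- vapply(grade, function(g) {
    d <- decomp[[g]]
    sample(nrow(d), 1)
  }, integer(1))
  loc <- vapply(seq_len(n), function(i) decomp[[grade[i]]]$loc[pick[i]], integer(1)) == 1
  edema <- vapply(seq_len(n), function(i) decomp[[grade[i]]]$edema[pick[i]], integer(1)) == 1
  bp <- vapply(seq_len(n), function(i) decomp[[grade[i]]]$bp[pick[i]], integer(1))

  # burden total uniform within the category band, then split into
  # hematoma points (rarely > 0), Hijdra and Le Roux components
  band_lo <- c(0L, 20L, 30L)[bp]
  band_hi <- c(19L, 29L, 49L)[bp]
  burden <- band_lo + vapply(band_hi - band_lo + 1L,
                             function(k) sample.int(k, 1L), integer(1)) - 1L
  ich_weights <- c(0.85, 0.06, 0.05, 0.04)   # most aSAH have no ICH
  ich_p <- vapply(burden, function(t) {
    allowed <- max(0L, t - 46L):min(3L, t)
    if (length(allowed) == 1) return(allowed)
    sample(allowed, 1, prob = ich_weights[allowed + 1])
  }, integer(1))
  rest <- burden - ich_p
  hij <- vapply(rest, function(r) {
    lo <- max(0L, r - 16L); hi <- min(30L, r)
    if (lo == hi) lo else sample(lo:hi, 1)
  }, integer(1))
  ler <- rest - hij

  cisterns <- t(vapply(hij, .spread_grades, integer(10),
                       n_slots = 10L, max_grade = 3L))
  ventricles <- t(vapply(ler, .spread_grades, integer(4),
                         n_slots = 4L, max_grade = 4L))

  # hematoma diameters reproducing the drawn point class under ABC/2
  vol <- numeric(n)
  vol[ich_p == 1] <- stats::runif(sum(ich_p == 1), 0.5, 9.5)
  vol[ich_p == 2] <- stats::runif(sum(ich_p == 2), 10.5, 29.5)
  vol[ich_p == 3] <- stats::runif(sum(ich_p == 3), 31, 80)
  diam <- ifelse(vol > 0, (2 * vol)^(1 / 3), NA_real_)

  # mRS from an ordinal-threshold model on z, anchored at the configured
  # unfavorable and mortality fractions; within-band splits follow the
  # published cohort shape
  cfav <- cumsum(c(113, 87, 25) / 225) * (1 - config$prevalence_unfavorable)
  cmid <- (1 - config$prevalence_unfavorable) +
    cumsum(c(22, 32, 22) / 76) *
    (config$prevalence_unfavorable - config$mortality)
  cum_p <- c(cfav, cmid[1:2], 1 - config$mortality)
  s_lat <- sqrt(1 + config$mrs_link_slope^2)
  thresholds <- stats::qnorm(cum_p) * s_lat
  y_lat <- config$mrs_link_slope * z + stats::rnorm(n)
  mrs <- findInterval(y_lat, thresholds)
  died <- mrs == 6L

  age <- round(stats::qnorm(
    stats::runif(n, stats::pnorm(18, config$age_mean, config$age_sd),
                 stats::pnorm(100, config$age_mean, config$age_sd)),
    config$age_mean, config$age_sd), 1)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  treatment <- ifelse(stats::runif(n) < config$clipping_fraction,
                      "clipping", "coiling")
  cm <- .draw_comorbidities(n)

  out <- data.frame(patient_id = seq_len(n), age = age, sex = sex,
                    treatment = treatment, stringsAsFactors = FALSE)
  out <- cbind(out, phys)
  colnames(cisterns) <- paste0("cistern_", 1:10)
  colnames(ventricles) <- paste0("ventricle_", 1:4)
  out <- cbind(out, cisterns, ventricles)
  out$hematoma_a <- diam; out$hematoma_b <- diam; out$hematoma_c <- diam
  out$loc <- loc; out$edema <- edema
  out <- cbind(out, cm)
  out$mrs <- as.integer(mrs)
  out$died_in_hospital <- died
  rownames(out) <- NULL
  out
}

# distribute a total over slots with a per-slot cap: each slot gets
# floor(total/slots), the remainder is spread over random distinct slots
.spread_grades <- function(total, n_slots, max_grade) {
  q <- total %/% n_slots
  r <- total %% n_slots
  g <- rep(q, n_slots)
  if (r > 0) {
    up <- sample.int(n_slots, r)
    g[up] <- g[up] + 1L
  }
  stopifnot(all(g <= max_grade))
  as.integer(g)
}

.comorbidity_probs <- c(
  cm_mi = 0.05, cm_chf = 0.03, cm_pvd = 0.03, cm_cvd = 0.04,
  cm_dementia = 0.01, cm_copd = 0.08, cm_ctd = 0.02, cm_ulcer = 0.03,
  cm_hemiplegia = 0.01, cm_renal = 0.03, cm_leukemia = 0.005,
  cm_lymphoma = 0.005, cm_aids = 0.002
)

.draw_comorbidities <- function(n) {
  out <- as.data.frame(lapply(.comorbidity_probs, function(p) {
    stats::runif(n) < p
  }))
  # severity-graded conditions drawn as exclusive categories
  liver <- sample(c("none", "mild", "modsev"), n, replace = TRUE,
                  prob = c(0.96, 0.03, 0.01))
  out$cm_liver_mild <- liver == "mild"
  out$cm_liver_mod_severe <- liver == "modsev"
  diab <- sample(c("none", "plain", "endorgan"), n, replace = TRUE,
                 prob = c(0.85, 0.12, 0.03))
  out$cm_diabetes <- diab == "plain"
  out$cm_diabetes_end_organ <- diab == "endorgan"
  tum <- sample(c("none", "any", "meta"), n, replace = TRUE,
                prob = c(0.94, 0.05, 0.01))
  out$cm_tumor <- tum == "any"
  out$cm_tumor_metastatic <- tum == "meta"
  out[, charlson_conditions()]
}
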