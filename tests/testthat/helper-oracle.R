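# Independent oracles kept deliberately separate from the implementation.

# Literal transcription of the organ-dysfunction point table as
# (system, variable, interval, points) rows; a system scores the maximum
# points of any triggered row, the total is the sum over systems.
lods_rule_table <- data.frame(
  system = c(rep("neurologic", 4),
             rep("cardiovascular", 8),
             rep("renal", 10),
             rep("pulmonary", 2),
             rep("hematologic", 5),
             rep("hepatic", 2)),
  variable = c(rep("gcs_min", 4),
               "hr_min", "hr_max", "sbp_min", "sbp_min", "sbp_min",
               "sbp_min", "sbp_max", "sbp_max",
               "urea_max", "urea_max", "urea_max", "urea_max",
               "creatinine_max", "creatinine_max", "creatinine_max",
               "urine_24h", "urine_24h", "urine_24h",
               "pao2_fio2", "pao2_fio2",
               "wbc_min", "wbc_min", "wbc_min", "wbc_max", "platelets_min",
               "bilirubin_max", "pt_excess_sec"),
  lo = c(3, 6, 9, 14,
         -Inf, 140, -Inf, 40, 70, 90, 240, 270,
         -Inf, 6, 10, 20, -Inf, 1.20, 1.60, -Inf, 0.5, 10,
         -Inf, 150,
         -Inf, 1.0, 2.5, 50, -Inf,
         2.0, 3),
  hi = c(6, 9, 14, 16,
         30, Inf, 40, 70, 90, 240, 270, Inf,
         6, 10, 20, Inf, 1.20, 1.60, Inf, 0.5, 0.75, Inf,
         150, Inf,
         1.0, 2.5, 50, Inf, 50,
         Inf, Inf),
  lo_open = c(rep(FALSE, 30), TRUE),  # pt row is "> 3"
  points = c(5, 3, 1, 0,
             5, 1, 5, 3, 1, 0, 1, 3,
             0, 1, 3, 5, 0, 1, 3, 5, 3, 3,
             3, 1,
             3, 1, 0, 1, 1,
             1, 1),
  stringsAsFactors = FALSE
)

# Brute-force scorer: evaluates every rule row against the observation.
oracle_lods <- function(obs) {
  vent <- isTRUE(obs$ventilated_or_cpap)
  systems <- unique(lods_rule_table$system)
  total <- 0L
  per_system <- integer(0)
  for (sys in systems) {
    rules <- lods_rule_table[lods_rule_table$system == sys, ]
    if (sys == "pulmonary" && !vent) {
      per_system[sys] <- 0L
      next
    }
    pts <- 0L
    for (i in seq_len(nrow(rules))) {
      v <- obs[[rules$variable[i]]]
      if (is.null(v) || is.na(v)) next
      hit <- if (rules$lo_open[i]) {
        v > rules$lo[i] & v < rules$hi[i]
      } else {
        v >= rules$lo[i] & v < rules$hi[i]
      }
      if (hit) pts <- max(pts, rules$points[i])
    }
    per_system[sys] <- pts
  }
  list(per_system = per_system, total = sum(per_system))
}

# Random, physiologically wide-ranging observation set (always complete,
# mmHg ratio units so the oracle's single pulmonary threshold applies).
random_observation <- function() {
  hr <- sort(runif(2, 10, 200))
  sbp <- sort(runif(2, 20, 320))
  wbc <- sort(runif(2, 0.1, 80))
  vent <- runif(1) < 0.5
  list(
    gcs_min = sample(3:15, 1),
    hr_min = hr[1], hr_max = hr[2],
    sbp_min = sbp[1], sbp_max = sbp[2],
    urea_max = runif(1, 0, 40),
    creatinine_max = runif(1, 0.2, 5),
    urine_24h = runif(1, 0, 15),
    ventilated_or_cpap = vent,
    pao2_fio2 = if (vent) runif(1, 30, 500) else NA_real_,
    pao2_fio2_unit = "mmHg",
    wbc_min = wbc[1], wbc_max = wbc[2],
    platelets_min = runif(1, 5, 500),
    bilirubin_max = runif(1, 0, 8),
    pt_excess_sec = runif(1, 0, 10)
  )
}

random_observation_frame <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    as.data.frame(random_observation(), stringsAsFactors = FALSE)
  }))
}

# Pair-counting AUC: P(score_pos > score_neg) with ties counted 0.5.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
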