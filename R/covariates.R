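# Per-subject clinical/demographic covariate simulation.
#
# Continuous covariates are drawn from scaled Beta distributions on each
# instrument's documented range, with shape parameters solved so that the
# configured group means and SDs are exact distribution moments (a truncated
# Gaussian would bias the means near the floor of skewed instruments).

# Default group means/SDs for the continuous covariates and the instrument
# ranges they live on. Group rows: patients (group 1) and controls (group 0).
#' @noRd
covariate_defaults <- function() {
  data.frame(
    name    = c("age", "docs_total", "mis_score", "bai_total", "bdi_total"),
    lo      = c(18, 0, 0, 0, 0),
    hi      = c(80, 80, 30, 63, 63),
    mean_g1 = c(34.89, 20.80, 5.90, 13.30, 16.00),
    sd_g1   = c(14.41, 17.99, 5.92, 11.87, 14.50),
    mean_g0 = c(35.90, 13.20, 8.38, 13.80, 7.00),
    sd_g0   = c(13.31, 15.91, 6.97, 15.32, 10.98),
    stringsAsFactors = FALSE
  )
}

# Scaled-Beta sampler with exact mean m and sd s on [lo, hi]. If the
# requested sd is infeasible for a Beta (s^2 >= m(1-m) in unit scale) it is
# shrunk to the feasible boundary.
#' @noRd
rbeta_moments <- function(n, m, s, lo, hi) {
  mu <- (m - lo) / (hi - lo)
  sg <- s / (hi - lo)
  mu <- min(max(mu, 1e-3), 1 - 1e-3)
  smax <- sqrt(mu * (1 - mu))
  if (sg >= smax) sg <- 0.95 * smax
  nu <- mu * (1 - mu) / sg^2 - 1
  lo + (hi - lo) * rbeta(n, mu * nu, (1 - mu) * nu)
}

# Called inside generate_cohort()'s RNG stream.
#' @noRd
simulate_covariates <- function(cfg, ids, groups) {
  n <- length(ids)
  defs <- covariate_defaults()
  sep <- cfg$covariate_separation
  out <- data.frame(subject_id = ids, group = groups,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(defs))) {
    d <- defs[k, ]
    m_all <- (d$mean_g1 + d$mean_g0) / 2
    m1 <- m_all + sep * (d$mean_g1 - m_all)
    m0 <- m_all + sep * (d$mean_g0 - m_all)
    x <- numeric(n)
    x[groups == 1L] <- rbeta_moments(sum(groups == 1L), m1, d$sd_g1, d$lo, d$hi)
    x[groups == 0L] <- rbeta_moments(sum(groups == 0L), m0, d$sd_g0, d$lo, d$hi)
    out[[d$name]] <- x
  }
  p_male <- ifelse(groups == 1L, 0.60, 0.70)
  out$sex <- factor(ifelse(runif(n) < p_male, "male", "female"),
                    levels = c("male", "female"))
  edu_levels <- c("some_college", "bachelor", "master", "doctoral",
                  "other_professional")
  edu_p1 <- c(0.2, 0.2, 0.0, 0.4, 0.2)
  edu_p0 <- c(0.0, 0.0, 0.1, 0.2, 0.7)
  edu <- character(n)
  for (i in seq_len(n)) {
    pr <- if (groups[i] == 1L) edu_p1 else edu_p0
    edu[i] <- sample(edu_levels, 1, prob = pr)
  }
  out$education <- factor(edu, levels = edu_levels)
  # default missingness: a few subjects lack age / MIS values
  if (cfg$age_missing > 0L) {
    out$age[sample.int(n, min(cfg$age_missing, n))] <- NA_real_
  }
  if (cfg$mis_missing > 0L) {
    out$mis_score[sample.int(n, min(cfg$mis_missing, n))] <- NA_real_
  }
  validate_covariates(out)
  out
}

#' @noRd
validate_covariates <- function(cov) {
  if (anyDuplicated(cov$subject_id)) stopf("subject ids must be unique")
  rng <- list(docs_total = c(0, 80), mis_score = c(0, 30),
              bai_total = c(0, 63), bdi_total = c(0, 63))
  for (nm in names(rng)) {
    v <- cov[[nm]]
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < rng[[nm]][1] || max(v) > rng[[nm]][2])) {
      stopf("%s outside its instrument range", nm)
    }
  }
  invisible(cov)
}
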