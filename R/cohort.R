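# Longitudinal cohort simulation: ear-visit "instances" with latent AR(1)
# E/P ratio trajectories around group baselines, hydrops labelling, and
# audiograms whose visit-to-visit shifts are driven by the latent
# endolymph dynamics through a Gamma log-link hearing model.

#' Parameters for the longitudinal cohort simulator
#'
#' Defaults reproduce the study conditions the generator emulates: 14
#' affected patients (28 ears, 3-7 visits over 15 months) and 12 healthy
#' volunteers (24 ears, 1-2 visits); healthy-volunteer vestibular E/P
#' 0.35 +/- 0.086 and cochlear E/P 0.24 +/- 0.05; affected vestibular E/P
#' 0.43 +/- 0.15; total volumes 93.18 +/- 10.47 uL (cochlea, HV),
#' 91.42 +/- 11.86 (cochlea, affected), 59.57 +/- 8.67 (vestibule, HV),
#' 57.39 +/- 9.32 (vestibule, affected).
#'
#' Each ear's vestibular E/P follows an AR(1) process around its baseline;
#' ears whose baseline exceeds `high_var_threshold` carry the larger
#' innovation SD, which reproduces the higher longitudinal E/P variance of
#' hydropic/unstable ears. Hearing level is Gamma with log link in the
#' vestibular E/P plus diagnosis, age and nested random intercepts; per-visit
#' threshold shifts are proportional to the latent E/P change, so shifts are
#' sign-consistent with endolymph dynamics.
#'
#' @param n_affected_patients,n_hv cohort sizes (patients).
#' @param visits_affected,visits_hv integer ranges `c(min, max)` of visits
#'   per group; affected ears need >= 3.
#' @param vest_ep_hv,vest_ep_affected,coch_ep_hv,coch_ep_affected `c(mean,
#'   sd)` of the baseline E/P distributions.
#' @param vest_tv_hv,vest_tv_affected,coch_tv_hv,coch_tv_affected `c(mean,
#'   sd)` of the per-ear total-volume distributions, uL.
#' @param ar1_phi AR(1) coefficient in \[0, 1).
#' @param innovation_sd_hv,innovation_sd_low,innovation_sd_high vestibular
#'   AR(1) innovation SDs for HV ears, low-variability affected ears, and
#'   high-variability (hydrops-prone) affected ears.
#' @param coch_innovation_scale cochlear innovation SD as a fraction of the
#'   vestibular one.
#' @param high_var_threshold baseline vestibular E/P above which an affected
#'   ear is treated as hydrops-prone (high innovation SD).
#' @param ep_noise_sd measurement noise SD added to the reported E/P.
#' @param tv_noise_sd visit-to-visit TV measurement noise SD, uL.
#' @param hydrops_threshold measured vestibular E/P above which the hydrops
#'   flag is set (strict inequality).
#' @param beta0,beta_ep,beta_dx,beta_age Gamma log-link hearing model:
#'   intercept (log dB HL), vestibular E/P slope, named diagnosis effects,
#'   and per-year age effect (age centred at 50).
#' @param shape Gamma shape parameter of the baseline hearing draw.
#' @param re_sd_patient,re_sd_ear SDs of the patient and ear-within-patient
#'   random intercepts on the log scale.
#' @param shift_gain dB of threshold shift per unit latent E/P change.
#' @param shift_noise_sd SD (dB) of E/P-independent threshold-shift noise
#'   added per frequency and visit before lattice quantization. The default
#'   0 makes every shift sign-consistent with the latent E/P change; a
#'   positive value decouples hearing dynamics from endolymph dynamics
#'   (useful for null simulations).
#' @param shift_profile per-frequency multipliers on `shift_gain` (length 6,
#'   ordered 0.25-8 kHz).
#' @param audio_profile per-frequency offsets (dB) of the baseline audiogram
#'   around the latent hearing level.
#' @param audio_noise_sd baseline audiogram noise SD, dB.
#' @param bilateral_prob probability an affected patient has bilateral
#'   disease.
#' @param seed integer seed.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_affected_patients = 14,
                          n_hv = 12,
                          visits_affected = c(3L, 7L),
                          visits_hv = c(1L, 2L),
                          vest_ep_hv = c(0.35, 0.086),
                          vest_ep_affected = c(0.43, 0.15),
                          coch_ep_hv = c(0.24, 0.05),
                          coch_ep_affected = c(0.23, 0.07),
                          vest_tv_hv = c(59.57, 8.67),
                          vest_tv_affected = c(57.39, 9.32),
                          coch_tv_hv = c(93.18, 10.47),
                          coch_tv_affected = c(91.42, 11.86),
                          ar1_phi = 0.6,
                          innovation_sd_hv = 0.008,
                          innovation_sd_low = 0.015,
                          innovation_sd_high = 0.09,
                          coch_innovation_scale = 0.6,
                          high_var_threshold = 0.45,
                          ep_noise_sd = 0.01,
                          tv_noise_sd = 1.0,
                          hydrops_threshold = 0.50,
                          beta0 = 2.48,
                          beta_ep = 1.5,
                          beta_dx = c(md = 0.5, ssnhl = 0.3, aied = 0.4, hi_nos = 0.3),
                          beta_age = 0.004,
                          shape = 20,
                          re_sd_patient = 0.15,
                          re_sd_ear = 0.10,
                          shift_gain = 120,
                          shift_noise_sd = 0,
                          shift_profile = c(0.7, 0.9, 1, 1, 1.2, 1.3),
                          audio_profile = c(0, 0, 0, 2, 4, 6),
                          audio_noise_sd = 2,
                          bilateral_prob = 0.43,
                          seed = 1L) {
  p <- as.list(environment())
  p$seed <- as.integer(seed)
  sds <- c(vest_ep_hv[2], vest_ep_affected[2], coch_ep_hv[2], coch_ep_affected[2],
           innovation_sd_hv, innovation_sd_low, innovation_sd_high,
           ep_noise_sd, tv_noise_sd, re_sd_patient, re_sd_ear, audio_noise_sd,
           shift_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (ar1_phi < 0 || ar1_phi >= 1) stop("ar1_phi must be in [0, 1)", call. = FALSE)
  if (visits_affected[1] < 3) {
    stop("affected ears require at least 3 visits", call. = FALSE)
  }
  if (visits_hv[1] < 1) stop("HV ears require at least 1 visit", call. = FALSE)
  if (n_affected_patients < 1 || n_hv < 0) stop("invalid cohort sizes", call. = FALSE)
  if (length(shift_profile) != 6L || length(audio_profile) != 6L) {
    stop("shift_profile and audio_profile must have length 6", call. = FALSE)
  }
  class(p) <- "cohort_params"
  p
}

# Truncated-normal draw via resampling (vectorized, cheap at these scales).
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

# Stationary AR(1) sample of length n around zero.
ar1_series <- function(n, phi, innov_sd) {
  if (innov_sd == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, innov_sd / sqrt(1 - phi^2))
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

# Default ear-level diagnosis assignment mirroring the mix of a hearing
# instability clinic population: mostly Meniere's, a few SSNHL/AIED, one
# not-otherwise-specified, some patients with mixed diagnoses.
assign_diagnoses <- function(n_patients) {
  base <- c(rep("md", 8), "ssnhl", "aied", "hi_nos", rep("mixed", 3))
  rep_len(base, n_patients)
}

#' Simulate a longitudinal ear-visit cohort
#'
#' Generates the full instance table the downstream analyses consume: per
#' patient and ear, visit times, covariates, latent and measured cochlear and
#' vestibular fluid volumes (TV/PV/EV and E/P), a hydrops flag, and a
#' six-frequency air-conduction audiogram on the clinical 5-dB lattice whose
#' visit-to-visit shifts are sign-consistent with the latent vestibular E/P
#' change. Deterministic given `params$seed` (or the `seed` override).
#'
#' @param params a [cohort_params()].
#' @param seed optional seed overriding `params$seed`.
#' @return a data frame with one row per instance; see the column dictionary
#'   in [write_cohort_csv()].
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed %||% params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  rows <- list()
  dx_by_patient <- assign_diagnoses(p$n_affected_patients)
  for (grp in c("affected", "hv")) {
    n_pat <- if (grp == "affected") p$n_affected_patients else p$n_hv
    for (i in seq_len(n_pat)) {
      pid <- sprintf("%s%02d", if (grp == "affected") "P" else "HV", i)
      age <- round(if (grp == "affected") rnorm_trunc(1, 48, 13, 18)
                   else rnorm_trunc(1, 50, 21, 18))
      age <- min(age, 80)
      sex <- if (i %% 2 == 0) "F" else "M"
      u_patient <- stats::rnorm(1, 0, p$re_sd_patient)
      n_visits <- sample(seq(
        if (grp == "affected") p$visits_affected[1] else p$visits_hv[1],
        if (grp == "affected") p$visits_affected[2] else p$visits_hv[2]), 1)
      visit_time <- if (grp == "hv") c(0, 3)[seq_len(n_visits)] else
        sort(c(0, stats::runif(n_visits - 1, 1, 15)))
      bilateral <- grp == "affected" && stats::runif(1) < p$bilateral_prob
      affected_side <- sample(c("L", "R"), 1)
      for (ear in c("L", "R")) {
        ear_aff <- grp == "affected" && (bilateral || ear == affected_side)
        dx <- c(md = 0L, ssnhl = 0L, aied = 0L, hi_nos = 0L)
        if (ear_aff) {
          lab <- dx_by_patient[i]
          if (lab == "mixed") dx[c("md", "ssnhl")] <- 1L else dx[lab] <- 1L
        }
        ep_grp_v <- if (ear_aff) p$vest_ep_affected else p$vest_ep_hv
        ep_grp_c <- if (ear_aff) p$coch_ep_affected else p$coch_ep_hv
        tv_grp_v <- if (grp == "affected") p$vest_tv_affected else p$vest_tv_hv
        tv_grp_c <- if (grp == "affected") p$coch_tv_affected else p$coch_tv_hv
        b_vest <- rnorm_trunc(1, ep_grp_v[1], ep_grp_v[2], 0.05)
        b_coch <- rnorm_trunc(1, ep_grp_c[1], ep_grp_c[2], 0.05)
        innov <- if (grp == "hv") p$innovation_sd_hv
          else if (b_vest > p$high_var_threshold) p$innovation_sd_high
          else p$innovation_sd_low
        ep_vest <- pmax(0.02, b_vest + ar1_series(n_visits, p$ar1_phi, innov))
        ep_coch <- pmax(0.02, b_coch +
                          ar1_series(n_visits, p$ar1_phi,
                                     innov * p$coch_innovation_scale))
        tv_vest_ear <- rnorm_trunc(1, tv_grp_v[1], tv_grp_v[2], 20)
        tv_coch_ear <- rnorm_trunc(1, tv_grp_c[1], tv_grp_c[2], 20)
        u_ear <- stats::rnorm(1, 0, p$re_sd_ear)
        eta_fix <- p$beta0 + sum(p$beta_dx * dx) + p$beta_age * (age - 50)
        level <- exp(eta_fix + p$beta_ep * ep_vest + u_patient + u_ear)
        # baseline audiogram: latent level + frequency profile + noise on the
        # 5-dB lattice; later visits shift with the latent E/P change only
        th <- matrix(NA_real_, n_visits, 6)
        base <- level[1] + p$audio_profile +
          stats::rnorm(6, 0, p$audio_noise_sd)
        th[1, ] <- pmin(120, pmax(0, 5 * round(base / 5)))
        if (n_visits > 1) {
          for (t in 2:n_visits) {
            d_ep <- ep_vest[t] - ep_vest[t - 1]
            raw <- p$shift_gain * p$shift_profile * d_ep
            if (p$shift_noise_sd > 0) {
              raw <- raw + stats::rnorm(6, 0, p$shift_noise_sd)
            }
            shift <- 5 * round(raw / 5)
            th[t, ] <- pmin(120, pmax(0, th[t - 1, ] + shift))
          }
        }
        ep_vest_meas <- pmax(0.01, ep_vest + stats::rnorm(n_visits, 0, p$ep_noise_sd))
        ep_coch_meas <- pmax(0.01, ep_coch + stats::rnorm(n_visits, 0, p$ep_noise_sd))
        tv_vest <- pmax(5, tv_vest_ear + stats::rnorm(n_visits, 0, p$tv_noise_sd))
        tv_coch <- pmax(5, tv_coch_ear + stats::rnorm(n_visits, 0, p$tv_noise_sd))
        pv_vest <- tv_vest / (1 + ep_vest_meas)
        pv_coch <- tv_coch / (1 + ep_coch_meas)
        df <- data.frame(
          patient_id = pid, ear = ear, group = grp,
          visit = seq_len(n_visits), visit_time = round(visit_time, 2),
          age = age, sex = sex, ear_affected = ear_aff,
          dx_md = dx[["md"]], dx_ssnhl = dx[["ssnhl"]],
          dx_aied = dx[["aied"]], dx_hi_nos = dx[["hi_nos"]],
          coch_tv = tv_coch, coch_pv = pv_coch, coch_ev = tv_coch - pv_coch,
          coch_ep = ep_coch_meas,
          vest_tv = tv_vest, vest_pv = pv_vest, vest_ev = tv_vest - pv_vest,
          vest_ep = ep_vest_meas, vest_ep_latent = ep_vest,
          hydrops = ep_vest_meas > p$hydrops_threshold,
          dose = rnorm_trunc(n_visits, 0.2, 0.01, 0.05),
          delay_h = stats::runif(n_visits, 4, 8),
          stringsAsFactors = FALSE
        )
        colnames(th) <- paste0("ac_", AUDIO_FREQS)
        df <- cbind(df, as.data.frame(th))
        df$pta4 <- rowMeans(th[, paste0("ac_", c(0.5, 1, 2, 4)), drop = FALSE])
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- p$seed
  out
}

#' Simulate a second operator's ratings
#'
#' Adds independent zero-mean Gaussian measurement error to a vector of
#' continuous ratings, emulating re-measurement of the same instances by an
#' independent operator.
#'
#' @param values numeric vector.
#' @param error_sd measurement error SD (>= 0).
#' @param seed integer seed.
#' @return numeric vector of the same length.
#' @export
perturb_ratings <- function(values, error_sd, seed = 1L) {
  stopifnot(is.numeric(values), error_sd >= 0)
  if (error_sd == 0) return(values)
  with_seed(seed, values + stats::rnorm(length(values), 0, error_sd))
}

#' Simulate instances from a plain Gamma log-link mixed model
#'
#' A focused generator for validating the GLMM fitting stage: hearing level
#' is Gamma with log-scale mean `beta0 + beta_ep * ep + u_patient + u_ear`,
#' with nested random intercepts and a known shape parameter.
#'
#' @param n_patients number of patients (2 ears each).
#' @param visits visits per ear.
#' @param beta0,beta_ep true fixed effects (log scale).
#' @param shape Gamma shape.
#' @param re_sd_patient,re_sd_ear random-intercept SDs.
#' @param ep_mean,ep_sd distribution of the E/P covariate.
#' @param seed integer seed.
#' @return data frame with `patient_id`, `ear`, `vest_ep`, `pta4`.
#' @export
simulate_glmm_data <- function(n_patients = 100, visits = 5,
                               beta0 = log(40), beta_ep = 1.5, shape = 20,
                               re_sd_patient = 0.1, re_sd_ear = 0.1,
                               ep_mean = 0.43, ep_sd = 0.15, seed = 1L) {
  with_seed(seed, {
    rows <- vector("list", n_patients * 2L)
    k <- 0L
    for (i in seq_len(n_patients)) {
      u_p <- stats::rnorm(1, 0, re_sd_patient)
      for (ear in c("L", "R")) {
        u_e <- stats::rnorm(1, 0, re_sd_ear)
        ep <- rnorm_trunc(visits, ep_mean, ep_sd, 0.01)
        mu <- exp(beta0 + beta_ep * ep + u_p + u_e)
        y <- stats::rgamma(visits, shape = shape, rate = shape / mu)
        k <- k + 1L
        rows[[k]] <- data.frame(patient_id = sprintf("P%03d", i), ear = ear,
                                visit = seq_len(visits), vest_ep = ep,
                                pta4 = y, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write / read a cohort table as CSV
#'
#' Column dictionary: `patient_id`, `ear` (L/R), `group`
#' (affected/hv), `visit` (1-based, strictly increasing per ear),
#' `visit_time` (months), `age` (years), `sex`, `ear_affected`,
#' `dx_md`/`dx_ssnhl`/`dx_aied`/`dx_hi_nos` (non-exclusive 0/1 indicators),
#' `coch_tv`/`coch_pv`/`coch_ev` (uL), `coch_ep`, `vest_tv`/`vest_pv`/
#' `vest_ev` (uL), `vest_ep`, `vest_ep_latent`, `hydrops` (logical),
#' `dose` (mmol/kg), `delay_h` (hours), `ac_<freq>` (air-conduction
#' thresholds, dB HL, at 0.25-8 kHz), `pta4` (dB HL), and, once scored,
#' `stability`, `unstable`, `cum_shift`.
#'
#' @param cohort data frame.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
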