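# Rule-based audiometric scoring: pure tone averages, the sensorineural
# hearing loss criterion, per-visit hearing-stability designation against the
# most recent prior audiogram, cumulative threshold shift, and the
# hearing-instability inclusion rules for serial audiometry.

#' Standard audiometric frequencies (kHz)
#' @export
AUDIO_FREQS <- c(0.25, 0.5, 1, 2, 4, 8)

#' Construct an audiogram
#'
#' @param ac named numeric vector of air-conduction thresholds (dB HL); names
#'   are frequencies in kHz (e.g. `"0.25"`, `"0.5"`, ..., `"8"`).
#' @param bc optional named numeric vector of bone-conduction thresholds.
#' @param ear,visit optional identifiers carried through.
#' @return object of class `audiogram`.
#' @export
#' @examples
#' audiogram(c(`0.25` = 10, `0.5` = 15, `1` = 20, `2` = 25, `4` = 30, `8` = 40))
audiogram <- function(ac, bc = NULL, ear = NA_character_, visit = NA_integer_) {
  stopifnot(is.numeric(ac), !is.null(names(ac)))
  if (any(ac < -10 | ac > 120, na.rm = TRUE)) {
    stop("thresholds must lie within [-10, 120] dB HL", call. = FALSE)
  }
  structure(list(ac = ac, bc = bc, ear = ear, visit = visit),
            class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat("Audiogram", if (!is.na(x$ear)) sprintf("(ear %s, visit %s)", x$ear, x$visit),
      "\n  AC:", paste(sprintf("%g kHz: %g", as.numeric(names(x$ac)), x$ac),
                       collapse = ", "), "\n")
  invisible(x)
}

ac_thresholds <- function(a) if (inherits(a, "audiogram")) a$ac else a

pta_freq_sets <- list(
  four_freq = c(0.5, 1, 2, 4),
  lf = c(0.25, 0.5),
  hf = c(4, 8)
)

#' Pure tone average
#'
#' Arithmetic mean of air-conduction thresholds over a standard frequency
#' set: 4-frequency (0.5, 1, 2, 4 kHz), low frequency (0.25, 0.5 kHz), or
#' high frequency (4, 8 kHz).
#'
#' @param a an [audiogram()] or a named numeric vector of AC thresholds.
#' @param set `"four_freq"`, `"lf"`, or `"hf"`.
#' @return PTA in dB HL.
#' @export
compute_pta <- function(a, set = c("four_freq", "lf", "hf")) {
  set <- match.arg(set)
  ac <- ac_thresholds(a)
  freqs <- pta_freq_sets[[set]]
  want <- as.character(freqs)
  missing <- setdiff(want, names(ac)[!is.na(ac)])
  if (length(missing) > 0) {
    stop(sprintf("missing frequency %s kHz for %s PTA",
                 paste(missing, collapse = ", "), set), call. = FALSE)
  }
  mean(ac[want])
}

#' Clinically significant sensorineural hearing loss
#'
#' SNHL is designated when the air-conduction PTA exceeds 25 dB HL with an
#' air-bone gap of at most 10 dB (ruling out a conductive component).
#'
#' @param air_pta air-conduction PTA, dB HL.
#' @param air_bone_gap air-bone gap, dB.
#' @return logical.
#' @export
classify_snhl <- function(air_pta, air_bone_gap) {
  stopifnot(is.numeric(air_pta), is.numeric(air_bone_gap))
  air_pta > 25 & air_bone_gap <= 10
}

# Per-frequency threshold differences current - prior on a shared grid.
threshold_deltas <- function(current, prior) {
  ac_c <- ac_thresholds(current)
  ac_p <- ac_thresholds(prior)
  if (!identical(names(ac_c), names(ac_p))) {
    stop("audiograms are on different frequency grids", call. = FALSE)
  }
  ac_c - ac_p
}

# The instability trigger: |delta| >= 20 dB at >= 1 frequency, or
# |delta| >= 15 dB at >= 2 adjacent frequencies (adjacent in the ordered
# audiometric set). Magnitudes are used so both worsening and improvement
# trigger.
unstable_trigger <- function(delta) {
  ad <- abs(delta)
  any(ad >= 20) || any(ad[-length(ad)] >= 15 & ad[-1] >= 15)
}

#' Cumulative threshold shift between consecutive audiograms
#'
#' Signed sum of per-frequency threshold differences whose magnitude exceeds
#' 10 dB HL (strictly), relative to the most recent prior audiogram.
#'
#' @param current,prior audiograms on a shared frequency grid.
#' @return shift in dB (negative = improvement).
#' @export
#' @examples
#' a <- audiogram(c(`0.25` = 40, `0.5` = 20, `1` = 20, `2` = 40, `4` = 35, `8` = 25))
#' b <- audiogram(c(`0.25` = 15, `0.5` = 25, `1` = 20, `2` = 25, `4` = 25, `8` = 25))
#' cumulative_shift(a, b)  # +25 and +15 count, +10 does not -> +40
cumulative_shift <- function(current, prior) {
  delta <- threshold_deltas(current, prior)
  sum(delta[abs(delta) > 10])
}

#' Per-visit hearing-stability designation
#'
#' A visit is unstable when, compared to the most recent prior audiogram, a
#' threshold shift of >= 20 dB HL occurs at one or more frequencies or >= 15
#' dB HL at two or more consecutive frequencies. Unstable visits are split
#' into improved (negative cumulative shift) and worsened (positive); the
#' first visit of an ear has no prior audiogram and is designated
#' `unknown_baseline`.
#'
#' @param current the visit's audiogram.
#' @param prior the most recent prior audiogram, or `NULL` at baseline.
#' @return list with `designation` (one of `"stable"`, `"unstable_improved"`,
#'   `"unstable_worsened"`, `"unstable_indeterminate"`,
#'   `"unknown_baseline"`), `unstable` (logical or `NA`), and
#'   `cumulative_shift` (dB, `NA` at baseline).
#' @export
classify_stability <- function(current, prior = NULL) {
  if (is.null(prior)) {
    return(list(designation = "unknown_baseline", unstable = NA,
                cumulative_shift = NA_real_))
  }
  delta <- threshold_deltas(current, prior)
  shift <- sum(delta[abs(delta) > 10])
  if (!unstable_trigger(delta)) {
    return(list(designation = "stable", unstable = FALSE,
                cumulative_shift = shift))
  }
  designation <- if (shift > 0) {
    "unstable_worsened"
  } else if (shift < 0) {
    "unstable_improved"
  } else {
    # an unstable trigger whose large shifts cancel exactly; direction
    # undefined, so flag rather than force a side
    warning("unstable visit with zero cumulative shift: direction indeterminate",
            call. = FALSE)
    "unstable_indeterminate"
  }
  list(designation = designation, unstable = TRUE, cumulative_shift = shift)
}

#' Hearing-instability inclusion screen over serial audiometry
#'
#' Scans all consecutive audiogram pairs for the two inclusion criteria:
#' fluctuating hearing (threshold shift >= 20 dB HL at one frequency, or
#' >= 15 dB HL at two or more frequencies, adjacency not required) and
#' sudden hearing loss (shift >= 30 dB at three consecutive frequencies).
#' Sudden takes precedence when both are met.
#'
#' @param audiograms list of >= 2 audiograms in visit order, shared grid.
#' @return list with `eligible` (logical) and `criterion` (`"sudden"`,
#'   `"fluctuating"`, or `"none"`).
#' @export
check_hi_inclusion <- function(audiograms) {
  if (!is.list(audiograms) || length(audiograms) < 2L) {
    stop("need at least 2 serial audiograms", call. = FALSE)
  }
  sudden <- fluct <- FALSE
  for (i in seq_len(length(audiograms) - 1L)) {
    delta <- threshold_deltas(audiograms[[i + 1L]], audiograms[[i]])
    ad <- abs(delta)
    n <- length(ad)
    if (n >= 3 && any(ad[1:(n - 2)] >= 30 & ad[2:(n - 1)] >= 30 & ad[3:n] >= 30)) {
      sudden <- TRUE
    }
    if (any(ad >= 20) || sum(ad >= 15) >= 2) fluct <- TRUE
  }
  criterion <- if (sudden) "sudden" else if (fluct) "fluctuating" else "none"
  list(eligible = sudden || fluct, criterion = criterion)
}

#' Score hearing stability across a longitudinal cohort table
#'
#' Applies [classify_stability()] and [cumulative_shift()] ear-wise down a
#' cohort table in visit order, each visit compared to the ear's most recent
#' prior audiogram.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]) containing
#'   `patient_id`, `ear`, `visit` and the `ac_*` threshold columns.
#' @return the cohort with `stability`, `unstable`, and `cum_shift` columns
#'   appended.
#' @export
score_cohort_stability <- function(cohort) {
  ac_cols <- paste0("ac_", AUDIO_FREQS)
  stopifnot(all(ac_cols %in% names(cohort)))
  key <- interaction(cohort$patient_id, cohort$ear, drop = TRUE)
  cohort$stability <- NA_character_
  cohort$unstable <- NA
  cohort$cum_shift <- NA_real_
  for (k in levels(key)) {
    rows <- which(key == k)
    rows <- rows[order(cohort$visit[rows])]
    prior <- NULL
    for (r in rows) {
      ac <- as.numeric(cohort[r, ac_cols])
      names(ac) <- AUDIO_FREQS
      cur <- audiogram(ac)
      res <- classify_stability(cur, prior)
      cohort$stability[r] <- res$designation
      cohort$unstable[r] <- res$unstable
      cohort$cum_shift[r] <- res$cumulative_shift
      prior <- cur
    }
  }
  cohort
}
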