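# End-to-end orchestration: validate a YAML run configuration, then
# simulate -> (phantom volumetry check) -> score audiograms -> statistics ->
# report, with deterministic outputs per seed.

run_config_defaults <- function() {
  list(
    seed = 1L,
    cohort = list(),            # overrides passed to cohort_params()
    phantoms_per_structure = 1L,
    phantom = list(),           # overrides passed to phantom_spec()
    hydrops_threshold = 0.50,
    hydrops_source = "measured",  # or "latent"
    stats_plan = list(contingency = TRUE, group_comparisons = TRUE,
                      variance_comparisons = TRUE, correlations = TRUE,
                      glmm = TRUE),
    glmm_fixed = c("vest_ep", "age", "dx_md", "dx_ssnhl", "dx_aied"),
    out_dir = NULL
  )
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML file (or takes a list), applies defaults, and validates
#' every key. Unknown keys and out-of-range values raise named errors.
#'
#' Recognized keys: `seed` (integer), `cohort` (overrides for
#' [cohort_params()]), `phantoms_per_structure` (integer >= 0), `phantom`
#' (overrides for [phantom_spec()]), `hydrops_threshold` (> 0),
#' `hydrops_source` (`"measured"` or `"latent"`), `stats_plan` (logical
#' switches: `contingency`, `group_comparisons`, `variance_comparisons`,
#' `correlations`, `glmm`), `glmm_fixed` (character), `out_dir`.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config of class `run_config` with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("config error: seed must be a single integer", call. = FALSE)
  }
  if (cfg$phantoms_per_structure < 0) {
    stop("config error: phantoms_per_structure must be >= 0", call. = FALSE)
  }
  if (cfg$hydrops_threshold <= 0) {
    stop("config error: hydrops_threshold must be > 0", call. = FALSE)
  }
  if (!cfg$hydrops_source %in% c("measured", "latent")) {
    stop("config error: hydrops_source must be 'measured' or 'latent'", call. = FALSE)
  }
  unknown_plan <- setdiff(names(cfg$stats_plan), names(defaults$stats_plan))
  if (length(unknown_plan) > 0) {
    stop("unknown statistics plan key(s): ",
         paste(unknown_plan, collapse = ", "), call. = FALSE)
  }
  cfg$stats_plan <- utils::modifyList(defaults$stats_plan, cfg$stats_plan)
  # surface invalid cohort/phantom overrides now rather than mid-run
  do.call(cohort_params, c(cfg$cohort, list(seed = cfg$seed)))
  if (cfg$phantoms_per_structure > 0) {
    do.call(phantom_spec, c(list(structure = "vestibule"), cfg$phantom))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: (1) simulate the longitudinal cohort;
#' (2) generate and segment calibration phantoms, reporting volume-recovery
#' error; (3) score per-visit hearing stability; (4) run the configured
#' statistics (hydrops-by-instability contingency with odds ratio and Woolf
#' interval, E/P group comparisons, per-ear variance comparisons, E/P-PTA
#' correlations, Gamma log-link GLMM); (5) assemble the report. When
#' `out_dir` is set, writes `cohort.csv`, `designations.csv`, `volumes.csv`,
#' `report.json` and `summary.txt`. Deterministic per seed.
#'
#' @param config a `run_config`, a list, or a YAML path (validated first).
#' @return an `analysis_report` list: `cohort` (scored), `volumetry`,
#'   `contingency`, `group_comparisons`, `variance_comparisons`,
#'   `correlations`, `glmm`, `bookkeeping`, `warnings`, `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  notes <- character()
  note <- function(...) notes <<- c(notes, sprintf(...))

  # stage 1: cohort simulation
  params <- do.call(cohort_params, c(cfg$cohort, list(seed = cfg$seed)))
  cohort <- tryCatch(simulate_cohort(params),
                     error = function(e) stop("stage cohort: ", conditionMessage(e),
                                              call. = FALSE))
  note("cohort: %d instances (%d ears)", nrow(cohort),
       nlevels(interaction(cohort$patient_id, cohort$ear, drop = TRUE)))

  # stage 2: phantom volumetry check
  volumetry <- NULL
  if (cfg$phantoms_per_structure > 0) {
    volumetry <- tryCatch({
      res <- list()
      for (st in c("vestibule", "cochlea")) {
        for (j in seq_len(cfg$phantoms_per_structure)) {
          spec <- do.call(phantom_spec,
                          c(list(structure = st), cfg$phantom,
                            list(seed = cfg$seed * 1000L + j +
                                   ifelse(st == "cochlea", 500L, 0L))))
          ph <- generate_phantom(spec)
          fv <- measure_phantom(ph)
          vv <- ph$voxel_size^3
          truth_tv <- sum(ph$labels > 0) * vv
          res[[length(res) + 1L]] <- data.frame(
            structure = st, replicate = j, tv = fv$tv, pv = fv$pv, ev = fv$ev,
            ep_ratio = fv$ep_ratio, truth_tv = truth_tv,
            tv_rel_error = (fv$tv - truth_tv) / truth_tv,
            n_clipped = fv$n_clipped)
        }
      }
      do.call(rbind, res)
    }, error = function(e) stop("stage volumetry: ", conditionMessage(e),
                                call. = FALSE))
    note("volumetry: %d phantoms, max |TV error| %.2f%%",
         nrow(volumetry), 100 * max(abs(volumetry$tv_rel_error)))
    if (any(volumetry$n_clipped > 0)) {
      note("volumetry warning: %d phantoms had clipped perilymph voxels",
           sum(volumetry$n_clipped > 0))
    }
  }

  # stage 3: hydrops source + audiometric scoring
  if (cfg$hydrops_source == "latent") {
    cohort$hydrops <- cohort$vest_ep_latent > cfg$hydrops_threshold
  } else if (cfg$hydrops_threshold != params$hydrops_threshold) {
    cohort$hydrops <- cohort$vest_ep > cfg$hydrops_threshold
  }
  cohort <- tryCatch(suppressWarnings(score_cohort_stability(cohort)),
                     error = function(e) stop("stage audiometry: ",
                                              conditionMessage(e), call. = FALSE))
  aff <- cohort[cohort$group == "affected", , drop = FALSE]
  bookkeeping <- list(
    n_affected_instances = nrow(aff),
    n_stable = sum(aff$stability == "stable"),
    n_unstable = sum(aff$unstable %in% TRUE),
    n_baseline_unknown = sum(aff$stability == "unknown_baseline"),
    n_hydrops = sum(aff$hydrops),
    n_hv_instances = sum(cohort$group == "hv"))
  note("audiometry: %d stable, %d unstable, %d baseline-unknown affected instances",
       bookkeeping$n_stable, bookkeeping$n_unstable, bookkeeping$n_baseline_unknown)

  # stage 4: statistics
  plan <- cfg$stats_plan
  report <- list(cohort = cohort, volumetry = volumetry,
                 bookkeeping = bookkeeping)
  post <- aff[aff$stability != "unknown_baseline", , drop = FALSE]
  if (isTRUE(plan$contingency)) {
    report$contingency <- {
      tab <- matrix(c(sum(post$hydrops & post$unstable),
                      sum(!post$hydrops & post$unstable),
                      sum(post$hydrops & !post$unstable),
                      sum(!post$hydrops & !post$unstable)), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        # degenerate at this cohort size (e.g. no unstable instance at all):
        # report the table, leave the statistics undefined
        note("contingency: degenerate table (empty marginal), OR undefined")
        list(table = tab, odds_ratio = NA_real_, p = NA_real_,
             ci95 = c(NA_real_, NA_real_), zero_cell = TRUE)
      } else {
        fe <- fisher_exact(tab)
        ci <- if (all(tab > 0)) or_confidence_interval(tab) else c(NA_real_, NA_real_)
        list(table = tab, odds_ratio = fe$odds_ratio, p = fe$p,
             ci95 = ci, zero_cell = fe$zero_cell)
      }
    }
  }
  if (isTRUE(plan$group_comparisons)) {
    report$group_comparisons <- tryCatch({
      out <- list()
      for (st in c("coch_ep", "vest_ep")) {
        groups <- list(hv = cohort[[st]][cohort$group == "hv"],
                       no_eh = aff[[st]][!aff$hydrops],
                       eh = aff[[st]][aff$hydrops])
        groups <- groups[vapply(groups, length, integer(1)) > 0]
        if (length(groups) >= 2) {
          out[[st]] <- list(kruskal = kruskal_wallis(groups),
                            posthoc = mann_whitney_posthoc(groups))
        }
      }
      out
    }, error = function(e) stop("stage group_comparisons: ",
                                conditionMessage(e), call. = FALSE))
  }
  if (isTRUE(plan$variance_comparisons)) {
    report$variance_comparisons <- tryCatch({
      aff$any_eh <- stats::ave(as.numeric(aff$hydrops),
                               interaction(aff$patient_id, aff$ear, drop = TRUE),
                               FUN = max) > 0
      aff$any_unstable <- stats::ave(as.numeric(aff$unstable %in% TRUE),
                                     interaction(aff$patient_id, aff$ear, drop = TRUE),
                                     FUN = max) > 0
      pv <- withCallingHandlers(
        per_ear_variance(aff, "vest_ep", carry = c("any_eh", "any_unstable")),
        warning = function(w) {
          note("variance: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      out <- list()
      for (g in c("any_eh", "any_unstable")) {
        out[[g]] <- tryCatch(variance_group_compare(pv, g),
                             error = function(e) NULL)
      }
      out
    }, error = function(e) stop("stage variance_comparisons: ",
                                conditionMessage(e), call. = FALSE))
  }
  if (isTRUE(plan$correlations)) {
    report$correlations <- tryCatch({
      out <- list()
      uns <- post[post$unstable %in% TRUE, , drop = FALSE]
      if (nrow(uns) >= 3 && stats::sd(uns$vest_ep) > 0 && stats::sd(uns$pta4) > 0) {
        out$vest_ep_vs_pta_unstable <- pearson_cor(uns$vest_ep, uns$pta4)
      }
      if (nrow(uns) >= 3 && stats::sd(uns$cum_shift) > 0) {
        dep <- ep_change_within_ear(post)
        uns2 <- merge(uns, dep, by = c("patient_id", "ear", "visit"))
        if (nrow(uns2) >= 3 && stats::sd(uns2$d_vest_ep) > 0) {
          out$d_vest_ep_vs_cum_shift_unstable <-
            pearson_cor(uns2$d_vest_ep, uns2$cum_shift)
        }
      }
      out
    }, error = function(e) stop("stage correlations: ", conditionMessage(e),
                                call. = FALSE))
  }
  if (isTRUE(plan$glmm)) {
    report$glmm <- tryCatch({
      fixed <- intersect(cfg$glmm_fixed, names(cohort))
      fit <- suppressWarnings(fit_gamma_glmm(cohort[cohort$pta4 > 0, , drop = FALSE],
                                             fixed = fixed))
      fit
    }, error = function(e) stop("stage glmm: ", conditionMessage(e),
                                call. = FALSE))
  }

  report$warnings <- notes
  report$provenance <- list(seed = cfg$seed,
                            config = cfg[setdiff(names(cfg), "out_dir")],
                            package_version = as.character(utils::packageVersion("earfluid")),
                            timestamp = NA)
  class(report) <- "analysis_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# Visit-to-visit change in vestibular E/P within each ear, keyed to the
# later visit (so it aligns with that visit's stability designation).
ep_change_within_ear <- function(cohort) {
  key <- interaction(cohort$patient_id, cohort$ear, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    sub <- cohort[key == k, , drop = FALSE]
    sub <- sub[order(sub$visit), , drop = FALSE]
    if (nrow(sub) < 2) next
    out[[k]] <- data.frame(patient_id = sub$patient_id[-1], ear = sub$ear[-1],
                           visit = sub$visit[-1],
                           d_vest_ep = diff(sub$vest_ep))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write an analysis report to disk
#'
#' Writes `cohort.csv` (scored instance table), `volumes.csv` (phantom
#' volumetry check), `designations.csv`, `report.json` (all statistics), and
#' `summary.txt`.
#'
#' @param report an `analysis_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_cohort_csv(report$cohort, file.path(out_dir, "cohort.csv"))
  if (!is.null(report$volumetry)) {
    utils::write.csv(report$volumetry, file.path(out_dir, "volumes.csv"),
                     row.names = FALSE)
  }
  des <- report$cohort[, c("patient_id", "ear", "visit", "stability",
                           "unstable", "cum_shift")]
  utils::write.csv(des, file.path(out_dir, "designations.csv"), row.names = FALSE)
  js <- report[setdiff(names(report), c("cohort", "glmm"))]
  if (!is.null(report$glmm)) {
    js$glmm <- list(coefficients = report$glmm$coefficients,
                    coefficients_scaled = report$glmm$coefficients_scaled,
                    shape = report$glmm$shape, re_var = as.list(report$glmm$re_var),
                    aic = report$glmm$aic, r2_marginal = report$glmm$r2_marginal,
                    r2_conditional = report$glmm$r2_conditional,
                    singular = report$glmm$singular)
  }
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(format_report(report), con)
  invisible(out_dir)
}

format_report <- function(report) {
  b <- report$bookkeeping
  lines <- c(
    "Inner-ear fluid pipeline report",
    sprintf("seed: %s", report$provenance$seed),
    sprintf("affected instances: %d (%d stable, %d unstable, %d baseline-unknown)",
            b$n_affected_instances, b$n_stable, b$n_unstable, b$n_baseline_unknown),
    sprintf("hydrops-positive affected instances: %d", b$n_hydrops),
    sprintf("HV instances: %d", b$n_hv_instances))
  if (!is.null(report$contingency)) {
    ci <- report$contingency$ci95
    lines <- c(lines, sprintf(
      "contingency (EH x instability): OR = %.2f, 95%% CI [%.1f, %.1f], p = %.3g",
      report$contingency$odds_ratio, ci[1], ci[2], report$contingency$p))
  }
  if (!is.null(report$glmm)) {
    lines <- c(lines, sprintf("GLMM: AIC %.1f, R2 marginal %.3f conditional %.3f",
                              report$glmm$aic, report$glmm$r2_marginal,
                              report$glmm$r2_conditional))
  }
  c(lines, "stage log:", paste(" -", report$warnings))
}

#' @export
print.analysis_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
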