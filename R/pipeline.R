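# End-to-end orchestration: cohort -> rate models -> reconstruction ->
# expectation -> O/E inference -> IPD analyses, with provenance written
# alongside every output.

#' Pipeline run configuration
#'
#' Validates paths and analysis settings for [run_pipeline()]. Can be
#' loaded from a YAML file via `run_config_from_yaml()`.
#'
#' @param cohort_path cohort CSV (required, must exist).
#' @param trial_summary_path aggregate trial CSV, or `NULL` to skip the
#'   aggregate analysis.
#' @param arm_path optional per-arm CSV for arm-level comparisons.
#' @param ipd_dir directory of IPD CSVs, or `NULL` to skip IPD analyses.
#' @param conditions index conditions to analyse; `NULL` = all found.
#' @param bases standardization bases: subset of
#'   `c("age_sex", "age_sex_mm")`.
#' @param comorbidity_map_path mapping TSV; required when medications
#'   must be converted to counts and the IPD has no `mm_count` column.
#' @param n_draws Monte-Carlo draws for intervals (default 1000).
#' @param seed master seed; every stochastic stage derives its seed from
#'   it and records it.
#' @param output_dir directory for result tables (created on run).
#' @param control_arm_only restrict observed counts to control arms when
#'   arm-level rows are available.
#' @param include_index_in_mm count the index-condition category in the
#'   multimorbidity count (default FALSE: comorbidities are conditions
#'   other than the index condition).
#' @param age_powers optional fixed FP powers for age (NULL = select).
#' @param permissive forwarded to the readers.
#' @return a validated `run_config` list.
#' @export
run_config <- function(cohort_path,
                       trial_summary_path = NULL,
                       arm_path = NULL,
                       ipd_dir = NULL,
                       conditions = NULL,
                       bases = c("age_sex"),
                       comorbidity_map_path = NULL,
                       n_draws = 1000,
                       seed = 1L,
                       output_dir = "saerep-output",
                       control_arm_only = FALSE,
                       include_index_in_mm = FALSE,
                       age_powers = NULL,
                       permissive = FALSE) {
  bases <- match.arg(bases, c("age_sex", "age_sex_mm"), several.ok = TRUE)
  for (p in c(cohort_path, trial_summary_path, arm_path,
              comorbidity_map_path)) {
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input path does not exist: %s", p), call. = FALSE)
  }
  if (!is.null(ipd_dir) && !dir.exists(ipd_dir))
    stop(sprintf("IPD directory does not exist: %s", ipd_dir),
         call. = FALSE)
  cfg <- list(cohort_path = cohort_path,
              trial_summary_path = trial_summary_path,
              arm_path = arm_path, ipd_dir = ipd_dir,
              conditions = conditions, bases = bases,
              comorbidity_map_path = comorbidity_map_path,
              n_draws = n_draws, seed = as.integer(seed),
              output_dir = output_dir,
              control_arm_only = control_arm_only,
              include_index_in_mm = include_index_in_mm,
              age_powers = age_powers, permissive = permissive)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file whose keys are `run_config()` arguments.
#' @export
run_config_from_yaml <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full observed/expected SAE pipeline
#'
#' Reads the configured inputs, fits sex-stratified rate models per
#' index condition and basis, computes expected SAE counts (aggregate
#' trials via reconstructed age bands, IPD trials via observed
#' participants), forms per-trial and pooled observed/expected ratios,
#' runs the IPD multimorbidity analyses where configured, and writes
#' all result tables plus a provenance JSON into `output_dir`. Any
#' stage failure aborts with the stage name; tables already written are
#' preserved.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) a list of the result tables, also written to
#'   `cfg$output_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if ("age_sex_mm" %in% cfg$bases && is.null(cfg$comorbidity_map_path)) {
    # counts may already be present; validated again at stage time
    cmap <- NULL
  } else if (!is.null(cfg$comorbidity_map_path)) {
    cmap <- load_comorbidity_map(cfg$comorbidity_map_path)
  } else cmap <- NULL
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  meta <- list(config_md5 = hash, seed = cfg$seed,
               package = as.character(utils::packageVersion("saerep")))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("read_cohort",
                  read_cohort(cfg$cohort_path, cfg$permissive))
  summaries <- if (!is.null(cfg$trial_summary_path))
    stage("read_trial_summaries",
          read_trial_summaries(cfg$trial_summary_path, cfg$permissive))
  arms <- if (!is.null(cfg$arm_path))
    stage("read_arms", read_csv_skip_comments(cfg$arm_path))
  ipd <- if (!is.null(cfg$ipd_dir))
    stage("read_trial_ipd", read_trial_ipd(cfg$ipd_dir, cfg$permissive))

  conditions <- cfg$conditions %||% unique(c(
    if (!is.null(summaries)) summaries$condition,
    if (!is.null(ipd)) vapply(ipd, function(d)
      d$condition[1] %||% NA_character_, character(1)),
    cohort$condition))
  conditions <- conditions[!is.na(conditions)]

  need_mm <- "age_sex_mm" %in% cfg$bases
  if (need_mm && !"mm_count" %in% names(cohort)) {
    if (is.null(cmap))
      stop("stage 'validate': basis age_sex_mm needs a comorbidity map or an mm_count column in the cohort",
           call. = FALSE)
    cohort$mm_count <- stage("count_comorbidities",
      count_comorbidities(split_medications(cohort$medications), cmap))
  }

  models <- stage("fit_rate_models", {
    out <- list()
    for (cond in conditions) {
      out[[cond]] <- list()
      for (basis in cfg$bases) {
        covs <- if (basis == "age_sex_mm") c("age", "mm_count") else "age"
        out[[cond]][[basis]] <- list(
          male = fit_rate_model(cohort, cond, "male", covs,
                                age_powers = cfg$age_powers),
          female = fit_rate_model(cohort, cond, "female", covs,
                                  age_powers = cfg$age_powers))
      }
    }
    out
  })

  results <- list(models = models)

  if (!is.null(summaries)) {
    oe_rows <- stage("aggregate_oe", {
      rows <- list()
      for (i in seq_len(nrow(summaries))) {
        s <- summaries[i, , drop = FALSE]
        if (!s$condition %in% names(models)) next
        obs <- s$sae_count
        if (cfg$control_arm_only && !is.null(arms)) {
          a <- arms[arms$trial_id == s$trial_id &
                      arms$designation == "placebo", , drop = FALSE]
          if (nrow(a) > 0L) obs <- sum(a$sae_count)
        }
        dist <- reconstruct_age_distribution(s)
        exp_c <- expected_events_aggregate(
          models[[s$condition]][["age_sex"]], dist, s$n_participants,
          s$followup_days, s$sae_count, n_draws = cfg$n_draws,
          seed = cfg$seed + i)
        r <- oe_ratio(obs, exp_c, n_draws = cfg$n_draws,
                      seed = cfg$seed + 10000L + i)
        rows[[i]] <- data.frame(
          trial_id = s$trial_id, condition = s$condition,
          observed = obs, expected = exp_c$expected,
          ratio = r$ratio, lower = r$lower, upper = r$upper,
          person_time_days = exp_c$person_time_days,
          flags = paste(dist$flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
    results$oe_trials <- oe_rows
    write_table_with_provenance(oe_rows,
                                file.path(cfg$output_dir, "oe_trials.csv"),
                                "oe_trials", meta)
    pooled <- stage("pool_oe", {
      do.call(rbind, lapply(split(oe_rows, oe_rows$condition), function(d) {
        p <- pool_oe(d$observed, d$expected, condition = d$condition[1])
        data.frame(condition = d$condition[1], k = p$k, ratio = p$ratio,
                   lower = p$lower, upper = p$upper, tau = p$tau,
                   stringsAsFactors = FALSE)
      }))
    })
    results$oe_pooled <- pooled
    write_table_with_provenance(pooled,
                                file.path(cfg$output_dir, "oe_pooled.csv"),
                                "oe_pooled", meta)
  }

  if (!is.null(arms)) {
    arm_rows <- stage("arm_comparisons", {
      do.call(rbind, lapply(split(arms, arms$trial_id), function(a) {
        cmp <- tryCatch(arm_log_rate_ratio(a), error = function(e) NULL)
        if (is.null(cmp)) return(NULL)
        data.frame(trial_id = a$trial_id[1], comparison = cmp$comparison,
                   log_rr = cmp$log_rr, se = cmp$se,
                   continuity = cmp$continuity, stringsAsFactors = FALSE)
      }))
    })
    results$arm_comparisons <- arm_rows
    if (!is.null(arm_rows))
      write_table_with_provenance(
        arm_rows, file.path(cfg$output_dir, "arm_comparisons.csv"),
        "arm_comparisons", meta)
  }

  if (!is.null(ipd)) {
    if (need_mm) {
      ipd <- stage("ipd_mm_counts", lapply(ipd, function(d) {
        if (!"mm_count" %in% names(d)) {
          if (is.null(cmap))
            stop("IPD lacks mm_count and no comorbidity map configured")
          d$mm_count <- count_comorbidities(
            split_medications(d$medications), cmap)
        }
        d
      }))
    }
    ipd_rows <- stage("ipd_oe", {
      rows <- lapply(seq_along(ipd), function(i) {
        d <- ipd[[i]]
        cond <- d$condition[1] %||% NA_character_
        if (!cond %in% names(models)) return(NULL)
        if (need_mm) {
          ds <- dual_standardization(d, models[[cond]][["age_sex"]],
                                     models[[cond]][["age_sex_mm"]],
                                     n_draws = cfg$n_draws,
                                     seed = cfg$seed + 20000L + i)
          cbind(condition = cond, ds$table)
        } else {
          e <- expected_events_ipd(models[[cond]][["age_sex"]], d,
                                   n_draws = cfg$n_draws,
                                   seed = cfg$seed + 20000L + i)
          r <- oe_ratio(sum(d$sae_count > 0), e, n_draws = cfg$n_draws,
                        seed = cfg$seed + 30000L + i)
          data.frame(condition = cond, trial_id = r$trial_id,
                     observed = r$observed,
                     expected_age_sex = e$expected,
                     ratio_age_sex = r$ratio, lower_age_sex = r$lower,
                     upper_age_sex = r$upper, stringsAsFactors = FALSE)
        }
      })
      do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    })
    results$ipd_oe <- ipd_rows
    write_table_with_provenance(ipd_rows,
                                file.path(cfg$output_dir, "ipd_oe.csv"),
                                "ipd_oe", meta)
    assoc <- stage("mm_associations", mm_association_table(ipd))
    results$mm_associations <- assoc
    write_table_with_provenance(
      assoc, file.path(cfg$output_dir, "mm_associations.csv"),
      "mm_associations", meta)
    if (nrow(assoc) >= 2L) {
      results$mm_pooled <- stage("mm_meta", {
        do.call(rbind, lapply(split(assoc, assoc$sex), function(d) {
          if (nrow(d) < 1L) return(NULL)
          m <- meta_analyze(d$coef, d$se)
          data.frame(sex = d$sex[1], k = m$k, coef = m$pooled,
                     se = m$se, lower = m$lower, upper = m$upper,
                     tau2 = m$tau2, stringsAsFactors = FALSE)
        }))
      })
      write_table_with_provenance(
        results$mm_pooled,
        file.path(cfg$output_dir, "mm_pooled.csv"), "mm_pooled", meta)
    }
  }

  prov <- c(list(config = unclass(cfg), config_md5 = hash,
                 r_version = R.version.string,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            list())
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(results)
}
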