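RESULTS_SCHEMA_VERSION <- "1"

#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis
#' pipeline.  Every field has a documented default and the object
#' round-trips through YAML ([read_run_config()]).
#'
#' @param panel path to a panel CSV, or an `arrest_panel`.
#' @param covariates optional path to a covariate CSV, or a data frame.
#' @param out_dir output directory (created if needed).
#' @param age_range analysis age restriction applied first, inclusive.
#' @param window age window for rate tables and the decomposition.
#' @param j_min,j_max candidate numbers of groups for model selection.
#' @param degree polynomial degree of the trajectory basis.
#' @param n_starts,seed,em_tol fitting settings shared by all candidates.
#' @param bic_n BIC sample-size convention (`"persons"` or
#'   `"person-periods"`).
#' @param cohort_map optional named vector collapsing cohort labels (e.g.
#'   `c("0" = "younger", "9" = "older", ...)`); the decomposition and
#'   permutation test require exactly two labels after mapping.
#' @param profiles named list of covariate profiles for
#'   [profile_probabilities()] (used when covariates are supplied).
#' @param at_means profile-probability convention flag.
#' @param drop_drug_only apply [drop_drug_only()] before fitting.
#' @param dense_windows require dense in-window rows when reading the panel.
#' @param by_offense add offense-specific columns to the rate table.
#' @return a validated `run_config` list.
#' @export
pipeline_config <- function(panel, covariates = NULL, out_dir,
                            age_range = c(10, 33), window = c(17, 24),
                            j_min = 2L, j_max = 4L, degree = 3L,
                            n_starts = 5L, seed = 1L, em_tol = 1e-8,
                            bic_n = "persons", cohort_map = NULL,
                            profiles = NULL, at_means = FALSE,
                            drop_drug_only = FALSE, dense_windows = TRUE,
                            by_offense = FALSE) {
  if (j_min > j_max) stop_arg("j_min must be <= j_max")
  if (age_range[1L] > age_range[2L]) stop_arg("invalid age_range")
  if (window[1L] > window[2L]) stop_arg("invalid window")
  cfg <- list(panel = panel, covariates = covariates, out_dir = out_dir,
              age_range = age_range, window = window,
              j_min = as.integer(j_min), j_max = as.integer(j_max),
              degree = as.integer(degree), n_starts = as.integer(n_starts),
              seed = as.integer(seed), em_tol = em_tol, bic_n = bic_n,
              cohort_map = cohort_map, profiles = profiles,
              at_means = at_means, drop_drug_only = drop_drug_only,
              dense_windows = dense_windows, by_offense = by_offense)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields of [pipeline_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full trajectory analysis pipeline
#'
#' Age restriction, model selection over the group-count grid, adequacy
#' diagnostics, covariate membership effects and profile probabilities
#' (when covariates are supplied), the within-group rate table, the
#' permutation test for the highest group, and the counterfactual
#' decomposition (when exactly two cohort labels are present after
#' mapping).  Writes a versioned machine-readable `results.json` plus CSV
#' tables (`selection.csv`, `adequacy.csv`, `rate_table.csv`,
#' `posterior.csv`, `curves.csv` with dense per-age rate predictions, and
#' `effects.csv` / `profiles.csv` when applicable) into `out_dir`.  A rerun
#' with an identical config and seed is byte-identical.  Any stage error
#' aborts the run, removes partial outputs, and names the failing stage.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @param quiet suppress stage log messages.
#' @return (invisibly) a list with the fitted objects and the results
#'   bundle.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) if (!quiet)
    message(sprintf("[%7.2fs] ", proc.time()[["elapsed"]] - t0), ...)
  created <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    created <<- c(created, path)
  }
  stage <- "setup"
  result <- tryCatch({
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "read_panel"
    panel <- if (inherits(config$panel, "arrest_panel")) config$panel
             else read_panel(config$panel, dense = config$dense_windows)
    covs <- config$covariates
    if (is.character(covs)) covs <- utils::read.csv(covs)
    if (!is.null(config$cohort_map))
      panel <- map_cohorts(panel, unlist(config$cohort_map))
    if (config$drop_drug_only) panel <- drop_drug_only(panel)

    stage <- "restrict_ages"
    panel <- restrict_ages(panel, config$age_range[1L], config$age_range[2L])
    log_stage("panel: ", length(unique(panel$person_id)), " persons, ",
              sum(panel$count), " arrests (seed ", config$seed, ")")

    stage <- "select_model"
    sel <- select_model(panel, covariates = covs,
                        J_range = config$j_min:config$j_max,
                        specs = list(trajectory_spec(degree = config$degree)),
                        bic_n = config$bic_n, seed = config$seed,
                        n_starts = config$n_starts, em_tol = config$em_tol,
                        se = !is.null(covs))
    if (is.na(sel$chosen)) stop("no candidate model converged")
    fit <- sel$fits[[sel$chosen]]
    log_stage("selected J = ", fit$model$J, ", loglik = ",
              format(fit$loglik), ", BIC = ", format(fit$bic))
    emit(sel$table, "selection.csv")

    stage <- "adequacy"
    adq <- adequacy(fit)
    emit(adq, "adequacy.csv")

    eff <- prof <- NULL
    if (!is.null(covs)) {
      stage <- "membership_effects"
      eff <- membership_effects(fit)
      emit(eff, "effects.csv")
      if (!is.null(config$profiles)) {
        stage <- "profile_probabilities"
        prof <- profile_probabilities(fit, config$profiles,
                                      at_means = config$at_means)
        emit(prof, "profiles.csv")
      }
    }

    stage <- "rate_table"
    rt <- suppressMessages(
      rate_table(panel, fit$assignments, config$window,
                 by_offense = config$by_offense))
    emit(rt, "rate_table.csv")

    stage <- "curves"
    grid <- seq(min(panel$age), max(panel$age))
    curves <- data.frame(age = rep(grid, fit$model$J),
                         group = rep(seq_len(fit$model$J), each = length(grid)))
    curves$rate <- unlist(lapply(seq_len(fit$model$J), function(j)
      rate(fit$model, j, grid)), use.names = FALSE)
    emit(curves, "curves.csv")
    post_df <- data.frame(person_id = rownames(fit$posterior),
                          fit$posterior,
                          assigned = unname(fit$assignments))
    emit(post_df, "posterior.csv")

    decomp <- ptest <- NULL
    cohorts <- sort(unique(panel$cohort))
    # decomposition orientation: "younger" label if present, else the
    # lexicographically second label plays the younger role
    if (length(cohorts) == 2L && "younger" %in% cohorts)
      cohorts <- c(setdiff(cohorts, "younger"), "younger")
    if (length(cohorts) == 2L) {
      stage <- "decompose"
      hi <- fit$model$J
      w <- panel_windows(panel)
      covered <- w$person_id[w$min_age <= config$window[1L] &
                               w$max_age >= config$window[2L]]
      sub_assign <- fit$assignments[covered]
      shares <- lapply(cohorts, function(cl) {
        in_c <- w$cohort[match(covered, w$person_id)] == cl
        tabulate(sub_assign[in_c], nbins = fit$model$J) / sum(in_c)
      })
      rts <- lapply(cohorts, function(cl) {
        r <- rt$rate[rt$cohort == cl][order(rt$group[rt$cohort == cl])]
        if (length(r) != fit$model$J)
          stop("empty (group, cohort) cell; decomposition undefined")
        r
      })
      decomp <- decompose(shares[[2L]], rts[[2L]], shares[[1L]], rts[[1L]],
                          target_group = hi)
      stage <- "permutation_test"
      ptest <- permutation_test(panel, fit$assignments, hi, config$window,
                                n_perm = 999L, seed = config$seed)
      log_stage("decomposition gap = ", format(decomp$gap),
                "; high-group permutation p = ", format(ptest$p_value))
    } else {
      log_stage("skipping decomposition (", length(cohorts),
                " cohort labels; supply cohort_map for two)")
    }

    stage <- "write_results"
    results <- list(
      schema_version = RESULTS_SCHEMA_VERSION,
      seed = config$seed,
      settings = config[c("age_range", "window", "j_min", "j_max", "degree",
                          "n_starts", "em_tol", "bic_n", "at_means",
                          "drop_drug_only", "by_offense")],
      selection = sel$table,
      chosen_J = fit$model$J,
      loglik = fit$loglik, bic = fit$bic, n_params = fit$n_params,
      converged = fit$converged,
      beta = fit$model$beta, theta = fit$model$theta,
      membership_shares = colMeans(fit$posterior),
      adequacy = adq,
      effects = eff, profiles = prof,
      rate_table = rt,
      decomposition = if (!is.null(decomp)) unclass(decomp),
      permutation_test = ptest)
    res_path <- file.path(config$out_dir, "results.json")
    jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, matrix = "rowmajor")
    created <- c(created, res_path)
    log_stage("wrote ", length(created) + 0, " artifact(s) to ",
              config$out_dir)
    list(fit = fit, selection = sel, adequacy = adq, effects = eff,
         profiles = prof, rate_table = rt, decomposition = decomp,
         permutation_test = ptest, results = results, files = created)
  }, error = function(e) {
    unlink(created)
    unlink(file.path(config$out_dir, "results.json"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Load a pipeline results bundle
#'
#' Fails loudly on a schema-version mismatch rather than silently
#' reinterpreting an older report.
#'
#' @param path path to a `results.json` written by [run_pipeline()].
#' @export
read_results <- function(path) {
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(res$schema_version, RESULTS_SCHEMA_VERSION))
    stop_arg("results schema version '", res$schema_version,
             "' does not match this package's version '",
             RESULTS_SCHEMA_VERSION, "'")
  res
}
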