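#' Default regression model battery
#'
#' The study's model set: the main stepwise model (RNT composite on age,
#' sex, DASS, emotional stability, cognitive complaints and the five
#' network segregation terms), one model per RNT questionnaire (RRS,
#' brooding subscale, PSWQ, PTQ), the two post-hoc connectivity models
#' (within-LECN/within-ASN plus the LECN/ASN pairwise connectivity terms
#' with the retained covariates), and the reversed model with DASS as the
#' outcome.
#'
#' @return Named list of model specs (`outcome`, `candidates`).
#' @export
default_model_specs <- function() {
  base_cand <- c("age", "sex", "dass", "emotional_stability",
                 "cognitive_complaints", "sys_asn", "sys_ddmn", "sys_vdmn",
                 "sys_lecn", "sys_recn")
  posthoc_cand <- c("within_lecn", "within_asn", "fc_lecn_asn",
                    "fc_lecn_ddmn", "fc_lecn_vdmn", "fc_asn_ddmn",
                    "fc_asn_vdmn", "dass", "emotional_stability",
                    "cognitive_complaints", "age")
  list(
    main = list(outcome = "rnt", candidates = base_cand),
    rrs = list(outcome = "rrs", candidates = base_cand),
    brooding = list(outcome = "brooding", candidates = base_cand),
    pswq = list(outcome = "pswq", candidates = base_cand),
    ptq = list(outcome = "ptq", candidates = base_cand),
    posthoc_rnt = list(outcome = "rnt", candidates = posthoc_cand),
    posthoc_ptq = list(outcome = "ptq", candidates = posthoc_cand),
    reversed_dass = list(outcome = "dass",
                         candidates = c("rnt", "sex", "age",
                                        "emotional_stability",
                                        "cognitive_complaints", "sys_asn",
                                        "sys_ddmn", "sys_vdmn", "sys_lecn",
                                        "sys_recn"))
  )
}

#' Configure a pipeline run
#'
#' @param seed Seed forwarded to the synthetic generator.
#' @param input `"synthetic"` (default) or `"files"`. With `"files"`,
#'   supply `timeseries_dir` (one `<subject>.csv` of T x R signals per
#'   subject), `parcellation_path` (roi,network CSV) and `cohort_path`
#'   (per-subject behavioural totals incl. `subject`, `age`, `sex`, `ptq`,
#'   `pswq`, `rrs`, `dass`, `cognitive_complaints`, `emotional_stability`).
#' @param simulation A [simulation_config()] (synthetic mode). If `NULL`, a
#'   default one is built with `seed`.
#' @param models Model battery, default [default_model_specs()].
#' @param alpha_enter,ci_level Stepwise entry alpha and CI level.
#' @param sex_ttest Run the two-sample t test of the RNT composite between
#'   sexes?
#' @param write_timeseries Persist per-subject time-series CSVs (synthetic
#'   mode)?
#' @param timeseries_dir,parcellation_path,cohort_path File-mode inputs.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, input = c("synthetic", "files"),
                       simulation = NULL, models = default_model_specs(),
                       alpha_enter = 0.05, ci_level = 0.99,
                       sex_ttest = TRUE, write_timeseries = FALSE,
                       timeseries_dir = NULL, parcellation_path = NULL,
                       cohort_path = NULL) {
  input <- match.arg(input)
  if (input == "synthetic" && is.null(simulation)) {
    simulation <- simulation_config(seed = seed)
  }
  if (input == "files" &&
      (is.null(timeseries_dir) || is.null(parcellation_path) ||
       is.null(cohort_path))) {
    abort("File input needs timeseries_dir, parcellation_path, cohort_path.",
          class = "sysseg_validation_error")
  }
  structure(list(seed = as.integer(seed), input = input,
                 simulation = simulation, models = models,
                 alpha_enter = alpha_enter, ci_level = ci_level,
                 sex_ttest = sex_ttest, write_timeseries = write_timeseries,
                 timeseries_dir = timeseries_dir,
                 parcellation_path = parcellation_path,
                 cohort_path = cohort_path),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; the `simulation`
#' block mirrors [simulation_config()] (its `parcellation` entry may be a
#' path to a roi,network CSV).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sa <- raw$simulation
    if (!is.null(sa$parcellation)) {
      sa$parc <- read_parcellation(sa$parcellation)
      sa$parcellation <- NULL
    }
    if (!is.null(sa$behavioral$sys)) {
      sa$behavioral$sys <- unlist(sa$behavioral$sys)
    }
    sim <- do.call(simulation_config, sa)
  }
  args <- raw[setdiff(names(raw), "simulation")]
  args$simulation <- sim
  do.call(run_config, args)
}

# 10-significant-digit float formatting for reproducible CSV output
format_numeric_cols <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.numeric),
    function(x) {
      out <- formatC(x, digits = 10, format = "g")
      whole <- !is.na(x) & x == round(x) & abs(x) < 1e15
      out[whole] <- format(x[whole], scientific = FALSE, trim = TRUE)
      out[is.na(x)] <- NA_character_
      out
    }))
}

write_table <- function(df, path) {
  readr::write_csv(format_numeric_cols(df), path)
  path
}

model_table <- function(fit) {
  tab <- dplyr::filter(tidy(fit), .data$term != "(Intercept)")
  tibble::tibble(variable = tab$term, beta = tab$estimate,
                 se = tab$std_error, t = tab$statistic, p = tab$p_value,
                 ci99_low = tab$conf_low, ci99_high = tab$conf_high)
}

trace_table <- function(fit, outcome_label) {
  tr <- fit$trace
  tibble::tibble(outcome = rep(outcome_label, nrow(tr)), step = tr$step,
                 variable = tr$variable, adj_r2 = tr$adj_r_squared,
                 t = tr$statistic, p = tr$p_value)
}

load_file_inputs <- function(config) {
  parc <- read_parcellation(config$parcellation_path)
  files <- list.files(config$timeseries_dir, pattern = "\\.(csv|tsv)$",
                      full.names = TRUE)
  if (length(files) == 0) {
    abort("stage connectivity: no time-series files found.",
          class = "sysseg_validation_error")
  }
  ts_list <- setNames(purrr::map(files, read_timeseries),
                      tools::file_path_sans_ext(basename(files)))
  seg <- cohort_network_summary(ts_list, parc)
  pw <- purrr::imap(ts_list, function(ts, id) {
    out <- pairwise_connectivity(compute_connectivity(ts), parc)
    dplyr::mutate(out, subject = id, .before = 1)
  }) |> dplyr::bind_rows()
  cohort <- readr::read_csv(config$cohort_path, show_col_types = FALSE)
  wide_sys <- tidyr::pivot_wider(
    seg, id_cols = "subject", names_from = "network",
    values_from = c("sys", "w"), names_glue = "{.value}_{tolower(network)}")
  names(wide_sys) <- sub("^w_", "within_", names(wide_sys))
  wide_pw <- tidyr::pivot_wider(
    dplyr::filter(pw, .data$net_a < .data$net_b),
    id_cols = "subject", names_from = c("net_a", "net_b"),
    values_from = "fc",
    names_glue = "fc_{tolower(net_a)}_{tolower(net_b)}")
  cohort <- dplyr::left_join(cohort, wide_sys, by = "subject")
  cohort <- dplyr::left_join(cohort, wide_pw, by = "subject")
  cohort <- rnt_composite(cohort)
  list(cohort = cohort, segregation = seg, pairwise = pw)
}

#' Run the full analysis pipeline and persist its outputs
#'
#' Orchestrates simulate (or load) -> connectivity -> psychometric scoring
#' -> stepwise regressions, writing every intermediate and final artifact
#' to `out_dir`: `segregation.csv` and `pairwise.csv` (per subject),
#' `cohort.csv`, one `model_<name>.csv` per regression (columns `variable`,
#' `beta`, `se`, `t`, `p`, `ci99_low`, `ci99_high`), a combined step trace
#' `steps.csv` (`outcome`, `step`, `variable`, `adj_r2`, `t`, `p`),
#' `ttest.csv`, `truth.csv` (synthetic mode) and `manifest.json` (seed,
#' config hash, package version). Outputs are a pure function of
#' (config, seed): rerunning with the same configuration gives
#' byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage-level progress?
#' @return Invisibly, a list with the cohort table, fitted models, t-test
#'   table and the vector of files written.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- character()

  if (config$input == "synthetic") {
    say("stage simulate: ", config$simulation$n_subjects, " subjects")
    sim <- simulate_cohort(config$simulation,
                           return_timeseries = config$write_timeseries)
    cohort <- sim$cohort
    seg <- sim$segregation
    pw <- sim$pairwise
    files <- c(files, write_table(sim$truth, file.path(out_dir, "truth.csv")))
    if (config$write_timeseries) {
      ts_dir <- file.path(out_dir, "timeseries")
      dir.create(ts_dir, showWarnings = FALSE)
      for (id in names(sim$timeseries)) {
        files <- c(files, write_table(
          tibble::as_tibble(sim$timeseries[[id]]),
          file.path(ts_dir, paste0(id, ".csv"))))
      }
    }
  } else {
    say("stage connectivity: reading ", config$timeseries_dir)
    loaded <- load_file_inputs(config)
    cohort <- loaded$cohort
    seg <- loaded$segregation
    pw <- loaded$pairwise
  }

  say("stage connectivity: writing per-subject summaries")
  files <- c(files,
             write_table(seg, file.path(out_dir, "segregation.csv")),
             write_table(pw, file.path(out_dir, "pairwise.csv")),
             write_table(cohort, file.path(out_dir, "cohort.csv")))

  say("stage inference: ", length(config$models), " models on ",
      nrow(cohort), " subjects")
  fits <- list()
  traces <- list()
  for (nm in names(config$models)) {
    ms <- config$models[[nm]]
    missing_cols <- setdiff(c(ms$outcome, ms$candidates), names(cohort))
    if (length(missing_cols) > 0) {
      abort(paste0("stage inference [", nm, "]: missing columns ",
                   paste(missing_cols, collapse = ", ")),
            class = "sysseg_validation_error")
    }
    fit <- forward_stepwise(cohort, ms$outcome, ms$candidates,
                            alpha_enter = config$alpha_enter,
                            ci_level = config$ci_level)
    fits[[nm]] <- fit
    traces[[nm]] <- trace_table(fit, nm)
    files <- c(files, write_table(model_table(fit),
                                  file.path(out_dir,
                                            paste0("model_", nm, ".csv"))))
  }
  files <- c(files, write_table(dplyr::bind_rows(traces),
                                file.path(out_dir, "steps.csv")))

  ttest <- NULL
  if (isTRUE(config$sex_ttest)) {
    groups <- split(cohort$rnt, cohort$sex)
    ttest <- two_sample_ttest(groups[["1"]], groups[["0"]])
    names(ttest)[names(ttest) == "mean_a"] <- "mean_female"
    names(ttest)[names(ttest) == "mean_b"] <- "mean_male"
    files <- c(files, write_table(ttest, file.path(out_dir, "ttest.csv")))
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("sysseg")),
    input = config$input,
    n_subjects = nrow(cohort),
    models = names(config$models),
    generator = if (config$input == "synthetic") {
      list(r_within = as.list(config$simulation$r_within),
           r_between = config$simulation$r_between,
           behavioral = config$simulation$behavioral,
           t_points = config$simulation$t_points)
    }
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, manifest_path)
  say("done: ", length(files), " files in ", out_dir)
  invisible(list(cohort = cohort, fits = fits, ttest = ttest,
                 files = files))
}
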