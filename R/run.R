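# Configuration-driven analysis runs: load -> exclude -> directional
# filter -> chosen non-directional test, with serialised, reproducible
# results.

#' Read a run configuration from YAML or JSON
#'
#' A run configuration mirrors all CLI flags and fully determines a run:
#' `input` (path), `columns` (mapping of `participant`, `condition`,
#' `outcome`, optional `condition2`/`accuracy`/`confidence`/`signal`),
#' `condition_levels`, `statistic`, `method` (one of `sign_consistency`,
#' `absolute_es`, `gnt`, `oanova`), `params` (`n_splits`, `M`, `B`,
#' `alpha_individual`, `alpha_prevalence`, `min_trials`, `seed`), and
#' `output` (file prefix).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run a configured non-directional analysis
#'
#' Executes the full pipeline: load the trial table, apply the exclusion
#' rules, report the directional sign-flipping filter test, then run the
#' configured non-directional test. Writes a JSON result embedding the
#' complete configuration (audit trail), the package version and the seed,
#' plus CSVs of the exclusion report and any per-participant scores.
#' The directional test is always reported alongside the non-directional
#' result, which complements rather than replaces it; interpreting both
#' raises an obvious multiple-testing concern that is noted in the log.
#'
#' @param config A list or `run_config` (see [read_run_config()]), or a
#'   path to a config file.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with the test result, directional filter,
#'   exclusion report and output paths.
#' @export
run_nondir <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  say <- function(...) if (!quiet) message(...)
  need <- function(field) {
    if (is.null(config[[field]])) {
      stop("run config is missing required field `", field, "`",
           call. = FALSE)
    }
    config[[field]]
  }
  input <- need("input")
  method <- match.arg(need("method"),
                      c("sign_consistency", "absolute_es", "gnt", "oanova"))
  cols <- config$columns %||% list()
  pars <- config$params %||% list()
  stat_name <- config$statistic %||%
    if (method == "absolute_es") "cohen_d" else "mean_diff"
  spec <- statistic_spec(stat_name)
  seed <- pars$seed %||% NULL
  out_prefix <- config$output %||% sub("\\.[^.]+$", "", input)

  say("stage load: ", input)
  tt <- withCallingHandlers(
    read_trial_table(
      input,
      participant = cols$participant %||% "participant",
      condition = cols$condition %||% "condition",
      outcome = cols$outcome %||% "outcome",
      condition2 = cols$condition2,
      accuracy = cols$accuracy,
      confidence = cols$confidence,
      signal = cols$signal,
      condition_levels = config$condition_levels),
    error = function(e) stop("stage load: ", conditionMessage(e),
                             call. = FALSE))

  say("stage exclusions (min_trials = ", pars$min_trials %||% 5, ")")
  excl <- tryCatch(apply_exclusions(tt, min_trials = pars$min_trials %||% 5),
                   error = function(e) stop("stage exclusions: ",
                                            conditionMessage(e),
                                            call. = FALSE))
  tt <- excl$table
  excl_path <- paste0(out_prefix, "_exclusions.csv")
  utils::write.csv(excl$report, excl_path, row.names = FALSE)
  if (!quiet) print(excl)

  say("stage directional filter: sign-flipping test on the population mean")
  filt_spec <- if (stat_name %in% c("mean_diff", "cohen_d")) {
    statistic_spec("mean_diff")
  } else {
    spec
  }
  directional <- sign_flip_test(participant_effects(tt, filt_spec),
                                seed = seed)
  if (!quiet) print(directional)
  if (directional$p.value < 0.05) {
    say("note: significant directional effect; a non-directional test ",
        "complements rather than replaces it (two tests are being ",
        "interpreted on one dataset)")
  }

  say("stage test: ", method)
  result <- tryCatch(switch(method,
    sign_consistency = sign_consistency_test(
      tt, spec = spec, n_splits = pars$n_splits %||% 500,
      M = pars$M %||% 100, B = pars$B %||% 10000, seed = seed),
    absolute_es = absolute_es_test(
      tt, spec = spec, M = pars$M %||% 100, B = pars$B %||% 10000,
      seed = seed),
    gnt = gnt_test(
      tt, method = pars$individual_method %||% "t",
      alpha_individual = pars$alpha_individual %||% 0.05,
      alpha_prevalence = pars$alpha_prevalence %||% 0.05, seed = seed),
    oanova = oanova_test(tt)),
    error = function(e) stop("stage test (", method, "): ",
                             conditionMessage(e), call. = FALSE))
  if (!quiet) print(result)

  json_path <- paste0(out_prefix, "_result.json")
  payload <- list(
    package = "nondirtest",
    version = as.character(utils::packageVersion("nondirtest")),
    config = unclass(config),
    seed = seed,
    exclusions = excl$report,
    directional_filter = list(statistic = directional$statistic,
                              p.value = directional$p.value,
                              exhaustive = directional$exhaustive),
    result = serialise_result(result))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(result = json_path, exclusions = excl_path)
  if (!is.null(result$per_participant)) {
    pp_path <- paste0(out_prefix, "_participants.csv")
    utils::write.csv(result$per_participant, pp_path, row.names = FALSE)
    paths["participants"] <- pp_path
  }
  say("wrote: ", paste(paths, collapse = ", "))
  invisible(list(result = result, directional = directional,
                 exclusions = excl, paths = paths))
}

#' Run one configuration over a directory of datasets
#'
#' Applies [run_nondir()] to every file in `dir` matching `pattern`, using
#' the same configuration (its `input` field is replaced per file), and
#' collects one summary row per dataset.
#'
#' @param dir Directory of delimited trial tables.
#' @param config As in [run_nondir()], minus `input`.
#' @param pattern Filename regexp (default `"\\.csv$"`).
#' @param quiet Suppress per-run messages (default TRUE).
#' @return A data.frame with one row per dataset: `file`, `method`,
#'   `statistic`, `p.value`, `directional_p`.
#' @export
run_nondir_batch <- function(dir, config, pattern = "\\.csv$",
                             quiet = TRUE) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- read_run_config(config)
  }
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stop("no datasets match in ", dir, call. = FALSE)
  rows <- lapply(files, function(f) {
    cfg <- config
    cfg$input <- f
    res <- run_nondir(cfg, quiet = quiet)
    r <- res$result
    stat <- if (!is.null(r$statistic)) r$statistic else r$prevalence
    data.frame(file = basename(f), method = config$method,
               statistic = stat, p.value = r$p.value,
               directional_p = res$directional$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

serialise_result <- function(r) {
  if (inherits(r, "nondir_result")) {
    list(method = r$method, statistic = r$statistic, p.value = r$p.value,
         params = r$params, per_participant = r$per_participant)
  } else if (inherits(r, "prevalence_result")) {
    list(method = "gnt", n = r$n, k = r$k, prevalence = r$prevalence,
         ci_lower = r$ci_lower, p.value = r$p.value,
         alpha_individual = r$alpha_individual,
         alpha_prevalence = r$alpha_prevalence,
         individual = r$individual)
  } else if (inherits(r, "oanova_result")) {
    list(method = "oanova", F = r$statistic, df1 = r$df1, df2 = r$df2,
         p.value = r$p.value, sse_full = r$sse_full,
         sse_reduced = r$sse_reduced)
  } else {
    unclass(r)
  }
}
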