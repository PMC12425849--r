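#' Construct a validated trial-level table
#'
#' A `trial_table` is the universal input to every test in the package: one
#' row per trial, with a participant identifier, a two-level condition
#' factor, and a numeric outcome (e.g., a reaction time in ms, a confidence
#' rating, or a binary response coded 0/1). Optional columns support the
#' signal-detection and metacognition statistics (`accuracy`, `confidence`,
#' `signal`) and interaction contrasts (`condition2`).
#'
#' The order of `condition_levels` defines the sign convention for every
#' downstream signed statistic: the *second* level is the "positive"
#' condition (e.g., `c("congruent", "incongruent")` makes a positive mean
#' difference mean slower incongruent responses). The ordering is taken from
#' an explicit declaration, never from file or factor order, so that sign
#' conventions are reproducible across files.
#'
#' @param data A data.frame with one row per trial.
#' @param participant,condition,outcome Names of the mandatory columns in
#'   `data`.
#' @param condition2,accuracy,confidence,signal Optional column names:
#'   a second two-level factor (interaction designs), a 0/1 correctness
#'   flag, an ordinal confidence rating, and a 0/1 signal-class indicator
#'   (for d-prime).
#' @param condition_levels Character vector of length 2 declaring the
#'   condition levels in `(reference, positive)` order. Defaults to the
#'   sorted unique values, with a message, since relying on an implicit
#'   order is fragile.
#' @param condition2_levels As `condition_levels`, for `condition2`.
#'
#' @return A data.frame of class `trial_table` with standardised columns
#'   `participant`, `condition` (factor, 2 levels), `outcome`, and any of
#'   `condition2`, `accuracy`, `confidence`, `signal` that were mapped.
#'
#' @examples
#' d <- data.frame(subj = rep(1:3, each = 4),
#'                 cond = rep(c("cong", "incong"), 6),
#'                 rt = rnorm(12, 500, 50))
#' tt <- trial_table(d, participant = "subj", condition = "cond",
#'                   outcome = "rt",
#'                   condition_levels = c("cong", "incong"))
#' @export
trial_table <- function(data, participant = "participant",
                        condition = "condition", outcome = "outcome",
                        condition2 = NULL, accuracy = NULL,
                        confidence = NULL, signal = NULL,
                        condition_levels = NULL, condition2_levels = NULL) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data.frame of trials", call. = FALSE)
  }
  mapped <- c(participant = participant, condition = condition,
              outcome = outcome, condition2 = condition2,
              accuracy = accuracy, confidence = confidence, signal = signal)
  missing_cols <- setdiff(unname(mapped), names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in `data`: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  out <- data.frame(participant = as.character(data[[participant]]),
                    stringsAsFactors = FALSE)

  out$condition <- declare_factor(data[[condition]], condition_levels,
                                  "condition")

  raw_outcome <- data[[outcome]]
  num_outcome <- suppressWarnings(as.numeric(as.character(raw_outcome)))
  bad <- which(is.na(num_outcome) & !is.na(raw_outcome))
  if (length(bad) > 0) {
    stop("non-numeric outcome value at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  nonfinite <- which(!is.finite(num_outcome))
  if (length(nonfinite) > 0) {
    stop("outcome is missing or non-finite at row(s) ",
         paste(utils::head(nonfinite, 5), collapse = ", "),
         if (length(nonfinite) > 5) " ..." else "", call. = FALSE)
  }
  out$outcome <- num_outcome

  if (!is.null(condition2)) {
    out$condition2 <- declare_factor(data[[condition2]], condition2_levels,
                                     "condition2")
  }
  for (col in c("accuracy", "signal")) {
    src <- mapped[col]
    if (!is.na(src)) {
      v <- as.numeric(data[[src]])
      if (!all(v %in% c(0, 1) | is.na(v))) {
        stop("`", col, "` column must be coded 0/1", call. = FALSE)
      }
      out[[col]] <- v
    }
  }
  if (!is.null(confidence)) {
    out$confidence <- as.numeric(data[[confidence]])
  }

  class(out) <- c("trial_table", "data.frame")
  out
}

declare_factor <- function(x, levels, what) {
  x <- as.character(x)
  obs <- unique(x[!is.na(x)])
  if (is.null(levels)) {
    levels <- sort(obs)
    if (length(levels) == 2) {
      message("`", what, "_levels` not declared; using sorted order (",
              paste(levels, collapse = " < "), "), where the second level ",
              "is the positive condition")
    }
  }
  if (length(levels) != 2 || length(obs) > 2 || !all(obs %in% levels)) {
    stop("`", what, "` must have exactly 2 levels; found: ",
         paste(sort(obs), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = levels)
}

#' Read a trial table from a delimited text file
#'
#' Thin wrapper around [utils::read.csv()]/[utils::read.delim()] (chosen by
#' file extension, or forced with `sep`) followed by [trial_table()]
#' validation.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param sep Field separator; by default `"\t"` for `.tsv`/`.txt`, `","`
#'   otherwise.
#' @inheritParams trial_table
#' @param ... Further column mappings passed to [trial_table()]
#'   (`condition2`, `accuracy`, `confidence`, `signal`, `*_levels`).
#' @return A validated [trial_table()].
#' @export
read_trial_table <- function(path, participant = "participant",
                             condition = "condition", outcome = "outcome",
                             sep = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  trial_table(raw, participant = participant, condition = condition,
              outcome = outcome, ...)
}

#' @export
print.trial_table <- function(x, ...) {
  np <- length(unique(x$participant))
  cat("Trial table: ", nrow(x), " trials, ", np, " participants\n", sep = "")
  cat("  condition levels (reference, positive): ",
      paste(levels(x$condition), collapse = ", "), "\n", sep = "")
  if (!is.null(x$condition2)) {
    cat("  condition2 levels: ",
        paste(levels(x$condition2), collapse = ", "), "\n", sep = "")
  }
  extra <- intersect(c("accuracy", "confidence", "signal"), names(x))
  if (length(extra) > 0) {
    cat("  extra columns: ", paste(extra, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# condition cells of a participant's trials: condition, or condition x
# condition2 when a second factor is present
cell_index <- function(trials) {
  if (!is.null(trials$condition2)) {
    interaction(trials$condition, trials$condition2, drop = FALSE)
  } else {
    trials$condition
  }
}

#' Apply the participant exclusion rules
#'
#' Drops participants with fewer than `min_trials` trials in any
#' experimental condition cell, and participants with zero variance in the
#' outcome across all their trials (e.g., an accuracy score that is
#' constant). With a second factor present, the per-cell rule applies to
#' each factor combination. The zero-variance rule is evaluated globally
#' over the participant's trials: a participant constant within one
#' condition but not the other still carries information.
#'
#' @param x A [trial_table()].
#' @param min_trials Minimum number of trials required in every condition
#'   cell (default 5).
#' @return A list of class `exclusion_result` with elements `table` (the
#'   retained [trial_table()]) and `report` (a data.frame with one row per
#'   participant: minimum cell count, outcome variance, `excluded` flag and
#'   `reason`).
#' @examples
#' tt <- simulate_scenario(sigma_b = 15, sigma_w = 30, n_participants = 5,
#'                         n_trials = 10, seed = 1)
#' apply_exclusions(tt)$report
#' @export
apply_exclusions <- function(x, min_trials = 5) {
  stopifnot(inherits(x, "trial_table"))
  ids <- sort(unique(x$participant))
  cells <- cell_index(x)
  n_cells <- nlevels(cells)

  report <- do.call(rbind, lapply(ids, function(id) {
    rows <- x$participant == id
    counts <- table(cells[rows])
    v <- stats::var(x$outcome[rows])
    if (is.na(v)) v <- 0  # single trial: no spread to analyse
    low_n <- any(counts < min_trials)
    zero_var <- v == 0
    reason <- paste(c(if (low_n) "min_trials",
                      if (zero_var) "zero_variance"), collapse = "; ")
    data.frame(participant = id,
               n_trials = sum(rows),
               min_cell_n = min(counts),
               outcome_variance = v,
               excluded = low_n || zero_var,
               reason = if (reason == "") NA_character_ else reason,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL

  keep <- report$participant[!report$excluded]
  if (length(keep) == 0) {
    stop("empty analysis set: all ", length(ids),
         " participants excluded (min_trials = ", min_trials, ")",
         call. = FALSE)
  }
  retained <- x[x$participant %in% keep, , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- class(x)
  structure(list(table = retained, report = report,
                 min_trials = min_trials, n_cells = n_cells),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  n_excl <- sum(x$report$excluded)
  cat("Exclusion report: ", n_excl, " of ", nrow(x$report),
      " participants excluded (min_trials = ", x$min_trials, ")\n", sep = "")
  if (n_excl > 0) {
    excl <- x$report[x$report$excluded, c("participant", "reason")]
    for (i in seq_len(nrow(excl))) {
      cat("  - ", excl$participant[i], ": ", excl$reason[i], "\n", sep = "")
    }
  }
  invisible(x)
}

# Split a trial table into a named list of per-participant data.frames,
# in sorted participant order (the canonical iteration order everywhere).
split_participants <- function(x) {
  ids <- sort(unique(x$participant))
  out <- lapply(ids, function(id) x[x$participant == id, , drop = FALSE])
  names(out) <- ids
  out
}

# Analysis-entry check: every participant needs >= min_per_cell trials in
# every condition cell (tests are undefined otherwise).
check_cells <- function(x, min_per_cell = 1) {
  cells <- cell_index(x)
  counts <- table(x$participant, cells)
  bad <- rownames(counts)[apply(counts, 1, min) < min_per_cell]
  if (length(bad) > 0) {
    stop("participant(s) with fewer than ", min_per_cell,
         " trial(s) in a condition cell: ", paste(bad, collapse = ", "),
         "; run apply_exclusions() first", call. = FALSE)
  }
  invisible(TRUE)
}
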