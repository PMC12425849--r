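write_sim_csv <- function(path, seed, n_participants = 6, n_trials = 12) {
  tt <- simulate_scenario(15, 30, n_participants = n_participants,
                          n_trials = n_trials, seed = seed)
  write.csv(as.data.frame(tt), path, row.names = FALSE)
  path
}

base_config <- function(input, out_prefix) {
  list(input = input,
       method = "sign_consistency",
       statistic = "mean_diff",
       columns = list(participant = "participant",
                      condition = "condition", outcome = "outcome"),
       condition_levels = c("congruent", "incongruent"),
       params = list(n_splits = 100, M = 40, B = 500, seed = 7),
       output = out_prefix)
}

test_that("a configured run is reproducible and fully serialised", {
  dir <- withr::local_tempdir()
  input <- write_sim_csv(file.path(dir, "data.csv"), seed = 19)
  cfg <- base_config(input, file.path(dir, "run1"))

  r1 <- run_nondir(cfg, quiet = TRUE)
  cfg$output <- file.path(dir, "run2")
  r2 <- run_nondir(cfg, quiet = TRUE)
  expect_identical(r1$result$p.value, r2$result$p.value)
  expect_identical(r1$directional$p.value, r2$directional$p.value)

  # result JSON embeds the complete config, version and seed
  payload <- jsonlite::read_json(r1$paths[["result"]],
                                 simplifyVector = TRUE)
  expect_equal(payload$config$params$seed, 7)
  expect_equal(payload$config$method, "sign_consistency")
  expect_equal(payload$config$condition_levels,
               c("congruent", "incongruent"))
  expect_equal(payload$result$p.value, r1$result$p.value)
  expect_true(file.exists(r1$paths[["exclusions"]]))
  expect_true(file.exists(r1$paths[["participants"]]))
})

test_that("config files round-trip through YAML and JSON", {
  dir <- withr::local_tempdir()
  input <- write_sim_csv(file.path(dir, "data.csv"), seed = 23)
  cfg <- base_config(input, file.path(dir, "out"))

  ypath <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, ypath)
  jpath <- file.path(dir, "run.json")
  jsonlite::write_json(cfg, jpath, auto_unbox = TRUE)

  ry <- run_nondir(ypath, quiet = TRUE)
  cfgj <- read_run_config(jpath)
  cfgj$output <- file.path(dir, "outj")
  rj <- run_nondir(cfgj, quiet = TRUE)
  expect_identical(ry$result$p.value, rj$result$p.value)
})

test_that("missing required config fields and failing stages are named", {
  expect_error(run_nondir(list(method = "gnt"), quiet = TRUE), "`input`")
  dir <- withr::local_tempdir()
  input <- write_sim_csv(file.path(dir, "data.csv"), seed = 3)
  expect_error(run_nondir(list(input = input), quiet = TRUE), "`method`")

  cfg <- base_config(input, file.path(dir, "bad"))
  cfg$columns$outcome <- "nope"
  expect_error(run_nondir(cfg, quiet = TRUE), "stage load")
})

test_that("batch mode emits one result row per dataset", {
  dir <- withr::local_tempdir()
  for (s in 1:3) {
    write_sim_csv(file.path(dir, sprintf("exp%d.csv", s)), seed = s)
  }
  cfg <- base_config(NULL, NULL)
  cfg$input <- NULL
  cfg$output <- file.path(dir, "batch")
  got <- run_nondir_batch(dir, cfg)
  expect_equal(nrow(got), 3)
  expect_equal(got$file, sprintf("exp%d.csv", 1:3))
  expect_true(all(got$p.value > 0 & got$p.value <= 1))
  expect_true(all(got$method == "sign_consistency"))
})

test_that("gnt and oanova methods run through the pipeline", {
  dir <- withr::local_tempdir()
  input <- write_sim_csv(file.path(dir, "data.csv"), seed = 31)
  cfg <- base_config(input, file.path(dir, "g"))
  cfg$method <- "gnt"
  cfg$statistic <- NULL
  rg <- run_nondir(cfg, quiet = TRUE)
  expect_s3_class(rg$result, "prevalence_result")

  cfg$method <- "oanova"
  cfg$output <- file.path(dir, "o")
  ro <- run_nondir(cfg, quiet = TRUE)
  expect_s3_class(ro$result, "oanova_result")
  payload <- jsonlite::read_json(ro$paths[["result"]],
                                 simplifyVector = TRUE)
  expect_equal(payload$result$df2, ro$result$df2)
})
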