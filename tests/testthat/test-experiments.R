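# Configuration presets, validation, run orchestration and summaries.

test_that("presets pin the reference parameter combinations", {
  s1 <- mt_config("sim1")
  expect_identical(s1$mode, "protofilament")
  expect_identical(c(s1$n_alpha, s1$n_beta), c(300L, 300L))
  expect_identical(s1$p_gtp, 1)
  expect_identical(s1$iterations, 120000L)
  expect_false(s1$extended_rules)
  s3 <- mt_config("sim3")
  expect_identical(s3$mode, "ring")
  expect_identical(s3$n_nucleotides, 600L)
  expect_identical(s3$p_gtp, 1)
  s4 <- mt_config("sim4")
  expect_true(s4$extended_rules)
  expect_identical(s4$start_nucleotide_state, "GDP")
  expect_identical(s4$limit_gdp, 3)
  expect_identical(s4$iterations, 100000L)
  expect_identical(s4$p_break, 0.1)
  # expansion is pure: same inputs, same config
  expect_identical(mt_config("sim2", seed = 9), mt_config("sim2", seed = 9))
  expect_identical(mt_config("sim2")$p_gtp, 0.5)
})

test_that("scaled presets preserve population ratios and density", {
  full <- mt_config("sim1")
  tenth <- mt_config("sim1", scale = 0.1)
  expect_identical(tenth$n_alpha, 30L)
  expect_identical(tenth$n_nucleotides, 60L)
  expect_equal(tenth$n_nucleotides / (tenth$n_alpha + tenth$n_beta),
               full$n_nucleotides / (full$n_alpha + full$n_beta))
  # tray area shrinks with the population: constant number density
  expect_equal(
    (tenth$n_alpha + tenth$n_beta) /
      (tenth$space_width * tenth$space_height),
    (full$n_alpha + full$n_beta) /
      (full$space_width * full$space_height),
    tolerance = 1e-9)
  expect_identical(tenth$iterations, 20000L)
})

test_that("validation lists every violation and rejects unknown keys", {
  expect_error(mt_config(p_gtp = 1.5), "p_gtp")
  expect_error(mt_config(n_alpha = -3), "n_alpha")
  expect_error(mt_config(not_a_key = 1), "unknown configuration key")
  err <- tryCatch(mt_config(p_gtp = 2, p_break = -1, damping = 3),
                  error = conditionMessage)
  expect_match(err, "p_gtp")
  expect_match(err, "p_break")
  expect_match(err, "damping")
  expect_error(mt_config(kick_interval = 0.015), "multiple")
})

test_that("runs are reproducible bit for bit from config + seed", {
  dir1 <- tempfile("runA")
  dir2 <- tempfile("runB")
  cfg1 <- mt_config(n_alpha = 8, n_beta = 8, n_nucleotides = 16,
                    space_width = 0.5, space_height = 0.5,
                    iterations = 2000, trials = 1, seed = 7,
                    output_dir = dir1)
  cfg2 <- mt_config(n_alpha = 8, n_beta = 8, n_nucleotides = 16,
                    space_width = 0.5, space_height = 0.5,
                    iterations = 2000, trials = 1, seed = 7,
                    output_dir = dir2)
  r1 <- mt_run(cfg1)
  r2 <- mt_run(cfg2)
  expect_identical(tidy(r1), tidy(r2))
  f1 <- file.path(dir1, "trial-1", "counts.csv")
  f2 <- file.path(dir2, "trial-1", "counts.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("run outputs include a complete manifest and state tables", {
  dir <- tempfile("run")
  cfg <- mt_config(n_alpha = 6, n_beta = 6, n_nucleotides = 12,
                   space_width = 0.5, space_height = 0.5,
                   iterations = 500, trials = 2, seed = 5,
                   output_dir = dir)
  run <- mt_run(cfg)
  for (t in 1:2) {
    td <- file.path(dir, paste0("trial-", t))
    expect_true(file.exists(file.path(td, "counts.csv")))
    expect_true(file.exists(file.path(td, "final_state.csv")))
    man <- yaml::read_yaml(file.path(td, "manifest.yaml"))
    expect_identical(man$status, "completed")
    expect_identical(man$seed, cfg$seed + t)
    expect_identical(man$config$p_gtp, cfg$p_gtp)
    expect_identical(man$iterations_run, 500L)
  }
  back <- mt_read_trial(file.path(dir, "trial-1"))
  expect_identical(nrow(back$counts), 501L)
  expect_identical(nrow(back$final_state), 24L)
  unlink(dir, recursive = TRUE)
})

test_that("trial worlds are seeded independently and logged per trial", {
  cfg <- mt_config(n_alpha = 5, n_beta = 5, n_nucleotides = 10,
                   space_width = 0.5, space_height = 0.5,
                   iterations = 100, trials = 3, seed = 2)
  run <- mt_run(cfg)
  expect_identical(vapply(run$trials, `[[`, integer(1), "seed"),
                   c(3L, 4L, 5L))
  td <- tidy(run)
  expect_identical(unique(td$trial), 1:3)
  # different seeds, different trajectories
  expect_false(identical(run$trials[[1]]$world$tub_x,
                         run$trials[[2]]$world$tub_x))
})

test_that("summaries aggregate trials and refuse empty input", {
  cfg <- mt_config(n_alpha = 6, n_beta = 6, n_nucleotides = 12,
                   space_width = 0.4, space_height = 0.4,
                   iterations = 800, trials = 3, seed = 1)
  run <- mt_run(cfg)
  s <- mt_summarize(run)
  expect_identical(nrow(s$trials), 3L)
  expect_identical(nrow(s$combinations), 1L)
  expect_equal(s$combinations$final_active,
               mean(s$trials$final_active))
  expect_identical(s$combinations$trials, 3L)
  # single run: means equal values
  cfg1 <- mt_config(n_alpha = 6, n_beta = 6, n_nucleotides = 12,
                    space_width = 0.4, space_height = 0.4,
                    iterations = 200, trials = 1, seed = 1)
  r1 <- mt_run(cfg1)
  s1 <- mt_summarize(r1)
  expect_identical(s1$trials$final_active, s1$combinations$final_active)
  expect_error(mt_summarize(list()), "no runs")
})

test_that("tidy, glance and autoplot expose the run results", {
  cfg <- mt_config(n_alpha = 6, n_beta = 6, n_nucleotides = 12,
                   space_width = 0.4, space_height = 0.4,
                   iterations = 300, trials = 1, seed = 4)
  run <- mt_run(cfg)
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 301L)
  g <- glance(run)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("final_active", "max_chain_length", "closed_rings")
                  %in% names(g)))
  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
  pw <- autoplot(run$trials[[1]]$world)
  expect_s3_class(pw, "ggplot")
})

test_that("the command-line driver dispatches and reports usage", {
  out <- utils::capture.output(status <- mtswarm_cli(character()))
  expect_match(out[1], "usage: mtswarm")
  expect_identical(status, 0L)
  out <- utils::capture.output(status <- mtswarm_cli("frobnicate"))
  expect_match(out[1], "unknown command")
  expect_identical(status, 1L)
  # a tiny end-to-end run through the CLI surface
  dir <- tempfile("cli")
  utils::capture.output(mtswarm_cli(c(
    "run", "--preset", "sim1", "--gtp", "12", "--iterations", "200",
    "--trials", "1", "--seed", "3", "--scale", "0.1", "--out", dir)))
  expect_true(file.exists(file.path(dir, "trial-1", "counts.csv")))
  out <- utils::capture.output(mtswarm_cli(c("summarize",
                                             file.path(dir, "trial-1"))))
  expect_true(any(grepl("active", out)))
  unlink(dir, recursive = TRUE)
})
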