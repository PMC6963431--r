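# Run orchestration: trial loop, logging, manifests, output layout and
# cross-run summaries.

#' Run a simulation
#'
#' For each trial `t` in `1..trials` the world is initialised at random
#' non-overlapping locations with seed `seed + t`, then iterated for
#' `iterations` steps of: physics step, collision resolution, rule sweep,
#' analytics snapshot. Identical configuration and seed give identical
#' output, bit for bit.
#'
#' If `config$output_dir` is set, each trial writes `counts.csv` (the
#' analytics log), `rates.csv` (the derived GTP consumption-rate table, when
#' the run is longer than the smoothing window), `final_state.csv` (agent
#' coordinates) and `manifest.yaml` into `<output_dir>/trial-<t>/`. The
#' manifest is written before stepping begins and finalised at completion;
#' on numerical instability the partial log is flushed and the manifest is
#' marked failed.
#'
#' @param config an [mt_config()].
#' @param rate_window smoothing window for the rate table written to disk.
#' @param progress print a line per trial.
#' @return an `mtswarm_run` object: list with `config` and one entry per
#'   trial (`seed`, `counts` tibble, final `world`, `manifest`).
#' @examples
#' \donttest{
#' cfg <- mt_config("sim1", scale = 0.05, iterations = 200, trials = 1)
#' run <- mt_run(cfg)
#' tidy(run)
#' }
#' @export
mt_run <- function(config, rate_window = 1000L, progress = FALSE) {
  stopifnot(inherits(config, "mt_config"))
  trials <- vector("list", config$trials)
  for (t in seq_len(config$trials)) {
    if (progress) {
      message(sprintf("trial %d/%d (seed %d)", t, config$trials,
                      config$seed + t))
    }
    trials[[t]] <- run_trial(config, t, rate_window)
  }
  structure(list(config = config, trials = trials),
            class = "mtswarm_run")
}

run_trial <- function(config, trial, rate_window) {
  seed <- config$seed + trial
  set.seed(seed)
  out_dir <- NULL
  if (!is.null(config$output_dir)) {
    out_dir <- file.path(config$output_dir, paste0("trial-", trial))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  manifest <- list(
    package = "mtswarm",
    version = as.character(utils::packageVersion("mtswarm")),
    trial = trial,
    seed = seed,
    status = "running",
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_echo(config)
  )
  if (!is.null(out_dir)) {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  t0 <- proc.time()[["elapsed"]]
  w <- init_world(config)
  nlog <- config$iterations %/% config$log_every + 1L
  counts <- matrix(NA_real_, nrow = nlog, ncol = 9)
  counts[1, ] <- snapshot_row(w)
  row <- 1L
  status <- "completed"
  err <- NULL
  tryCatch({
    for (i in seq_len(config$iterations)) {
      w <- advance_world(w, config) # fused step + collision resolution
      w <- rules_sweep(w, config)
      if (i %% config$log_every == 0L) {
        row <- row + 1L
        counts[row, ] <- snapshot_row(w)
      }
    }
  }, error = function(e) {
    status <<- "failed"
    err <<- conditionMessage(e)
  })
  counts <- counts[seq_len(row), , drop = FALSE]
  colnames(counts) <- c("iteration", "inactive_dimers", "active_dimers",
                        "free_gtp", "free_gdp", "max_chain_length",
                        "chain_count", "closed_ring_count", "bound_nt")
  counts <- tibble::as_tibble(counts)
  manifest$status <- status
  if (!is.null(err)) manifest$error <- err
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  manifest$iterations_run <- w$iteration
  if (!is.null(out_dir)) {
    write_counts(counts, file.path(out_dir, "counts.csv"))
    if (nrow(counts) > rate_window) {
      write_counts(gtp_consumption_rate(counts, rate_window),
                   file.path(out_dir, "rates.csv"))
    }
    write_counts(world_coordinates(w), file.path(out_dir, "final_state.csv"))
    manifest$files <- list.files(out_dir)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  if (status == "failed") {
    abort(paste0("trial ", trial, " aborted: ", err))
  }
  list(trial = trial, seed = seed, counts = counts, world = w,
       manifest = manifest)
}

#' Run a single trial until a condition is met
#'
#' Steps one world (initialised like trial `trial` of [mt_run()]) until
#' `predicate(world)` returns TRUE or `max_iterations` is reached. The
#' predicate is evaluated every `check_every` iterations. Useful for
#' rare-event runs such as "simulate until the first ring closes".
#'
#' @param config an [mt_config()].
#' @param predicate function of an `mt_world` returning TRUE/FALSE.
#' @param max_iterations hard iteration cap.
#' @param check_every predicate evaluation period, iterations.
#' @param trial trial number (the world is seeded with `seed + trial`).
#' @param log_every snapshot period for the returned counts table.
#' @param world optional `mt_world` to continue from (RNG state is then
#'   left as-is rather than reseeded); `max_iterations` counts only the
#'   additional iterations of this call.
#' @return list with `world`, `counts`, `iterations` and `satisfied`.
#' @export
mt_run_until <- function(config, predicate, max_iterations = 1000000L,
                         check_every = 100L, trial = 1L,
                         log_every = 1000L, world = NULL) {
  stopifnot(inherits(config, "mt_config"), is.function(predicate))
  if (is.null(world)) {
    set.seed(config$seed + trial)
    w <- init_world(config)
  } else {
    w <- world
  }
  rows <- list(snapshot_row(w))
  satisfied <- isTRUE(predicate(w))
  it <- 0L
  while (!satisfied && it < max_iterations) {
    w <- advance_world(w, config)
    w <- rules_sweep(w, config)
    it <- it + 1L
    if (it %% log_every == 0L) rows[[length(rows) + 1L]] <- snapshot_row(w)
    if (it %% check_every == 0L) satisfied <- isTRUE(predicate(w))
  }
  counts <- tibble::as_tibble(do.call(rbind, rows))
  list(world = w, counts = counts, iterations = it, satisfied = satisfied)
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- if (is.null(cfg$output_dir)) "" else cfg$output_dir
  cfg
}

combination_label <- function(config) {
  sprintf("%s mode=%s nGTP=%d P_GTP=%g P_break=%g ext=%d",
          config$preset, config$mode, config$n_nucleotides, config$p_gtp,
          config$p_break, as.integer(config$extended_rules))
}

#' Summarise one or more runs
#'
#' One row per (parameter combination, trial) with final counts, the
#' time-to-half-saturation of the active-dimer count (first iteration
#' reaching half the final value; NA if no dimer ever activates), the mean
#' magnitude of the GTP consumption rate, and the maximum chain length seen.
#' The `$combinations` table holds per-combination means over trials.
#'
#' @param ... `mtswarm_run` objects (or a single list of them).
#' @param rate_window smoothing window for the rate magnitude (skipped with
#'   NA when a run is shorter than the window).
#' @return an `mtswarm_summary`: list of tibbles `trials` and `combinations`.
#' @export
mt_summarize <- function(..., rate_window = 1000L) {
  runs <- list(...)
  if (length(runs) == 1 && !inherits(runs[[1]], "mtswarm_run")) {
    runs <- runs[[1]]
  }
  if (length(runs) == 0) abort("no runs to summarise")
  if (!all(vapply(runs, inherits, logical(1), "mtswarm_run"))) {
    abort("inputs must be `mtswarm_run` objects")
  }
  presets <- vapply(runs, function(r) r$config$preset, character(1))
  if (length(unique(presets)) > 1) {
    warn("summarising runs from different presets; rows are grouped by combination")
  }
  rows <- purrr::map_dfr(runs, function(r) {
    purrr::map_dfr(r$trials, function(tr) {
      cc <- tr$counts
      final <- cc[nrow(cc), ]
      half_it <- NA_real_
      if (final$active_dimers > 0) {
        half_it <-
          cc$iteration[which(cc$active_dimers >= final$active_dimers / 2)[1]]
      }
      mean_rate <- NA_real_
      if (nrow(cc) > rate_window) {
        mean_rate <- mean(abs(gtp_consumption_rate(cc, rate_window)$rate))
      }
      tibble::tibble(
        combination = combination_label(r$config),
        preset = r$config$preset,
        n_nucleotides = r$config$n_nucleotides,
        p_gtp = r$config$p_gtp,
        p_break = r$config$p_break,
        trial = tr$trial,
        seed = tr$seed,
        final_inactive = final$inactive_dimers,
        final_active = final$active_dimers,
        final_free_gtp = final$free_gtp,
        final_free_gdp = final$free_gdp,
        half_saturation_iter = half_it,
        mean_rate_magnitude = mean_rate,
        max_chain_length = max(cc$max_chain_length),
        closed_rings = final$closed_ring_count)
    })
  })
  combos <- rows |>
    dplyr::group_by(.data$combination, .data$preset, .data$n_nucleotides,
                    .data$p_gtp, .data$p_break) |>
    dplyr::summarise(
      trials = dplyr::n(),
      dplyr::across(c("final_inactive", "final_active", "final_free_gtp",
                      "final_free_gdp", "half_saturation_iter",
                      "mean_rate_magnitude", "max_chain_length",
                      "closed_rings"),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
  structure(list(trials = rows, combinations = combos),
            class = "mtswarm_summary")
}

#' @export
print.mtswarm_summary <- function(x, ...) {
  cat("<mtswarm_summary>\nPer-trial rows:\n")
  print(x$trials, ...)
  cat("\nPer-combination means:\n")
  print(x$combinations, ...)
  invisible(x)
}

#' Read a written trial back from disk
#'
#' @param dir a `trial-<t>` directory written by [mt_run()].
#' @return a list with `counts`, `final_state` and `manifest`.
#' @export
mt_read_trial <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  counts <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "counts.csv")))
  fs_path <- file.path(dir, "final_state.csv")
  final_state <- if (file.exists(fs_path)) {
    tibble::as_tibble(utils::read.csv(fs_path))
  } else {
    NULL
  }
  list(counts = counts, final_state = final_state, manifest = man)
}
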