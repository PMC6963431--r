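#' Simulation configuration
#'
#' Builds a validated configuration for a self-assembly run. Presets `sim1`
#' to `sim4` pin the reference parameter combinations (protofilament runs
#' with varying GTP population, varying GTP bonding probability, ring runs,
#' and extended-rule runs with terminal breakage); `custom` starts from the
#' package defaults. Any field can be overridden by name. `scale` produces a
#' desk-scale variant: populations are multiplied by `scale`, the tray side
#' is shrunk by `sqrt(scale)` so that number density (and hence encounter
#' kinetics) is preserved, and the iteration budget drops to 20,000 unless
#' set explicitly.
#'
#' @param preset one of `"custom"`, `"sim1"`, `"sim2"`, `"sim3"`, `"sim4"`.
#' @param ... named configuration overrides (see Details).
#' @param scale population scale factor in (0, 1]; 1 is the full experiment.
#'
#' @details Key fields and defaults:
#' * populations: `n_alpha` (300), `n_beta` (300), `n_nucleotides` (600)
#' * rules: `p_gtp` (1), `p_break` (0), `mode` (`"protofilament"` or
#'   `"ring"`), `limit_gdp` (3 s), `break_check_interval` (100 iterations),
#'   `extended_rules` (FALSE), `start_nucleotide_state` (`"GTP"`),
#'   `require_partner_active` (TRUE; set FALSE for the literal reading of the
#'   dimer-bond condition in which only the initiating dimer must be active)
#' * physics: `dt` (0.01 s), `f_max` (1), `kick_interval` (0.1 s),
#'   `damping` (0.98 per step), `collision_passes` (4), `collision_tol`
#'   (1e-4), `tubulin_mass` (1), `nucleotide_mass` (0.5)
#' * geometry: `space_width`/`space_height` (3 units), `tubulin_radius`
#'   (0.03), `nucleotide_radius` (0.015), `trigger_radius` (0.06, i.e. twice
#'   the tubulin radius), `ring_theta` (30 degrees per junction)
#' * orchestration: `iterations` (120,000; 100,000 for `sim4`), `trials` (3),
#'   `seed` (1), `log_every` (1), `output_dir` (NULL = in-memory only)
#'
#' @return an object of class `mt_config` (a named list).
#' @examples
#' mt_config("sim3", scale = 0.1, seed = 7)
#' @export
mt_config <- function(preset = c("custom", "sim1", "sim2", "sim3", "sim4"),
                      ..., scale = 1) {
  preset <- match.arg(preset)
  cfg <- mt_defaults()
  cfg$preset <- preset
  cfg <- modifyList(cfg, mt_preset_values(preset))

  user <- list(...)
  if (length(user) > 0 && (is.null(names(user)) || any(names(user) == ""))) {
    abort("all configuration overrides must be named")
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, user)
  cfg$scale <- scale

  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0 || scale > 1) {
    abort("`scale` must be a single number in (0, 1]")
  }
  if (scale < 1) {
    for (key in c("n_alpha", "n_beta", "n_nucleotides")) {
      if (!key %in% names(user)) cfg[[key]] <- round(cfg[[key]] * scale)
    }
    for (key in c("space_width", "space_height")) {
      if (!key %in% names(user)) cfg[[key]] <- cfg[[key]] * sqrt(scale)
    }
    if (!"iterations" %in% names(user)) cfg$iterations <- 20000L
  }

  cfg$n_alpha <- as.integer(cfg$n_alpha)
  cfg$n_beta <- as.integer(cfg$n_beta)
  cfg$n_nucleotides <- as.integer(cfg$n_nucleotides)
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$trials <- as.integer(cfg$trials)
  cfg$seed <- as.integer(cfg$seed)
  cfg$log_every <- as.integer(cfg$log_every)
  cfg$break_check_interval <- as.integer(cfg$break_check_interval)

  validate_config(cfg)
  structure(cfg, class = "mt_config")
}

mt_defaults <- function() {
  list(
    preset = "custom",
    # populations
    n_alpha = 300L, n_beta = 300L, n_nucleotides = 600L,
    # rules
    p_gtp = 1, p_break = 0, mode = "protofilament",
    limit_gdp = 3, break_check_interval = 100L,
    extended_rules = FALSE, start_nucleotide_state = "GTP",
    require_partner_active = TRUE,
    # physics
    dt = 0.01, f_max = 1, kick_interval = 0.1, damping = 0.98,
    collision_passes = 4L, collision_tol = 1e-4,
    tubulin_mass = 1, nucleotide_mass = 0.5,
    # geometry
    space_width = 3, space_height = 3,
    tubulin_radius = 0.03, nucleotide_radius = 0.015,
    trigger_radius = 0.06, ring_theta = 30,
    # orchestration
    iterations = 120000L, trials = 3L, seed = 1L, log_every = 1L,
    scale = 1, output_dir = NULL
  )
}

mt_preset_values <- function(preset) {
  switch(preset,
    custom = list(),
    sim1 = list(mode = "protofilament", p_gtp = 1, n_nucleotides = 600L,
                iterations = 120000L, extended_rules = FALSE),
    sim2 = list(mode = "protofilament", p_gtp = 0.5, n_nucleotides = 600L,
                iterations = 120000L, extended_rules = FALSE),
    sim3 = list(mode = "ring", p_gtp = 1, n_nucleotides = 600L,
                iterations = 120000L, extended_rules = FALSE),
    sim4 = list(mode = "protofilament", p_gtp = 1, n_nucleotides = 600L,
                iterations = 100000L, extended_rules = TRUE,
                start_nucleotide_state = "GDP", limit_gdp = 3,
                p_break = 0.1)
  )
}

validate_config <- function(cfg) {
  problems <- character()
  bad <- function(msg) problems <<- c(problems, msg)

  prob_in_01 <- function(x) is.numeric(x) && length(x) == 1 &&
    is.finite(x) && x >= 0 && x <= 1
  pos_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x > 0
  nonneg_int <- function(x) is.numeric(x) && length(x) == 1 &&
    is.finite(x) && x >= 0 && x == round(x)

  if (!prob_in_01(cfg$p_gtp)) bad("`p_gtp` must be a probability in [0, 1]")
  if (!prob_in_01(cfg$p_break)) {
    bad("`p_break` must be a probability in [0, 1]")
  }
  for (key in c("n_alpha", "n_beta", "n_nucleotides", "iterations")) {
    if (!nonneg_int(cfg[[key]])) {
      bad(paste0("`", key, "` must be a non-negative integer"))
    }
  }
  if (!nonneg_int(cfg$trials) || cfg$trials < 1) {
    bad("`trials` must be a positive integer")
  }
  if (!nonneg_int(cfg$log_every) || cfg$log_every < 1) {
    bad("`log_every` must be a positive integer")
  }
  if (!pos_num(cfg$dt)) bad("`dt` must be a positive number")
  if (!pos_num(cfg$kick_interval)) bad("`kick_interval` must be positive")
  if (pos_num(cfg$dt) && pos_num(cfg$kick_interval)) {
    k <- cfg$kick_interval / cfg$dt
    if (abs(k - round(k)) > 1e-8) {
      bad("`kick_interval` must be an integer multiple of `dt`")
    }
  }
  if (!is.numeric(cfg$f_max) || length(cfg$f_max) != 1 ||
      !is.finite(cfg$f_max) || cfg$f_max < 0) {
    bad("`f_max` must be a non-negative number")
  }
  if (!is.numeric(cfg$damping) || length(cfg$damping) != 1 ||
      !is.finite(cfg$damping) || cfg$damping <= 0 || cfg$damping > 1) {
    bad("`damping` must lie in (0, 1]")
  }
  for (key in c("space_width", "space_height", "tubulin_radius",
                "nucleotide_radius", "trigger_radius", "tubulin_mass",
                "nucleotide_mass")) {
    if (!pos_num(cfg[[key]])) bad(paste0("`", key, "` must be positive"))
  }
  if (!is.numeric(cfg$ring_theta) || length(cfg$ring_theta) != 1 ||
      !is.finite(cfg$ring_theta) || cfg$ring_theta <= 0 ||
      cfg$ring_theta > 90) {
    bad("`ring_theta` must be in (0, 90] degrees")
  }
  if (!cfg$mode %in% c("protofilament", "ring")) {
    bad("`mode` must be \"protofilament\" or \"ring\"")
  }
  if (!cfg$start_nucleotide_state %in% c("GTP", "GDP")) {
    bad("`start_nucleotide_state` must be \"GTP\" or \"GDP\"")
  }
  if (!is.numeric(cfg$limit_gdp) || length(cfg$limit_gdp) != 1 ||
      !is.finite(cfg$limit_gdp) || cfg$limit_gdp < 0) {
    bad("`limit_gdp` must be a non-negative number of seconds")
  }
  if (!nonneg_int(cfg$break_check_interval) ||
      cfg$break_check_interval < 1) {
    bad("`break_check_interval` must be a positive integer")
  }
  if (!nonneg_int(cfg$collision_passes) || cfg$collision_passes < 1) {
    bad("`collision_passes` must be a positive integer")
  }
  if (length(problems) > 0) {
    abort(c("invalid configuration:", problems))
  }
  invisible(cfg)
}

#' @export
print.mt_config <- function(x, ...) {
  cat("<mt_config> preset:", x$preset, "\n")
  cat(sprintf("  populations: %d alpha, %d beta, %d nucleotides (start %s)\n",
              x$n_alpha, x$n_beta, x$n_nucleotides,
              x$start_nucleotide_state))
  cat(sprintf("  rules: mode=%s P_GTP=%g P_break=%g extended=%s\n",
              x$mode, x$p_gtp, x$p_break, x$extended_rules))
  cat(sprintf("  tray: %g x %g units, dt=%g s, F_max=%g, damping=%g\n",
              x$space_width, x$space_height, x$dt, x$f_max, x$damping))
  cat(sprintf("  run: %d iterations, %d trial(s), seed=%d\n",
              x$iterations, x$trials, x$seed))
  invisible(x)
}
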