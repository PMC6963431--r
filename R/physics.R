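# Environment contract: bounded tray, impulsive random forcing at regular
# intervals, damped semi-implicit integration with rigid cluster motion,
# and positional disc-collision resolution. The numerics live in
# src/kernels.cpp; all random draws happen here so a run consumes a single
# R RNG stream.

# assemble the mobile bodies (all tubulins + free nucleotides) for the kernels
body_arrays <- function(w, config) {
  nt <- n_tubulins(w)
  freen <- which(w$nuc_state != NT_BOUND)
  base <- if (nt > 0) max(w$cluster) else 0L
  list(
    freen = freen,
    x = c(w$tub_x, w$nuc_x[freen]),
    y = c(w$tub_y, w$nuc_y[freen]),
    vx = c(w$tub_vx, w$nuc_vx[freen]),
    vy = c(w$tub_vy, w$nuc_vy[freen]),
    om = c(w$tub_om, numeric(length(freen))),
    orient = c(w$tub_orient, numeric(length(freen))),
    cluster = c(w$cluster, base + seq_along(freen)),
    mass = c(rep(config$tubulin_mass, nt),
             rep(config$nucleotide_mass, length(freen))),
    radius = c(rep(config$tubulin_radius, nt),
               rep(config$nucleotide_radius, length(freen)))
  )
}

kick_period <- function(w, config) {
  max(1L, as.integer(round(config$kick_interval / w$dt)))
}

#' Draw the impulsive random forces for the current iteration
#'
#' At kick iterations (every `kick_interval / dt` steps) every tubulin and
#' every free nucleotide receives an independent force with components
#' uniform on `[-f_max, f_max]`; at all other iterations the force is zero.
#' A bonded cluster receives the force at each constituent tubulin, so net
#' force and net torque about the cluster centroid accumulate naturally in
#' the integrator. The pending forces are attached to the world and consumed
#' by the next [step_world()].
#'
#' @param w an `mt_world`.
#' @param config an [mt_config()].
#' @return the world with a `pending` force field.
#' @export
apply_random_forces <- function(w, config) {
  nt <- n_tubulins(w)
  freen <- which(w$nuc_state != NT_BOUND)
  nb <- nt + length(freen)
  if (w$iteration %% kick_period(w, config) == 0L && config$f_max > 0) {
    f <- matrix(runif(2 * nb, -config$f_max, config$f_max), ncol = 2)
  } else {
    f <- matrix(0, nrow = nb, ncol = 2)
  }
  w$pending <- list(force = f, freen = freen)
  w
}

#' Advance the world by one physics step
#'
#' Semi-implicit update: cluster velocity += net force / cluster mass * dt,
#' velocity *= damping, position += velocity * dt; bonded clusters move
#' rigidly (shared translation plus rotation about the centroid driven by the
#' net torque of the member kicks). Agents reflect off the tray walls and are
#' clamped inside. The iteration counter increments by one. If no forces are
#' pending, [apply_random_forces()] is called first.
#'
#' @param w an `mt_world`.
#' @param config an [mt_config()].
#' @return the stepped world.
#' @export
step_world <- function(w, config) {
  if (is.null(w$pending)) w <- apply_random_forces(w, config)
  b <- body_arrays(w, config)
  res <- cpp_integrate(b$x, b$y, b$vx, b$vy, b$om, b$orient, b$cluster,
                       b$mass, b$radius, w$pending$force[, 1],
                       w$pending$force[, 2], w$dt, config$damping,
                       w$space[1], w$space[2])
  if (any(!is.finite(res$x)) || any(!is.finite(res$y)) ||
      any(!is.finite(res$vx)) || any(!is.finite(res$vy))) {
    abort(paste("numerical instability: non-finite position or velocity;",
                "reduce `dt` or `f_max`"))
  }
  w <- write_back_bodies(w, b, res, velocities = TRUE)
  w$pending <- NULL
  w$iteration <- w$iteration + 1L
  sync_bound_nucleotides(w)
}

#' Resolve disc overlaps by positional correction
#'
#' Every overlapping pair of discs not bonded to each other is pushed apart
#' along the centre line, the correction split inversely by cluster mass and
#' applied to whole clusters (internal bond geometry is preserved). Repeats
#' up to `collision_passes` passes or until no overlap exceeds
#' `collision_tol`.
#'
#' @param w an `mt_world`.
#' @param config an [mt_config()].
#' @return the corrected world.
#' @export
resolve_collisions <- function(w, config) {
  b <- body_arrays(w, config)
  if (length(b$x) < 2) return(w)
  res <- cpp_resolve(b$x, b$y, b$radius, b$cluster, b$mass,
                     config$collision_passes, config$collision_tol,
                     w$space[1], w$space[2])
  w <- write_back_bodies(w, b, res, velocities = FALSE)
  sync_bound_nucleotides(w)
}

# fused step + collision resolution used by the run loop: one kernel call
# and one body assembly per iteration (numerics identical to step_world()
# followed by resolve_collisions())
advance_world <- function(w, config) {
  b <- body_arrays(w, config)
  nb <- length(b$x)
  if (w$iteration %% kick_period(w, config) == 0L && config$f_max > 0) {
    f <- runif(2 * nb, -config$f_max, config$f_max)
    fx <- f[seq_len(nb)]
    fy <- f[nb + seq_len(nb)]
  } else {
    fx <- numeric(0) # kernel treats empty as zero force
    fy <- numeric(0)
  }
  res <- cpp_advance(b$x, b$y, b$vx, b$vy, b$om, b$orient, b$cluster,
                     b$mass, b$radius, fx, fy, w$dt, config$damping,
                     config$collision_passes, config$collision_tol,
                     w$space[1], w$space[2])
  if (anyNA(res$x) || any(is.infinite(res$x)) || anyNA(res$vx) ||
      any(is.infinite(res$vx))) {
    abort(paste("numerical instability: non-finite position or velocity;",
                "reduce `dt` or `f_max`"))
  }
  w <- write_back_bodies(w, b, res, velocities = TRUE)
  w$iteration <- w$iteration + 1L
  w
}

write_back_bodies <- function(w, b, res, velocities) {
  nt <- n_tubulins(w)
  ti <- seq_len(nt)
  ni <- nt + seq_along(b$freen)
  w$tub_x <- res$x[ti]
  w$tub_y <- res$y[ti]
  w$nuc_x[b$freen] <- res$x[ni]
  w$nuc_y[b$freen] <- res$y[ni]
  if (velocities) {
    w$tub_vx <- res$vx[ti]
    w$tub_vy <- res$vy[ti]
    w$tub_om <- res$om[ti]
    w$tub_orient <- res$orient[ti]
    w$nuc_vx[b$freen] <- res$vx[ni]
    w$nuc_vy[b$freen] <- res$vy[ni]
  }
  w
}

# bound nucleotides ride their host tubulin
sync_bound_nucleotides <- function(w) {
  bound <- which(w$nuc_state == NT_BOUND)
  if (length(bound) > 0) {
    w$nuc_x[bound] <- w$tub_x[w$nuc_host[bound]]
    w$nuc_y[bound] <- w$tub_y[w$nuc_host[bound]]
    w$nuc_vx[bound] <- w$tub_vx[w$nuc_host[bound]]
    w$nuc_vy[bound] <- w$tub_vy[w$nuc_host[bound]]
  }
  w
}
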