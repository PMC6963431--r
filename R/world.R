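# World state: flat vectors over tubulins and nucleotides plus the bond
# graph, stored as per-site partner indices. Site semantics:
#   intra-dimer bond: alpha's A site  <-> beta's B site
#   inter-dimer bond: alpha's B site  <-> beta's A site
# so chains alternate ... beta-alpha | beta-alpha | ... and stay linear
# because every site holds at most one bond.

#' Create an empty world
#'
#' @param config an [mt_config()].
#' @return an `mt_world` with no agents; populate with [add_tubulin()] /
#'   [add_nucleotide()] or use [init_world()] for random placement.
#' @export
new_world <- function(config = mt_config()) {
  structure(list(
    iteration = 0L,
    dt = config$dt,
    mode = config$mode,
    space = c(config$space_width, config$space_height),
    tubulin_radius = config$tubulin_radius,
    nucleotide_radius = config$nucleotide_radius,
    tub_kind = integer(), tub_x = numeric(), tub_y = numeric(),
    tub_vx = numeric(), tub_vy = numeric(), tub_om = numeric(),
    tub_orient = numeric(), site_a = numeric(), site_b = numeric(),
    bond_a = integer(), bond_b = integer(), tub_nt = integer(),
    cluster = integer(),
    nuc_state = integer(), nuc_x = numeric(), nuc_y = numeric(),
    nuc_vx = numeric(), nuc_vy = numeric(), nuc_spawn = integer(),
    nuc_host = integer(),
    pending = NULL
  ), class = "mt_world")
}

#' Append a tubulin to a world
#'
#' @param w an `mt_world`.
#' @param kind `"alpha"` or `"beta"`.
#' @param position numeric length-2 centre, tray units.
#' @param orientation primary-axis rotation, radians.
#' @return the world with one more tubulin (a fresh singleton cluster, sites
#'   at azimuth 0 and pi, no nucleotide).
#' @export
add_tubulin <- function(w, kind = c("alpha", "beta"), position,
                        orientation = 0) {
  kind <- match.arg(kind)
  if (position[1] < 0 || position[1] > w$space[1]) {
    abort(sprintf("x position %g outside configuration space [0, %g]",
                  position[1], w$space[1]))
  }
  if (position[2] < 0 || position[2] > w$space[2]) {
    abort(sprintf("y position %g outside configuration space [0, %g]",
                  position[2], w$space[2]))
  }
  w$tub_kind <- c(w$tub_kind, if (kind == "alpha") KIND_ALPHA else KIND_BETA)
  w$tub_x <- c(w$tub_x, position[1])
  w$tub_y <- c(w$tub_y, position[2])
  w$tub_vx <- c(w$tub_vx, 0)
  w$tub_vy <- c(w$tub_vy, 0)
  w$tub_om <- c(w$tub_om, 0)
  w$tub_orient <- c(w$tub_orient, orientation)
  w$site_a <- c(w$site_a, 0)
  w$site_b <- c(w$site_b, pi)
  w$bond_a <- c(w$bond_a, 0L)
  w$bond_b <- c(w$bond_b, 0L)
  w$tub_nt <- c(w$tub_nt, 0L)
  w$cluster <- c(w$cluster, max(0L, w$cluster) + 1L)
  w
}

#' Append a free nucleotide to a world
#'
#' @param w an `mt_world`.
#' @param position numeric length-2 centre, tray units.
#' @param state `"GTP"` or `"GDP"`.
#' @param spawn_iteration iteration at which the particle entered its current
#'   state (used by the GDP-to-GTP duration rule).
#' @return the world with one more free nucleotide.
#' @export
add_nucleotide <- function(w, position, state = c("GTP", "GDP"),
                           spawn_iteration = 0L) {
  state <- match.arg(state)
  w$nuc_state <- c(w$nuc_state, if (state == "GTP") NT_GTP else NT_GDP)
  w$nuc_x <- c(w$nuc_x, position[1])
  w$nuc_y <- c(w$nuc_y, position[2])
  w$nuc_vx <- c(w$nuc_vx, 0)
  w$nuc_vy <- c(w$nuc_vy, 0)
  w$nuc_spawn <- c(w$nuc_spawn, as.integer(spawn_iteration))
  w$nuc_host <- c(w$nuc_host, 0L)
  w
}

#' Initialise a world with randomly placed agents
#'
#' Places `n_alpha` + `n_beta` tubulins and `n_nucleotides` nucleotides at
#' rejection-sampled non-overlapping uniform positions with uniform random
#' orientations and zero initial velocity. Uses the current RNG stream.
#'
#' @param config an [mt_config()].
#' @param max_attempts placement attempts per agent before giving up.
#' @return an `mt_world`.
#' @export
init_world <- function(config, max_attempts = 10000L) {
  w <- new_world(config)
  n_tub <- config$n_alpha + config$n_beta
  kinds <- c(rep(KIND_ALPHA, config$n_alpha), rep(KIND_BETA, config$n_beta))
  radii <- c(rep(config$tubulin_radius, n_tub),
             rep(config$nucleotide_radius, config$n_nucleotides))
  n_all <- n_tub + config$n_nucleotides
  px <- numeric(n_all)
  py <- numeric(n_all)
  for (i in seq_len(n_all)) {
    r <- radii[i]
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cx <- runif(1, r, config$space_width - r)
      cy <- runif(1, r, config$space_height - r)
      if (i == 1L) {
        ok <- TRUE
      } else {
        prev <- seq_len(i - 1L)
        ok <- all((px[prev] - cx)^2 + (py[prev] - cy)^2 >=
                    (radii[prev] + r)^2)
      }
      if (ok) {
        px[i] <- cx
        py[i] <- cy
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(paste0("could not place agent ", i, " without overlap after ",
                   max_attempts, " attempts; the tray is too crowded"))
    }
  }
  w$tub_kind <- kinds
  w$tub_x <- px[seq_len(n_tub)]
  w$tub_y <- py[seq_len(n_tub)]
  w$tub_vx <- numeric(n_tub)
  w$tub_vy <- numeric(n_tub)
  w$tub_om <- numeric(n_tub)
  w$tub_orient <- runif(n_tub, 0, 2 * pi)
  w$site_a <- numeric(n_tub)
  w$site_b <- rep(pi, n_tub)
  w$bond_a <- integer(n_tub)
  w$bond_b <- integer(n_tub)
  w$tub_nt <- integer(n_tub)
  w$cluster <- seq_len(n_tub)
  nn <- config$n_nucleotides
  state0 <- if (config$start_nucleotide_state == "GTP") NT_GTP else NT_GDP
  w$nuc_state <- rep(state0, nn)
  w$nuc_x <- px[n_tub + seq_len(nn)]
  w$nuc_y <- py[n_tub + seq_len(nn)]
  w$nuc_vx <- numeric(nn)
  w$nuc_vy <- numeric(nn)
  w$nuc_spawn <- integer(nn)
  w$nuc_host <- integer(nn)
  w
}

n_tubulins <- function(w) length(w$tub_kind)
n_nucleotides <- function(w) length(w$nuc_state)

recompute_clusters <- function(w) {
  w$cluster <- cpp_components(w$bond_a, w$bond_b)
  w
}

# alpha indices of all formed dimers
dimer_alphas <- function(w) {
  which(w$tub_kind == KIND_ALPHA & w$bond_a > 0L)
}

# is each dimer (indexed by its alpha) active, i.e. both members nucleotide-
# loaded?
dimer_active <- function(w, alphas = dimer_alphas(w)) {
  w$tub_nt[alphas] > 0L & w$tub_nt[w$bond_a[alphas]] > 0L
}

# number of free sites per cluster id (named by cluster id)
cluster_free_sites <- function(w) {
  free <- (w$bond_a == 0L) + (w$bond_b == 0L)
  vapply(split(free, w$cluster), sum, numeric(1))
}

#' Check world invariants
#'
#' Asserts bond-graph symmetry and complementarity, occupancy consistency,
#' cluster consistency with the bond graph, in-bounds positions and
#' nucleotide bookkeeping. Used heavily by the test-suite; errors on the
#' first violated invariant.
#'
#' @param w an `mt_world`.
#' @return `w`, invisibly.
#' @export
validate_world <- function(w) {
  n <- n_tubulins(w)
  for (i in seq_len(n)) {
    j <- w$bond_a[i]
    if (j > 0L) {
      # A site bonds: alpha A <-> beta B (intra) or beta A <-> alpha B (inter)
      if (w$tub_kind[i] == w$tub_kind[j]) {
        abort(sprintf("bond between same-kind tubulins %d and %d", i, j))
      }
      if (w$bond_b[j] != i) {
        abort(sprintf("asymmetric bond: %d's A site names %d", i, j))
      }
    }
  }
  if (!identical(as.integer(w$cluster),
                 as.integer(cpp_components(w$bond_a, w$bond_b)))) {
    abort("cluster labels are not the components of the bond graph")
  }
  if (any(w$tub_x < -1e-9 | w$tub_x > w$space[1] + 1e-9 |
          w$tub_y < -1e-9 | w$tub_y > w$space[2] + 1e-9)) {
    abort("tubulin position outside the configuration space")
  }
  free <- w$nuc_state != NT_BOUND
  if (any(w$nuc_x[free] < -1e-9 | w$nuc_x[free] > w$space[1] + 1e-9 |
          w$nuc_y[free] < -1e-9 | w$nuc_y[free] > w$space[2] + 1e-9)) {
    abort("nucleotide position outside the configuration space")
  }
  bound <- which(w$nuc_state == NT_BOUND)
  if (!identical(sort(w$nuc_host[bound]),
                 sort(which(w$tub_nt > 0L)))) {
    abort("bound-nucleotide hosts do not match tubulin nucleotide slots")
  }
  if (any(w$tub_nt > 0L & w$nuc_state[pmax(w$tub_nt, 1L)] != NT_BOUND)) {
    abort("tubulin names a nucleotide that is not in the bound state")
  }
  invisible(w)
}

#' @export
print.mt_world <- function(x, ...) {
  da <- dimer_alphas(x)
  cat(sprintf(
    "<mt_world> iteration %d: %d tubulins (%d alpha), %d nucleotides\n",
    x$iteration, n_tubulins(x), sum(x$tub_kind == KIND_ALPHA),
    n_nucleotides(x)))
  cat(sprintf("  dimers: %d (%d active); free GTP %d, free GDP %d\n",
              length(da), sum(dimer_active(x, da)),
              sum(x$nuc_state == NT_GTP), sum(x$nuc_state == NT_GDP)))
  invisible(x)
}

#' Agent coordinate table
#'
#' One row per agent (tubulins then nucleotides) with id, type, position,
#' orientation and state; the "final-frame coordinates" output of a run.
#'
#' @param w an `mt_world`.
#' @return a tibble.
#' @export
world_coordinates <- function(w) {
  w <- sync_bound_nucleotides(w)
  da <- dimer_alphas(w)
  act <- rep(FALSE, n_tubulins(w))
  if (length(da) > 0) {
    is_act <- dimer_active(w, da)
    act[da] <- is_act
    act[w$bond_a[da]] <- is_act
  }
  tub <- tibble::tibble(
    id = seq_len(n_tubulins(w)),
    type = ifelse(w$tub_kind == KIND_ALPHA, "alpha", "beta"),
    x = w$tub_x, y = w$tub_y, orientation = w$tub_orient,
    state = dplyr::case_when(
      act ~ "active_dimer",
      (w$tub_kind == KIND_ALPHA & w$bond_a > 0L) |
        (w$tub_kind == KIND_BETA & w$bond_b > 0L) ~ "inactive_dimer",
      TRUE ~ "monomer"))
  nuc <- tibble::tibble(
    id = n_tubulins(w) + seq_len(n_nucleotides(w)),
    type = "nucleotide",
    x = w$nuc_x, y = w$nuc_y, orientation = 0,
    state = c("GTP", "GDP", "bound")[w$nuc_state])
  dplyr::bind_rows(tub, nuc)
}
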