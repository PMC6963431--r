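# Interaction rules: heterodimer formation, GTP activation (protofilament
# and ring variants), dimer-dimer polymerization, GDP-to-GTP recovery and
# length-dependent terminal breakage, plus the per-iteration sweep that
# applies them in a fixed order. Candidate pairs are enumerated by trigger-
# zone proximity, processed nearest-first with ties broken by lower index,
# and every site undergoes at most one topology change per iteration.

# -- primitives shared by the sweep and the single-pair operations -----------

# rigidly move `moving`'s cluster so that its `moving_site` coincides with
# `fixed`'s `fixed_site` and the two site directions face each other
snap_to <- function(w, fixed, fixed_site, moving, moving_site, config) {
  af <- if (fixed_site == "A") w$site_a[fixed] else w$site_b[fixed]
  am <- if (moving_site == "A") w$site_a[moving] else w$site_b[moving]
  delta <- (w$tub_orient[fixed] + af - am + pi) - w$tub_orient[moving]
  delta <- delta - 2 * pi * round(delta / (2 * pi)) # keep orientations bounded
  mem <- which(w$cluster == w$cluster[moving])
  ca <- cos(delta)
  sa <- sin(delta)
  rx <- w$tub_x[mem] - w$tub_x[moving]
  ry <- w$tub_y[mem] - w$tub_y[moving]
  w$tub_x[mem] <- w$tub_x[moving] + ca * rx - sa * ry
  w$tub_y[mem] <- w$tub_y[moving] + sa * rx + ca * ry
  w$tub_orient[mem] <- w$tub_orient[mem] + delta
  dir <- w$tub_orient[fixed] + af
  dx <- w$tub_x[fixed] + 2 * config$tubulin_radius * cos(dir) -
    w$tub_x[moving]
  dy <- w$tub_y[fixed] + 2 * config$tubulin_radius * sin(dir) -
    w$tub_y[moving]
  w$tub_x[mem] <- w$tub_x[mem] + dx
  w$tub_y[mem] <- w$tub_y[mem] + dy
  w
}

# bond formation is treated as a perfectly inelastic junction: the merged
# cluster takes the mass-weighted mean velocity and zero spin
merge_velocities <- function(w, i, j, config) {
  mi <- which(w$cluster == w$cluster[i])
  mj <- which(w$cluster == w$cluster[j])
  m1 <- length(mi) * config$tubulin_mass
  m2 <- length(mj) * config$tubulin_mass
  vx <- (m1 * w$tub_vx[i] + m2 * w$tub_vx[j]) / (m1 + m2)
  vy <- (m1 * w$tub_vy[i] + m2 * w$tub_vy[j]) / (m1 + m2)
  all <- c(mi, mj)
  w$tub_vx[all] <- vx
  w$tub_vy[all] <- vy
  w$tub_om[all] <- 0
  w
}

form_intra_bond <- function(w, a, b, config) {
  w <- merge_velocities(w, a, b, config)
  mem_b <- which(w$cluster == w$cluster[b])
  w$bond_a[a] <- b
  w$bond_b[b] <- a
  w <- snap_to(w, a, "A", b, "B", config)
  w$cluster[mem_b] <- w$cluster[a]
  w
}

form_inter_bond <- function(w, alpha_b, beta_a, config) {
  same <- w$cluster[alpha_b] == w$cluster[beta_a]
  if (!same) {
    w <- merge_velocities(w, alpha_b, beta_a, config)
    # snap the smaller cluster onto the larger
    ni <- sum(w$cluster == w$cluster[alpha_b])
    nj <- sum(w$cluster == w$cluster[beta_a])
    if (nj <= ni) {
      mem <- which(w$cluster == w$cluster[beta_a])
      w$bond_b[alpha_b] <- beta_a
      w$bond_a[beta_a] <- alpha_b
      w <- snap_to(w, alpha_b, "B", beta_a, "A", config)
      w$cluster[mem] <- w$cluster[alpha_b]
    } else {
      mem <- which(w$cluster == w$cluster[alpha_b])
      w$bond_b[alpha_b] <- beta_a
      w$bond_a[beta_a] <- alpha_b
      w <- snap_to(w, beta_a, "A", alpha_b, "B", config)
      w$cluster[mem] <- w$cluster[beta_a]
    }
  } else {
    # cycle closure: geometry is already coincident, just set the bond
    w$bond_b[alpha_b] <- beta_a
    w$bond_a[beta_a] <- alpha_b
  }
  w
}

bind_gtp <- function(w, tub, nuc) {
  w$tub_nt[tub] <- nuc
  w$nuc_state[nuc] <- NT_BOUND
  w$nuc_host[nuc] <- tub
  w$nuc_x[nuc] <- w$tub_x[tub]
  w$nuc_y[nuc] <- w$tub_y[tub]
  w
}

release_as_gdp <- function(w, tub) {
  n <- w$tub_nt[tub]
  if (n > 0L) {
    w$nuc_state[n] <- NT_GDP
    w$nuc_host[n] <- 0L
    w$nuc_spawn[n] <- w$iteration
    w$nuc_x[n] <- w$tub_x[tub]
    w$nuc_y[n] <- w$tub_y[tub]
    w$nuc_vx[n] <- w$tub_vx[tub]
    w$nuc_vy[n] <- w$tub_vy[tub]
    w$tub_nt[tub] <- 0L
  }
  w
}

# detach a terminal dimer: remove its single inter-dimer bond, deactivate it
# (release both nucleotides as free GDP, mimicking hydrolysis) and reset any
# ring-displaced bond angles
break_dimer_off <- function(w, alpha_id, config) {
  beta_id <- w$bond_a[alpha_id]
  if (w$bond_b[alpha_id] > 0L) {
    other <- w$bond_b[alpha_id]
    w$bond_b[alpha_id] <- 0L
    w$bond_a[other] <- 0L
  } else if (w$bond_a[beta_id] > 0L) {
    other <- w$bond_a[beta_id]
    w$bond_a[beta_id] <- 0L
    w$bond_b[other] <- 0L
  }
  w <- release_as_gdp(w, alpha_id)
  w <- release_as_gdp(w, beta_id)
  w <- reset_bond_angles(w, alpha_id)
  w
}

ring_theta_rad <- function(config) config$ring_theta * pi / 180

apply_ring_displacement <- function(w, alphas, config) {
  theta <- ring_theta_rad(config)
  for (a in alphas) {
    b <- w$bond_a[a]
    # only free outward sites are displaced; the intra bond is untouched
    if (w$bond_b[a] == 0L) w$site_b[a] <- pi + theta / 2
    if (w$bond_a[b] == 0L) w$site_a[b] <- -theta / 2
  }
  w
}

# -- exported single-pair operations -----------------------------------------

#' Attempt heterodimer formation between two tubulins
#'
#' A bond forms only if one agent is an alpha and the other a beta tubulin,
#' the complementary sites (alpha's A, beta's B) are both free, and those
#' sites lie within each other's trigger zones. On success the bond snaps the
#' geometry (sites coincident, primary axes collinear) and the pair becomes
#' an inactive dimer. Any failed condition leaves the world unchanged; a
#' same-kind pair is not an error.
#'
#' @param w an `mt_world`.
#' @param a,b tubulin indices.
#' @param config an [mt_config()].
#' @return the (possibly unchanged) world.
#' @export
try_form_heterodimer <- function(w, a, b, config) {
  if (w$tub_kind[a] == w$tub_kind[b]) return(w)
  if (w$tub_kind[a] == KIND_BETA) {
    tmp <- a
    a <- b
    b <- tmp
  }
  if (w$bond_a[a] != 0L || w$bond_b[a] != 0L ||
      w$bond_a[b] != 0L || w$bond_b[b] != 0L) {
    return(w)
  }
  pa <- site_xy(w, a, "A")
  pb <- site_xy(w, b, "B")
  if (sqrt(sum((pa - pb)^2)) > config$trigger_radius) return(w)
  w <- form_intra_bond(w, a, b, config)
  recompute_clusters(w)
}

# choose two distinct free GTPs for a dimer, one inside each member's
# trigger zone, minimising the summed distance; `excluded` are GTP indices
# already claimed this sweep. Returns NULL or list(gtp_a, gtp_b, total_d).
pick_gtp_pair <- function(w, alpha_id, beta_id, config, excluded = integer()) {
  gtps <- setdiff(which(w$nuc_state == NT_GTP), excluded)
  if (length(gtps) < 2) return(NULL)
  da <- sqrt((w$nuc_x[gtps] - w$tub_x[alpha_id])^2 +
               (w$nuc_y[gtps] - w$tub_y[alpha_id])^2)
  db <- sqrt((w$nuc_x[gtps] - w$tub_x[beta_id])^2 +
               (w$nuc_y[gtps] - w$tub_y[beta_id])^2)
  in_a <- which(da <= config$trigger_radius)
  in_b <- which(db <= config$trigger_radius)
  if (length(in_a) == 0 || length(in_b) == 0) return(NULL)
  best <- NULL
  for (i in in_a) { # candidate sets are tiny; exact assignment
    for (j in in_b) {
      if (i == j) next
      tot <- da[i] + db[j]
      if (is.null(best) || tot < best$total_d) {
        best <- list(gtp_a = gtps[i], gtp_b = gtps[j], total_d = tot)
      }
    }
  }
  best
}

#' Attempt GTP activation of an inactive dimer
#'
#' Activation is atomic at the dimer level: it requires two distinct free
#' GTPs, one inside the trigger zone of each member tubulin, and a single
#' uniform draw `P_random <= P_GTP` then binds both simultaneously (free
#' GDPs never qualify). On activation in ring mode the free bond angles are
#' additionally displaced by the ring junction angle.
#'
#' @param w an `mt_world`.
#' @param alpha_id tubulin index of the dimer's alpha member.
#' @param config an [mt_config()].
#' @return the world, activated or unchanged.
#' @export
try_activate_dimer <- function(w, alpha_id, config) {
  beta_id <- w$bond_a[alpha_id]
  if (w$tub_kind[alpha_id] != KIND_ALPHA || beta_id == 0L) {
    abort("`alpha_id` must be the alpha member of a formed dimer")
  }
  if (any(dimer_active(w, alpha_id))) return(w)
  pair <- pick_gtp_pair(w, alpha_id, beta_id, config)
  if (is.null(pair)) return(w)
  if (runif(1) <= config$p_gtp) {
    w <- bind_gtp(w, alpha_id, pair$gtp_a)
    w <- bind_gtp(w, beta_id, pair$gtp_b)
    if (w$mode == "ring") {
      w <- apply_ring_displacement(w, alpha_id, config)
    }
  }
  w
}

#' Attempt a polymerization bond between two dimers
#'
#' An active dimer bonds with another dimer when the candidate free terminal
#' sites (the alpha member's B site of one dimer and the beta member's A site
#' of the other) are complementary, free, and within trigger distance. By
#' default both dimers must be active; with
#' `config$require_partner_active = FALSE` only one of them must be. The
#' joined chains snap to the current bond angles (straight in protofilament
#' mode, bent by the junction angle in ring mode). A bond between the two
#' termini of one chain closes it into a ring, after which it accepts no
#' further bonds.
#'
#' @param w an `mt_world`.
#' @param d1,d2 alpha-member tubulin indices of the two dimers.
#' @param config an [mt_config()].
#' @return the (possibly unchanged) world.
#' @export
try_bond_dimers <- function(w, d1, d2, config) {
  for (d in c(d1, d2)) {
    if (w$tub_kind[d] != KIND_ALPHA || w$bond_a[d] == 0L) {
      abort("`d1` and `d2` must be alpha members of formed dimers")
    }
  }
  a1 <- dimer_active(w, d1)
  a2 <- dimer_active(w, d2)
  if (config$require_partner_active) {
    if (!a1 || !a2) return(w)
  } else if (!a1 && !a2) {
    return(w)
  }
  # two possible complementary pairings of free termini
  cands <- list(c(d1, w$bond_a[d2]), c(d2, w$bond_a[d1]))
  best <- NULL
  best_d <- Inf
  for (p in cands) {
    ab <- p[1]
    ba <- p[2]
    if (w$bond_b[ab] != 0L || w$bond_a[ba] != 0L) next
    dd <- sqrt(sum((site_xy(w, ab, "B") - site_xy(w, ba, "A"))^2))
    if (dd <= config$trigger_radius && dd < best_d) {
      best <- p
      best_d <- dd
    }
  }
  if (is.null(best)) return(w)
  w2 <- polymerize_pair(w, best[1], best[2], config)
  w2
}

# capacity / closure logic shared by the sweep and try_bond_dimers;
# returns the world unchanged when the bond is refused
polymerize_pair <- function(w, alpha_b, beta_a, config) {
  same <- w$cluster[alpha_b] == w$cluster[beta_a]
  if (same) {
    if (w$mode != "ring") return(w)
    len <- sum(w$cluster == w$cluster[alpha_b]) / 2
    if (len != ring_capacity(config$ring_theta)) return(w)
  } else if (w$mode == "ring") {
    len <- (sum(w$cluster == w$cluster[alpha_b]) +
              sum(w$cluster == w$cluster[beta_a])) / 2
    if (len > ring_capacity(config$ring_theta)) return(w)
  }
  w <- form_inter_bond(w, alpha_b, beta_a, config)
  recompute_clusters(w)
}

#' GDP-to-GTP recovery
#'
#' Every free GDP whose time in the GDP state has reached `limit_gdp`
#' seconds flips back to GTP (the duration function standing in for
#' re-phosphorylation); all other nucleotides are unchanged. With the
#' defaults (`limit_gdp` 3 s, `dt` 0.01 s) a GDP recovers after exactly 300
#' iterations.
#'
#' @param w an `mt_world`.
#' @param config an [mt_config()].
#' @return the world.
#' @export
gdp_to_gtp_update <- function(w, config) {
  idx <- which(w$nuc_state == NT_GDP &
                 (w$iteration - w$nuc_spawn) * w$dt >= config$limit_gdp)
  if (length(idx) > 0) w$nuc_state[idx] <- NT_GTP
  w
}

#' Length-dependent breakage probability
#'
#' The probability that a terminal dimer of a protofilament of length
#' `proto_length` breaks off at a breakage check:
#' `1 - (1 - p_break)^proto_length`. Equal to `p_break` at length 1 and
#' strictly increasing in length for `p_break` in (0, 1).
#'
#' @param p_break per-dimer breakage constant in `[0, 1]`.
#' @param proto_length chain length in dimers (>= 1); vectorised.
#' @return breakage probability in `[0, 1]`.
#' @examples
#' compute_break_probability(0.2, 3) # 1 - 0.8^3 = 0.488
#' @export
compute_break_probability <- function(p_break, proto_length) {
  if (!is.numeric(p_break) || any(p_break < 0) || any(p_break > 1)) {
    abort("`p_break` must lie in [0, 1]")
  }
  if (!is.numeric(proto_length) || any(proto_length < 1)) {
    abort("`proto_length` must be >= 1")
  }
  1 - (1 - p_break)^proto_length
}

#' Attempt terminal breakage of a chain dimer
#'
#' The dimer must be a terminal member of an open chain (exactly one
#' inter-dimer bond); calling this on a non-terminal dimer is a contract
#' violation. A uniform draw against [compute_break_probability()] at the
#' chain's current length decides the break; on success the terminal bond is
#' removed, the dimer stays intact but turns inactive, and its two bound
#' nucleotides are released as free GDP particles timestamped at the current
#' iteration.
#'
#' @param w an `mt_world`.
#' @param alpha_id alpha-member tubulin index of the terminal dimer.
#' @param config an [mt_config()].
#' @return the (possibly unchanged) world.
#' @export
try_break_terminal <- function(w, alpha_id, config) {
  beta_id <- w$bond_a[alpha_id]
  if (w$tub_kind[alpha_id] != KIND_ALPHA || beta_id == 0L) {
    abort("`alpha_id` must be the alpha member of a formed dimer")
  }
  n_inter <- (w$bond_b[alpha_id] > 0L) + (w$bond_a[beta_id] > 0L)
  if (n_inter != 1L) {
    abort("dimer is not a terminal member of an open chain")
  }
  len <- sum(w$cluster == w$cluster[alpha_id]) / 2
  p <- compute_break_probability(config$p_break, len)
  if (runif(1) <= p) {
    w <- break_dimer_off(w, alpha_id, config)
    w <- recompute_clusters(w)
  }
  w
}

#' Can this ring-mode world still complete a ring?
#'
#' In ring mode without extended rules, chains only ever grow (by lone
#' dimers or by merging with other chains), so a ring can still close only
#' if some subset of the current open-chain lengths, topped up with dimers
#' that are not yet chained (lone dimers, plus dimers that could still form
#' from free monomers), sums to exactly the ring capacity. When that is
#' impossible the chain inventory is deadlocked and no ring will ever close
#' in this trial; rare-event run protocols use this to abandon dead trials
#' early.
#'
#' @param w an `mt_world` in ring mode.
#' @param config an [mt_config()].
#' @return TRUE if a closed ring exists or can still form.
#' @export
ring_completion_possible <- function(w, config) {
  cap <- ring_capacity(config$ring_theta)
  csize <- tabulate(w$cluster)
  nb <- length(csize)
  cfree <- tabulate(w$cluster[w$bond_a == 0L], nbins = nb) +
    tabulate(w$cluster[w$bond_b == 0L], nbins = nb)
  chains <- which(csize >= 4L)
  if (any(cfree[chains] == 0L)) return(TRUE) # a ring already closed
  lens <- csize[chains] / 2
  lone_dimers <- sum(csize == 2L)
  mono <- w$bond_a == 0L & w$bond_b == 0L
  potential <- min(sum(mono & w$tub_kind == KIND_ALPHA),
                   sum(mono & w$tub_kind == KIND_BETA))
  singles <- lone_dimers + potential
  sums <- 0L # subset sums of chain lengths, bounded by the capacity
  for (len in lens) {
    sums <- unique(c(sums, sums + as.integer(len)))
    sums <- sums[sums <= cap]
  }
  any(cap - sums <= singles)
}

# -- the per-iteration sweep -------------------------------------------------

#' Apply all interaction rules for one iteration
#'
#' Fixed order per iteration: GDP recovery, heterodimer formation, GTP
#' activation, dimer-dimer polymerization, then (with extended rules, at
#' breakage-check iterations only) terminal breakage. Candidate pairs are
#' enumerated by trigger-zone proximity and processed nearest-first with
#' ties broken by lower index; each bonding site and each nucleotide takes
#' part in at most one topology change per iteration.
#'
#' @param w an `mt_world`.
#' @param config an [mt_config()].
#' @return the world after one rule sweep.
#' @export
rules_sweep <- function(w, config) {
  w <- gdp_to_gtp_update(w, config)
  w <- sweep_dimerization(w, config)
  w <- sweep_activation(w, config)
  w <- sweep_polymerization(w, config)
  if (config$extended_rules && w$iteration > 0L &&
      w$iteration %% config$break_check_interval == 0L) {
    w <- sweep_breakage(w, config)
  }
  w
}

sweep_dimerization <- function(w, config) {
  mono <- w$bond_a == 0L & w$bond_b == 0L
  ai <- which(mono & w$tub_kind == KIND_ALPHA)
  bi <- which(mono & w$tub_kind == KIND_BETA)
  if (length(ai) == 0 || length(bi) == 0) return(w)
  pa <- site_xy(w, ai, "A")
  pb <- site_xy(w, bi, "B")
  cand <- cpp_pairs_within(pa[, 1], pa[, 2], pb[, 1], pb[, 2],
                           config$trigger_radius)
  if (length(cand$i) == 0) return(w)
  taken_a <- logical(length(ai))
  taken_b <- logical(length(bi))
  changed <- FALSE
  for (k in seq_along(cand$i)) {
    ia <- cand$i[k]
    ib <- cand$j[k]
    if (taken_a[ia] || taken_b[ib]) next
    w <- form_intra_bond(w, ai[ia], bi[ib], config)
    taken_a[ia] <- TRUE
    taken_b[ib] <- TRUE
    changed <- TRUE
  }
  if (changed) w <- recompute_clusters(w)
  w
}

sweep_activation <- function(w, config) {
  da <- dimer_alphas(w)
  if (length(da) == 0) return(w)
  inact <- da[!dimer_active(w, da)]
  if (length(inact) == 0) return(w)
  gtps <- which(w$nuc_state == NT_GTP)
  if (length(gtps) < 2) return(w)
  # one proximity query for all members of all inactive dimers
  betas <- w$bond_a[inact]
  k <- length(inact)
  mem <- c(inact, betas) # members 1..k alphas, k+1..2k betas
  cand <- cpp_pairs_within(w$tub_x[mem], w$tub_y[mem], w$nuc_x[gtps],
                           w$nuc_y[gtps], config$trigger_radius)
  if (length(cand$i) < 2) return(w)
  # per-member candidate GTPs, already sorted nearest-first
  by_mem <- split(seq_along(cand$i), cand$i)
  avail <- rep(TRUE, length(gtps))
  # best (min summed distance) distinct-GTP pair per dimer, given current
  # availability; candidate lists are tiny so exact search is fine
  best_pair <- function(i) {
    ra <- by_mem[[as.character(i)]]
    rb <- by_mem[[as.character(k + i)]]
    if (is.null(ra) || is.null(rb)) return(NULL)
    best <- NULL
    for (p in ra) {
      if (!avail[cand$j[p]]) next
      for (q in rb) {
        if (!avail[cand$j[q]] || cand$j[p] == cand$j[q]) next
        tot <- cand$d[p] + cand$d[q]
        if (is.null(best) || tot < best$total_d) {
          best <- list(a = cand$j[p], b = cand$j[q], total_d = tot)
        }
      }
    }
    best
  }
  pairs <- lapply(seq_len(k), best_pair)
  have <- which(!vapply(pairs, is.null, logical(1)))
  if (length(have) == 0) return(w)
  # closest assembled pair first, ties by lower alpha index
  ord <- have[order(vapply(pairs[have], `[[`, numeric(1), "total_d"),
                    inact[have])]
  for (i in ord) {
    pair <- best_pair(i) # re-pick from still-unclaimed GTPs
    if (is.null(pair)) next
    if (runif(1) <= config$p_gtp) {
      w <- bind_gtp(w, inact[i], gtps[pair$a])
      w <- bind_gtp(w, betas[i], gtps[pair$b])
      avail[c(pair$a, pair$b)] <- FALSE
      if (w$mode == "ring") {
        w <- apply_ring_displacement(w, inact[i], config)
      }
    }
  }
  w
}

sweep_polymerization <- function(w, config) {
  da <- dimer_alphas(w)
  if (length(da) < 2) return(w)
  act <- dimer_active(w, da)
  elig <- if (config$require_partner_active) da[act] else da
  if (length(elig) < 2) return(w)
  a_of <- integer(n_tubulins(w)) # active flag lookup by alpha id
  a_of[da] <- as.integer(act)
  ab <- elig[w$bond_b[elig] == 0L] # free B sites on alpha members
  betas <- w$bond_a[elig]
  ba <- betas[w$bond_a[betas] == 0L] # free A sites on beta members
  if (length(ab) == 0 || length(ba) == 0) return(w)
  pb <- site_xy(w, ab, "B")
  pa <- site_xy(w, ba, "A")
  cand <- cpp_pairs_within(pb[, 1], pb[, 2], pa[, 1], pa[, 2],
                           config$trigger_radius)
  if (length(cand$i) == 0) return(w)
  changed <- FALSE
  for (k in seq_along(cand$i)) {
    i <- ab[cand$i[k]]       # alpha whose B site would bond
    j <- ba[cand$j[k]]       # beta whose A site would bond
    if (w$bond_b[i] != 0L || w$bond_a[j] != 0L) next
    if (!config$require_partner_active) {
      # literal reading: at least one of the two dimers must be active
      alpha_j <- w$bond_b[j] # j's intra partner is its dimer's alpha
      if (a_of[i] == 0L && (alpha_j == 0L || a_of[alpha_j] == 0L)) next
    }
    w2 <- polymerize_pair(w, i, j, config)
    if (!identical(w2$bond_b[i], w$bond_b[i])) changed <- TRUE
    w <- w2
  }
  if (changed) w <- recompute_clusters(w)
  w
}

sweep_breakage <- function(w, config) {
  da <- dimer_alphas(w)
  if (length(da) == 0) return(w)
  betas <- w$bond_a[da]
  n_inter <- (w$bond_b[da] > 0L) + (w$bond_a[betas] > 0L)
  terminal <- da[n_inter == 1L]
  if (length(terminal) == 0) return(w)
  csize <- tabulate(w$cluster)
  # draw against the pre-check chain lengths for every terminal dimer first,
  # then apply, so both ends of a chain are judged at the same length
  lens <- csize[w$cluster[terminal]] / 2
  p <- compute_break_probability(config$p_break, lens)
  draws <- runif(length(terminal))
  hit <- terminal[draws <= p]
  if (length(hit) == 0) return(w)
  for (a in hit) w <- break_dimer_off(w, a, config)
  recompute_clusters(w)
}
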