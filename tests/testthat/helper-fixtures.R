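# Fixture builders: small worlds with hand-placed agents, assembled through
# the package's own bonding operations so snapped geometry is exact.

# config for hand-built fixtures: roomy tray, deterministic GTP binding;
# caller overrides take precedence over these defaults
fixture_config <- function(...) {
  args <- list(...)
  defaults <- list(n_alpha = 0L, n_beta = 0L, n_nucleotides = 0L,
                   p_gtp = 1, space_width = 4, space_height = 4)
  args <- c(args, defaults[setdiff(names(defaults), names(args))])
  do.call(mt_config, args)
}

# append one activated (GTP-loaded) dimer with the alpha at `pos`, the beta
# snapped on the alpha's A side along `orient`; returns list(w, alpha)
add_active_dimer <- function(w, cfg, pos, orient = 0) {
  r <- cfg$tubulin_radius
  a <- length(w$tub_kind) + 1L
  b <- a + 1L
  w <- add_tubulin(w, "alpha", pos, orient)
  w <- add_tubulin(w, "beta", pos + 2 * r * c(cos(orient), sin(orient)),
                   orient)
  w <- try_form_heterodimer(w, a, b, cfg)
  stopifnot(w$bond_a[a] == b)
  w <- add_nucleotide(w, c(w$tub_x[a], w$tub_y[a]))
  w <- add_nucleotide(w, c(w$tub_x[b], w$tub_y[b]))
  w <- try_activate_dimer(w, a, cfg)
  stopifnot(all(w$tub_nt[c(a, b)] > 0L))
  list(w = w, alpha = a)
}

# a chain of n active dimers built by sequential polymerization; returns
# list(w, alphas) with alphas in chain order (first element carries the free
# beta-A terminus, last the free alpha-B terminus)
fixture_chain <- function(n, cfg = fixture_config(),
                          start = c(2.8, 2), orient = pi) {
  grow_chain_at(new_world(cfg), cfg, n, start, orient)
}

# same, appended to an existing world
grow_chain_at <- function(w, cfg, n, start, orient = pi) {
  r <- cfg$tubulin_radius
  res <- add_active_dimer(w, cfg, start, orient)
  w <- res$w
  alphas <- res$alpha
  while (length(alphas) < n) {
    term <- alphas[length(alphas)]
    s <- mtswarm:::site_xy(w, term, "B") # free terminal site of the chain
    th <- w$tub_orient[term]
    # place the new dimer with its beta's A site on top of `s`
    beta_pos <- as.numeric(s)
    alpha_pos <- beta_pos - 2 * r * c(cos(th), sin(th))
    res <- add_active_dimer(w, cfg, alpha_pos, th)
    w <- res$w
    w2 <- try_bond_dimers(w, term, res$alpha, cfg)
    stopifnot(w2$bond_b[term] > 0L)
    w <- w2
    alphas <- c(alphas, res$alpha)
  }
  list(w = w, alphas = alphas)
}

# independent brute-force chain enumeration used as an oracle against the
# package's cluster-based statistics: walks inter-dimer bonds explicitly.
# Bond topology: a dimer's alpha `a` has its beta at bond_a[a]; the next
# dimer (through alpha's B site) has its beta at bond_b[a] and that beta's
# alpha at bond_b[beta]; the previous dimer's alpha is bond_a[own beta].
oracle_chains <- function(w) {
  alphas <- which(w$tub_kind == 1L & w$bond_a > 0L)
  seen <- integer()
  lens <- integer()
  closed <- logical()
  for (a in alphas) {
    if (a %in% seen) next
    members <- a
    is_closed <- FALSE
    cur <- a
    repeat { # forward, through the alpha's B site
      nb <- w$bond_b[cur]
      if (nb == 0L) break
      na <- w$bond_b[nb]
      if (na %in% members) {
        is_closed <- TRUE
        break
      }
      members <- c(members, na)
      cur <- na
    }
    if (!is_closed) {
      cur <- a
      repeat { # backward, through the beta's A site
        pa <- w$bond_a[w$bond_a[cur]]
        if (pa == 0L) break
        if (pa %in% members) {
          is_closed <- TRUE
          break
        }
        members <- c(members, pa)
        cur <- pa
      }
    }
    seen <- c(seen, members)
    lens <- c(lens, length(members))
    closed <- c(closed, is_closed)
  }
  keep <- lens >= 2L
  list(lengths = lens[keep], closed = closed[keep],
       n_lone = sum(lens == 1L))
}
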