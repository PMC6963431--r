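# Interaction rules: dimerization, activation, polymerization, recovery and
# terminal breakage.

test_that("heterodimer formation needs complementary kinds in trigger range", {
  cfg <- fixture_config()
  w <- new_world(cfg)
  w <- add_tubulin(w, "alpha", c(1, 1), 0)
  w <- add_tubulin(w, "beta", c(1.05, 1), 0) # sites 0.01 apart, in range
  w <- add_tubulin(w, "alpha", c(2, 2), 0)
  w <- add_tubulin(w, "alpha", c(2.05, 2), pi) # same kind, in range
  w <- add_tubulin(w, "beta", c(3, 3), 0) # far from everything
  w1 <- try_form_heterodimer(w, 1L, 2L, cfg)
  expect_identical(w1$bond_a[1], 2L)
  expect_identical(w1$bond_b[2], 1L)
  expect_false(any(dimer_active(w1, 1L))) # newly formed dimers are inactive
  # snapped geometry: sites coincide, axes collinear
  expect_equal(mtswarm:::site_xy(w1, 1L, "A"),
               mtswarm:::site_xy(w1, 2L, "B"), tolerance = 1e-12)
  expect_identical(try_form_heterodimer(w, 3L, 4L, cfg)$bond_a[3], 0L)
  expect_identical(try_form_heterodimer(w, 1L, 5L, cfg)$bond_a[1], 0L)
  # an occupied site refuses a second bond
  w2 <- add_tubulin(w1, "beta", c(1.05, 1.06), 0)
  expect_identical(try_form_heterodimer(w2, 1L, 6L, cfg)$bond_a[1], 2L)
})

test_that("activation is atomic: two distinct GTPs, one per member", {
  cfg <- fixture_config()
  w <- new_world(cfg)
  w <- add_tubulin(w, "alpha", c(2, 2), 0)
  w <- add_tubulin(w, "beta", c(2.06, 2), 0)
  w <- try_form_heterodimer(w, 1L, 2L, cfg)
  # one GTP in range of only one member: no binding, dimer stays inactive
  w1 <- add_nucleotide(w, c(1.98, 2))
  set.seed(1)
  w1 <- try_activate_dimer(w1, 1L, cfg)
  expect_identical(w1$tub_nt, c(0L, 0L))
  expect_false(any(dimer_active(w1, 1L)))
  # a second GTP near the beta: both bind in one activation event
  w2 <- add_nucleotide(w1, c(2.10, 2))
  w2 <- try_activate_dimer(w2, 1L, cfg)
  expect_true(all(dimer_active(w2, 1L)))
  expect_identical(sum(w2$nuc_state == 3L), 2L)
  expect_identical(sort(w2$tub_nt), 1:2)
  # a single GTP in range of both members cannot serve both
  w5 <- add_nucleotide(w, c(2.03, 2))
  w5 <- try_activate_dimer(w5, 1L, cfg)
  expect_identical(w5$tub_nt, c(0L, 0L))
  # free GDPs never activate
  w3 <- add_nucleotide(w, c(1.98, 2), state = "GDP")
  w3 <- add_nucleotide(w3, c(2.10, 2), state = "GDP")
  w3 <- try_activate_dimer(w3, 1L, cfg)
  expect_identical(w3$tub_nt, c(0L, 0L))
  # P_GTP = 0 never activates even with both GTPs in contact
  cfg0 <- fixture_config(p_gtp = 0)
  w4 <- add_nucleotide(add_nucleotide(w, c(1.98, 2)), c(2.10, 2))
  for (i in 1:20) w4 <- try_activate_dimer(w4, 1L, cfg0)
  expect_identical(w4$tub_nt, c(0L, 0L))
})

test_that("empirical activation frequency matches P_GTP", {
  cfg <- fixture_config(p_gtp = 0.5)
  w <- new_world(cfg)
  w <- add_tubulin(w, "alpha", c(2, 2), 0)
  w <- add_tubulin(w, "beta", c(2.06, 2), 0)
  w <- try_form_heterodimer(w, 1L, 2L, cfg)
  w <- add_nucleotide(w, c(1.98, 2))
  w <- add_nucleotide(w, c(2.10, 2))
  n <- 10000
  set.seed(123)
  hits <- 0L
  for (i in seq_len(n)) {
    wi <- try_activate_dimer(w, 1L, cfg)
    if (any(dimer_active(wi, 1L))) hits <- hits + 1L
  }
  expect_lt(abs(hits / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("polymerization needs active dimers and free complementary termini", {
  cfg <- fixture_config()
  w <- new_world(cfg)
  r1 <- add_active_dimer(w, cfg, c(2, 2), 0)
  # second dimer with its beta-A terminus near dimer 1's alpha-B site
  r2 <- add_active_dimer(r1$w, cfg, c(1.84, 2), 0)
  w <- try_bond_dimers(r2$w, r1$alpha, r2$alpha, cfg)
  expect_gt(w$bond_b[r1$alpha], 0L)
  oc <- oracle_chains(w)
  expect_identical(oc$lengths, 2L)
  # inactive partner refuses under the default (both-active) reading
  w0 <- new_world(cfg)
  p1 <- add_active_dimer(w0, cfg, c(2, 2), 0)
  w0 <- p1$w
  w0 <- add_tubulin(w0, "alpha", c(1.84, 2), 0)
  w0 <- add_tubulin(w0, "beta", c(1.90, 2), 0)
  w0 <- try_form_heterodimer(w0, 3L, 4L, cfg)
  wb <- try_bond_dimers(w0, p1$alpha, 3L, cfg)
  expect_identical(wb$bond_b[p1$alpha], 0L)
  # the literal single-active reading is available as a toggle
  cfg_lit <- fixture_config(require_partner_active = FALSE)
  wl <- try_bond_dimers(w0, p1$alpha, 3L, cfg_lit)
  expect_gt(wl$bond_b[p1$alpha], 0L)
})

test_that("chains stay linear: occupied termini refuse further bonds", {
  cfg <- fixture_config()
  fx <- fixture_chain(3, cfg)
  w <- fx$w
  mid <- fx$alphas[2]
  expect_identical(w$bond_b[mid] > 0L, TRUE)
  # a fresh active dimer next to the chain interior cannot branch: bonding
  # to the middle dimer's occupied B terminus is refused
  res <- add_active_dimer(w, cfg, c(w$tub_x[mid], w$tub_y[mid] + 0.08), 0)
  w2 <- try_bond_dimers(res$w, mid, res$alpha, cfg)
  expect_identical(w2$bond_b[mid], w$bond_b[mid])
  validate_world(w2)
})

test_that("GDP recovery follows the duration rule exactly", {
  cfg <- fixture_config(limit_gdp = 3)
  w <- new_world(cfg)
  w <- add_nucleotide(w, c(1, 1), state = "GDP", spawn_iteration = 0L)
  w$iteration <- 299L
  w <- gdp_to_gtp_update(w, cfg)
  expect_identical(w$nuc_state, 2L) # still GDP at 2.99 s
  w$iteration <- 300L
  w <- gdp_to_gtp_update(w, cfg)
  expect_identical(w$nuc_state, 1L) # GTP at exactly 3.00 s
  # GTP input is unchanged; limit 0 converts on the next update
  w2 <- add_nucleotide(new_world(cfg), c(1, 1), state = "GTP")
  expect_identical(gdp_to_gtp_update(w2, cfg)$nuc_state, 1L)
  cfg0 <- fixture_config(limit_gdp = 0)
  w3 <- add_nucleotide(new_world(cfg0), c(1, 1), state = "GDP")
  expect_identical(gdp_to_gtp_update(w3, cfg0)$nuc_state, 1L)
})

test_that("breakage probability matches its closed form and is monotone", {
  expect_equal(compute_break_probability(0.1, 1), 0.1)
  expect_equal(compute_break_probability(0, 7), 0)
  expect_equal(compute_break_probability(0.2, 3), 0.488)
  expect_equal(compute_break_probability(1, 5), 1)
  for (p in c(0.05, 0.3, 0.7)) {
    for (len in 1:20) {
      expect_equal(compute_break_probability(p, len), 1 - (1 - p)^len)
    }
    v <- compute_break_probability(p, 1:20)
    expect_true(all(diff(v) > 0))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(compute_break_probability(0.2, 0), ">= 1")
  expect_error(compute_break_probability(1.2, 1), "\\[0, 1\\]")
})

test_that("terminal breakage detaches, deactivates and releases GDP", {
  cfg <- fixture_config(p_break = 1, extended_rules = TRUE)
  fx <- fixture_chain(2, cfg)
  w <- fx$w
  set.seed(2)
  w <- try_break_terminal(w, fx$alphas[1], cfg)
  # one lone inactive dimer + one lone active dimer, 2 free GDPs
  expect_identical(w$bond_b[fx$alphas], c(0L, 0L))
  expect_identical(sum(w$nuc_state == 2L), 2L)
  expect_false(any(dimer_active(w, fx$alphas[1])))
  expect_true(all(dimer_active(w, fx$alphas[2])))
  expect_identical(w$nuc_spawn[w$nuc_state == 2L], rep(w$iteration, 2))
  validate_world(w)
  # p_break = 0 never breaks
  cfg0 <- fixture_config(p_break = 0, extended_rules = TRUE)
  fx0 <- fixture_chain(2, cfg0)
  w0 <- try_break_terminal(fx0$w, fx0$alphas[1], cfg0)
  expect_gt(w0$bond_b[fx0$alphas[1]], 0L)
  # a non-terminal dimer is a contract violation
  fx3 <- fixture_chain(3, cfg)
  expect_error(try_break_terminal(fx3$w, fx3$alphas[2], cfg),
               "not a terminal")
})

test_that("breakage only ever removes bonds at chain termini", {
  cfg <- fixture_config(p_break = 1, extended_rules = TRUE,
                        break_check_interval = 1)
  fx <- fixture_chain(5, cfg)
  w <- fx$w
  w$iteration <- 1L # a break-check iteration
  inner_before <- w$bond_b[fx$alphas[2:3]]
  set.seed(3)
  w2 <- rules_sweep(w, cfg)
  # both terminal dimers detach at P = 1; the three interior bonds of the
  # remaining 3-chain are kept except those incident to the old termini
  oc <- oracle_chains(w2)
  expect_identical(oc$lengths, 3L)
  expect_identical(w2$bond_b[fx$alphas[2:3]], inner_before)
  validate_world(w2)
})

test_that("ring closure happens at exactly the geometric capacity", {
  cfg <- fixture_config(mode = "ring", ring_theta = 30, space_width = 6,
                        space_height = 6)
  fx <- fixture_chain(12, cfg, start = c(3, 3))
  w <- try_bond_dimers(fx$w, fx$alphas[12], fx$alphas[1], cfg)
  oc <- oracle_chains(w)
  expect_identical(oc$lengths, 12L)
  expect_true(oc$closed)
  expect_identical(mt_snapshot(w)$closed_ring_count, 1)
  # a closed ring accepts no further bonds (no free sites remain)
  res <- add_active_dimer(w, cfg, c(3, 2.5), 0)
  w2 <- try_bond_dimers(res$w, fx$alphas[5], res$alpha, cfg)
  expect_identical(w2$bond_b[res$alpha], 0L)
  # an 11-chain's termini are a dimer-length apart: never within trigger
  fx11 <- fixture_chain(11, cfg, start = c(3, 3))
  gap <- sqrt(sum((mtswarm:::site_xy(fx11$w, fx11$alphas[11], "B") -
                     mtswarm:::site_xy(fx11$w, fx11$alphas[1], "A"))^2))
  expect_gt(gap, cfg$trigger_radius)
})

test_that("ring-mode merges refuse chains beyond the ring capacity", {
  cfg <- fixture_config(mode = "ring", ring_theta = 30, space_width = 8,
                        space_height = 8)
  fx <- fixture_chain(8, cfg, start = c(4, 5))
  # build a 5-chain whose beta-A terminus sits near the 8-chain's B terminus
  s <- mtswarm:::site_xy(fx$w, fx$alphas[8], "B")
  w <- fx$w
  r <- cfg$tubulin_radius
  th <- w$tub_orient[fx$alphas[8]]
  res5 <- add_active_dimer(w, cfg, as.numeric(s) - 2 * r * c(cos(th), sin(th)), th)
  w <- res5$w
  five <- res5$alpha
  for (k in 1:4) {
    term <- five[length(five)]
    s2 <- mtswarm:::site_xy(w, term, "B")
    th2 <- w$tub_orient[term]
    resk <- add_active_dimer(w, cfg, as.numeric(s2) - 2 * r * c(cos(th2), sin(th2)), th2)
    w <- resk$w
    w <- try_bond_dimers(w, term, resk$alpha, cfg)
    five <- c(five, resk$alpha)
  }
  expect_identical(sort(oracle_chains(w)$lengths), c(5L, 8L))
  # 8 + 5 = 13 > 12: the merge is refused
  w2 <- try_bond_dimers(w, fx$alphas[8], five[1], cfg)
  expect_identical(w2$bond_b[fx$alphas[8]], 0L)
})

test_that("rule cascade assembles an active dimer from a staged contact", {
  cfg <- fixture_config()
  w <- new_world(cfg)
  w <- add_tubulin(w, "alpha", c(2, 2), 0)
  w <- add_tubulin(w, "beta", c(2.05, 2), 0)
  w <- add_nucleotide(w, c(1.97, 2))
  w <- add_nucleotide(w, c(2.11, 2))
  set.seed(6)
  w <- rules_sweep(w, cfg)
  w <- rules_sweep(w, cfg)
  expect_true(all(dimer_active(w, 1L)))
  expect_identical(sum(w$nuc_state == 1L), 0L)
  validate_world(w)
  # an empty world passes through unchanged
  we <- rules_sweep(new_world(cfg), cfg)
  expect_identical(n_tubulins(we), 0L)
})

test_that("nucleotide conservation holds through bind/release cycles", {
  cfg <- mt_config(n_alpha = 6, n_beta = 6, n_nucleotides = 12,
                   space_width = 0.4, space_height = 0.4,
                   extended_rules = TRUE, p_break = 0.5,
                   break_check_interval = 20, iterations = 2000,
                   trials = 1, seed = 8)
  set.seed(9)
  w <- init_world(cfg)
  for (i in 1:2000) {
    w <- mtswarm:::advance_world(w, cfg)
    w <- rules_sweep(w, cfg)
    total <- sum(w$nuc_state == 1L) + sum(w$nuc_state == 2L) +
      sum(w$nuc_state == 3L)
    expect_identical(total, 12L)
    expect_identical(sum(w$nuc_state == 3L), sum(w$tub_nt > 0L))
  }
  # every dimer pairs one alpha with one beta
  da <- mtswarm:::dimer_alphas(w)
  expect_true(all(w$tub_kind[da] == 1L))
  expect_true(all(w$tub_kind[w$bond_a[da]] == 2L))
  validate_world(w)
})

test_that("a zero-GTP world forms inactive dimers but never chains", {
  cfg <- mt_config(n_alpha = 6, n_beta = 6, n_nucleotides = 0,
                   space_width = 0.3, space_height = 0.3,
                   iterations = 3000, trials = 1, seed = 10)
  run <- mt_run(cfg)
  td <- tidy(run)
  expect_true(all(td$active_dimers == 0))
  expect_true(all(td$chain_count == 0))
  expect_gt(max(td$inactive_dimers), 0)
})

test_that("without extended rules GTP only flows into dimers", {
  cfg <- mt_config(n_alpha = 8, n_beta = 8, n_nucleotides = 10,
                   space_width = 0.4, space_height = 0.4,
                   iterations = 4000, trials = 1, seed = 12)
  run <- mt_run(cfg)
  td <- tidy(run)
  expect_true(all(diff(td$active_dimers) >= 0)) # non-decreasing
  expect_true(all(diff(td$free_gtp) <= 0)) # non-increasing
  expect_lte(max(td$active_dimers), 5) # floor(10 / 2)
  expect_true(all(td$free_gdp == 0))
})

test_that("ring-completion reachability tracks the chain inventory", {
  cfg <- fixture_config(mode = "ring", space_width = 10, space_height = 10)
  # a lone 9-chain with no spare dimers can never reach 12
  fx <- fixture_chain(9, cfg, start = c(5, 5))
  expect_false(ring_completion_possible(fx$w, cfg))
  # 9 + 3 can merge to exactly 12
  expect_true(ring_completion_possible(
    grow_chain_at(fx$w, cfg, 3, start = c(2, 2))$w, cfg))
  # 9 + 4 overshoots and 9 + 4 + one lone dimer still cannot make 12
  w94 <- grow_chain_at(fx$w, cfg, 4, start = c(2, 2))$w
  expect_false(ring_completion_possible(w94, cfg))
  expect_false(ring_completion_possible(
    add_active_dimer(w94, cfg, c(8, 8))$w, cfg))
  # free monomers count as potential dimers
  w_mono <- add_tubulin(add_tubulin(fx$w, "alpha", c(1, 1)),
                        "beta", c(1, 2))
  w_m3 <- w_mono
  for (k in 1:2) {
    w_m3 <- add_tubulin(w_m3, "alpha", c(1, 2 + k))
    w_m3 <- add_tubulin(w_m3, "beta", c(2, 2 + k))
  }
  expect_true(ring_completion_possible(w_m3, cfg)) # 9 + 3 potential dimers
  # a closed ring reports TRUE regardless of the rest
  fx12 <- fixture_chain(12, cfg, start = c(5, 5))
  wr <- try_bond_dimers(fx12$w, fx12$alphas[12], fx12$alphas[1], cfg)
  expect_true(ring_completion_possible(wr, cfg))
})
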