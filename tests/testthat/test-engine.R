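# Move semantics, MC step composition, dwell bookkeeping, reproducibility.

test_that("accepted separation moves change exactly one field value", {
  p <- test_params_small(6, 6, n_tcr = 0, n_lfa = 0, n_self = 0,
                         n_foreign = 0, n_icam = 0)
  sim <- simulation(p, membrane_state(matrix(25, 6, 6)), seed = 3)
  before <- get_state(sim)$l
  out <- NULL
  for (k in 1:50) {
    out <- attempt_move(sim, 1)
    if (out$accepted) break
  }
  expect_true(out$accepted)
  after <- get_state(sim)$l
  diff <- which(after != before, arr.ind = TRUE)
  expect_equal(nrow(diff), 1L)
  expect_equal(unname(diff[1, ]), unname(out$pos))
  expect_equal(after[diff] - before[diff], out$dl)
})

test_that("a free protein on an empty membrane always moves (dE = 0)", {
  p <- test_params_small(6, 6, n_tcr = 1, n_lfa = 0, n_self = 0,
                         n_foreign = 0, n_icam = 0)
  st <- membrane_state(matrix(40, 6, 6))
  st <- place_protein(st, 1, 3, 3, "TCR")
  sim <- simulation(p, st, seed = 9)
  for (k in 1:30) {
    out <- attempt_move(sim, 2)
    expect_identical(out$dE, 0)
    expect_true(out$accepted)
  }
  expect_equal(sum(get_state(sim)$occ1 != 0L), 1L)
})

test_that("a bound protein may not hop directly into a new complex", {
  # bound TCR at (1,1); membrane 2 fully covered with self-pMHC at 15 nm, so
  # every TCR hop would form a new complex at the target -> always excluded;
  # the pMHCs themselves can never move (all membrane-2 patches occupied)
  p <- model_parameters(nx = 4, ny = 4, n_tcr = 1, n_lfa = 0, n_self = 16,
                        n_foreign = 0, n_icam = 0, u_self = 5.9)
  st <- membrane_state(matrix(15, 4, 4),
                       occ2 = matrix(1L, 4, 4))
  st <- place_protein(st, 1, 1, 1, "TCR")
  sim <- simulation(p, st, seed = 4)
  expect_equal(unname(bond_counts(sim)["tcr_self"]), 1L)
  n_excl <- 0L
  for (k in 1:300) {
    out <- attempt_move(sim, 2)
    expect_false(out$accepted)
    if (out$mover_membrane == 1) {
      expect_true(out$excluded)
      n_excl <- n_excl + 1L
    } else {
      expect_false(out$excluded)  # pMHC hops fail on occupancy, not exclusion
    }
  }
  expect_gt(n_excl, 0L)
  expect_equal(unname(bond_counts(sim)["tcr_self"]), 1L)
})

test_that("an unbound protein hopping into binding position binds downhill", {
  p <- test_params_small(6, 6, n_tcr = 1, n_lfa = 0, n_self = 1,
                         n_foreign = 0, n_icam = 0)
  st <- membrane_state(matrix(15, 6, 6))
  st <- place_protein(st, 1, 3, 3, "TCR")
  st <- place_protein(st, 2, 3, 5, "SMHC")
  sim <- simulation(p, st, seed = 12)
  formed <- NULL
  for (k in 1:2000) {
    out <- attempt_move(sim, 2)
    if (!is.na(out$formed)) { formed <- out; break }
  }
  expect_false(is.null(formed))
  expect_equal(formed$formed, "tcr_self")
  expect_equal(formed$dE, -p$u_self)
  expect_true(formed$accepted)
  expect_false(formed$excluded)
})

test_that("pair moves: free diffusion in-window, +U barrier out of window", {
  p <- test_params_small(6, 6, n_tcr = 1, n_lfa = 0, n_self = 1,
                         n_foreign = 0, n_icam = 0)
  # both source and all targets inside the window: dE = 0, bond persists
  st <- membrane_state(matrix(15, 6, 6))
  st <- place_protein(st, 1, 3, 3, "TCR")
  st <- place_protein(st, 2, 3, 3, "SMHC")
  sim <- simulation(p, st, seed = 21)
  out <- attempt_move(sim, 3)
  expect_identical(out$dE, 0)
  expect_true(out$accepted)
  expect_equal(unname(bond_counts(sim)["tcr_self"]), 1L)
  expect_identical(move_counters(sim)$unbind_events[["tcr_self"]], 0)
  # every target at 25 nm: dE = +Us = 5.9, acceptance probability exp(-5.9)
  n_acc <- 0L
  for (k in 1:300) {
    l <- matrix(25, 6, 6); l[3, 3] <- 15
    st <- membrane_state(l)
    st <- place_protein(st, 1, 3, 3, "TCR")
    st <- place_protein(st, 2, 3, 3, "SMHC")
    sim <- simulation(p, st, seed = 100 + k)
    out <- attempt_move(sim, 3)
    expect_equal(out$dE, 5.9)
    n_acc <- n_acc + out$accepted
  }
  # binomial(300, exp(-5.9) = 0.0027): >= 7 acceptances is astronomically rare
  expect_lte(n_acc, 7L)
  # occupied target patches reject the pair move
  st <- membrane_state(matrix(15, 4, 4), occ2 = matrix(1L, 4, 4))
  st <- place_protein(st, 1, 2, 2, "TCR")
  p2 <- model_parameters(nx = 4, ny = 4, n_tcr = 1, n_lfa = 0, n_self = 16,
                         n_foreign = 0, n_icam = 0, u_self = 5.9)
  sim <- simulation(p2, st, seed = 5)
  for (k in 1:20) {
    out <- attempt_move(sim, 3)
    expect_false(out$accepted)
    expect_equal(out$reason, 1)  # target occupied
  }
})

test_that("one MC step performs exactly nx*ny + N + M attempts", {
  # fixture with an immutable pair count: membrane 2 fully covered, so the
  # single TCR always apposes a pMHC (M = 1) wherever it sits
  p <- model_parameters(nx = 4, ny = 4, n_tcr = 1, n_lfa = 0, n_self = 16,
                        n_foreign = 0, n_icam = 0, u_self = 5.9)
  st <- membrane_state(matrix(15, 4, 4), occ2 = matrix(1L, 4, 4))
  st <- place_protein(st, 1, 1, 1, "TCR")
  sim <- simulation(p, st, seed = 32)
  run_steps(sim, 5)
  expect_equal(unname(move_counters(sim)$attempts),
               5 * c(16, 17, 1))
  # empty membranes: only separation attempts
  pe <- test_params_small(8, 8, n_tcr = 0, n_lfa = 0, n_self = 0,
                          n_foreign = 0, n_icam = 0)
  sim <- simulation(pe, membrane_state(matrix(30, 8, 8)), seed = 1)
  run_steps(sim, 3)
  expect_equal(unname(move_counters(sim)$attempts), c(192, 0, 0))
})

test_that("dwell records pair formation with rupture inside the window", {
  recs <- data.frame(bind = c(10, 400, 900), unbind = c(250, 950, NA),
                     kind = c("tcr_self", "tcr_self", "lfa_icam"))
  dw <- build_dwell_record(recs, c(0, 1000))
  expect_equal(dw$lifetimes$tcr_self, c(240, 550))
  expect_equal(unname(dw$censored[["lfa_icam"]]), 1L)
  expect_equal(mean_dwell(dw), 395)
  # window filtering: bonds formed before the window start do not count
  dw2 <- build_dwell_record(recs, c(100, 1000))
  expect_equal(dw2$lifetimes$tcr_self, 550)
  # a bond rupturing after the window end is censored, not a lifetime
  dw3 <- build_dwell_record(recs, c(0, 800))
  expect_equal(dw3$lifetimes$tcr_self, 240)
  expect_equal(unname(dw3$censored[["tcr_self"]]), 1L)
  # counts respect unbind <= bind + initial invariant
  expect_lte(sum(dw$unbind_counts), sum(dw$bind_counts))
})

test_that("species are conserved and occupancy stays single under a storm", {
  p <- test_params_small(8, 8, u_self = 3, u_foreign = 4)
  st <- make_initial_state(p, c(13, 42), seed = 51)
  counts0 <- species_counts(st)
  sim <- simulation(p, st, seed = 52)
  run_steps(sim, 300)
  stf <- get_state(sim)
  expect_identical(species_counts(stf), counts0)
  expect_true(all(stf$occ1 %in% 0:2))
  expect_true(all(stf$occ2 %in% 0:3))
  expect_true(all(stf$l >= 0))
  # engine bond cache equals bonds() recomputed from the configuration
  bm <- synapsim:::sim_bond_map(sim$ptr)
  b <- bonds(stf, p)
  expect_equal(sum(bm >= 0), nrow(b))
  if (nrow(b) > 0) {
    kinds <- c(tcr_self = 0L, tcr_foreign = 1L, lfa_icam = 2L)
    expect_identical(bm[cbind(b$row, b$col)], unname(kinds[b$kind]))
  }
  expect_equal(unname(bond_counts(sim)),
               unname(table(factor(b$kind, c("tcr_self", "tcr_foreign",
                                             "lfa_icam")))),
               ignore_attr = TRUE)
})

test_that("identical seeds reproduce trajectories bit for bit", {
  p <- test_params_small(8, 8, n_steps = 200, equilibration = 50,
                         sampling_interval = 10)
  st <- make_initial_state(p, c(14.5, 40.5), seed = 61)
  t1 <- run_trajectory(p, st, seed = 62)
  t2 <- run_trajectory(p, st, seed = 62)
  expect_identical(t1$series, t2$series)
  expect_identical(t1$bond_records, t2$bond_records)
  expect_identical(t1$final_state, t2$final_state)
  t3 <- run_trajectory(p, st, seed = 63)
  expect_false(identical(t1$series, t3$series))
})

test_that("trajectories reject states inconsistent with the parameters", {
  p <- test_params_small(8, 8)
  st <- make_initial_state(p, c(14.5, 40.5), seed = 1)
  p$n_tcr <- 5L
  expect_error(simulation(p, st), "disagree")
})
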