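# R bindings over the compiled Metropolis engine.

.sim_par <- function(p) {
  list(patch_size = p$patch_size, kappa = p$kappa,
       tcr_rest = p$tcr_rest, tcr_halfwidth = p$tcr_halfwidth,
       lfa_rest = p$lfa_rest, lfa_halfwidth = p$lfa_halfwidth,
       u_self = p$u_self, u_foreign = p$u_foreign, u_li = p$u_li,
       sep_halfwidth = p$sep_halfwidth,
       contact_threshold = p$contact_threshold)
}

#' Create a Monte Carlo simulation from a parameter set and a state
#'
#' Builds the compiled engine holding the separation field, the protein
#' placements, the derived bond bookkeeping and a seeded deterministic
#' random-number stream. The engine is mutated in place by [run_steps()] and
#' [attempt_move()].
#'
#' @param p An `adhesion_params` object.
#' @param state A `membrane_state`; defaults to a random initial state on
#'   the interval `c(14.5, 40.5)` drawn with seed `p$seed`.
#' @param seed Integer seed of the engine's move stream (default `p$seed`).
#' @return An object of class `adhesion_sim`.
#' @export
simulation <- function(p, state = NULL, seed = p$seed) {
  validate_parameters(p)
  if (is.null(state))
    state <- make_initial_state(p, c(14.5, 40.5), seed = seed)
  validate_state(state)
  if (!all(dim(state$l) == c(p$nx, p$ny)))
    stop("state dimensions do not match the parameters")
  cnt <- species_counts(state)
  want <- c(TCR = p$n_tcr, LFA1 = p$n_lfa, SMHC = p$n_self,
            FMHC = p$n_foreign, ICAM1 = p$n_icam)
  if (!all(cnt == want))
    stop("species counts in the state disagree with the parameters (",
         paste(names(cnt), cnt, sep = "=", collapse = " "), " vs ",
         paste(names(want), want, sep = "=", collapse = " "), ")")
  ptr <- sim_create(state$l, state$occ1, state$occ2, .sim_par(p),
                    as.numeric(seed), state$step)
  structure(list(ptr = ptr, params = p, seed = seed),
            class = "adhesion_sim")
}

#' @export
print.adhesion_sim <- function(x, ...) {
  cnt <- sim_counters(x$ptr)
  nb <- sim_bond_counts(x$ptr)
  cat(sprintf("Adhesion simulation: %d x %d lattice, step %g t0, seed %d\n",
              x$params$nx, x$params$ny, cnt$step, x$seed))
  cat(sprintf("  bonds: %d TCR/self + %d TCR/foreign + %d LFA-1/ICAM-1; %d apposing pairs\n",
              nb[1], nb[2], nb[3], cnt$n_pairs))
  invisible(x)
}

#' Advance a simulation and record sampled conformations
#'
#' Runs full MC steps (each `nx*ny` separation attempts, `N` protein
#' attempts, `M` pair attempts with `M` frozen at the pair-substep start) and
#' records one observable row whenever the step counter is a multiple of
#' `sample_every`.
#'
#' @param sim An `adhesion_sim`.
#' @param n_steps Number of MC steps to run.
#' @param sample_every Sampling interval in steps; `0` disables sampling.
#' @return Data frame of sampled conformations (an event-series fragment):
#'   `step`, bond counts per kind, close-contact and binding-window patch
#'   counts, minimum separation, and the energy breakdown.
#' @export
run_steps <- function(sim, n_steps, sample_every = 0) {
  m <- sim_run(sim$ptr, n_steps, sample_every)
  as_event_series(m, sim$params)
}

as_event_series <- function(m, p) {
  df <- as.data.frame(m)
  names(df) <- c("step", "n_tcr_self", "n_tcr_foreign", "n_lfa_icam",
                 "n_contact", "n_window", "min_separation",
                 "e_bend", "e_bind")
  attr(df, "sampling_interval") <- if (nrow(df) > 1)
    df$step[2] - df$step[1] else p$sampling_interval
  attr(df, "params") <- p
  class(df) <- c("event_series", class(df))
  df
}

#' Attempt a single elementary move
#'
#' Executes one attempted move of the given type with the engine's random
#' stream and returns its outcome record. Used by the test suite to probe
#' move-level behaviour; [run_steps()] is the production path.
#'
#' @param sim An `adhesion_sim`.
#' @param type 1 (separation shift), 2 (protein hop) or 3 (pair hop).
#' @return A list: `type`, `pos` and `target` (1-based `c(row, col)`),
#'   `dE` (kBT), `dl`, `accepted`, `excluded` (bound-hop exclusion),
#'   `reason`, mover identity, and the kinds of any bond `formed`/`broken`
#'   (`NA` if none).
#' @export
attempt_move <- function(sim, type) {
  o <- sim_attempt(sim$ptr, as.integer(type))
  o$formed <- if (o$formed < 0) NA_character_ else .kind_names[o$formed + 1L]
  o$broken <- if (o$broken < 0) NA_character_ else .kind_names[o$broken + 1L]
  o
}

#' Extract the current membrane state of a simulation
#'
#' @param sim An `adhesion_sim`.
#' @return A `membrane_state`.
#' @export
get_state <- function(sim) {
  s <- sim_state(sim$ptr)
  membrane_state(s$l, s$occ1, s$occ2, step = s$step)
}

#' Move and event counters of a simulation
#'
#' @param sim An `adhesion_sim`.
#' @return List of per-move-type attempt/accept counts, the excluded-move
#'   count, binding/unbinding event counts per complex kind, and the current
#'   pair and protein numbers.
#' @export
move_counters <- function(sim) {
  cnt <- sim_counters(sim$ptr)
  names(cnt$attempts) <- names(cnt$accepts) <- c("separation", "protein", "pair")
  names(cnt$bind_events) <- names(cnt$unbind_events) <- .kind_names
  cnt
}

#' Current bond counts per complex kind
#'
#' @param sim An `adhesion_sim`.
#' @return Named integer vector over `tcr_self`, `tcr_foreign`, `lfa_icam`.
#' @export
bond_counts <- function(sim) {
  stats::setNames(sim_bond_counts(sim$ptr), .kind_names)
}

#' Engine energy breakdown
#'
#' @param sim An `adhesion_sim`.
#' @return List with `e_bend`, `e_bind`, `e_total` in kBT.
#' @export
engine_energy <- function(sim) {
  sim_energy(sim$ptr)
}

#' Bond history of a simulation
#'
#' Every completed bond (formation and rupture step in t0) recorded since
#' construction, plus right-censored rows (`unbind = NA`) for bonds still
#' alive.
#'
#' @param sim An `adhesion_sim`.
#' @return Data frame with columns `bind`, `unbind`, `kind`.
#' @export
bond_records <- function(sim) {
  r <- sim_bond_records(sim$ptr)
  data.frame(bind = r$bind, unbind = r$unbind,
             kind = .kind_names[r$kind + 1L], stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------

#' Assemble a dwell-time record from bond history
#'
#' Filters bond records to a measurement window and collects per-kind bond
#' lifetimes (rupture step minus formation step, in t0). Only bonds formed
#' at or after the window start contribute; bonds still alive (or rupturing
#' after the window end) are counted as right-censored and excluded from the
#' lifetime lists. Lifetimes are recorded at MC-step resolution, so a bond
#' that forms and ruptures within the same step has lifetime 0.
#'
#' @param records Data frame from [bond_records()] (columns `bind`,
#'   `unbind`, `kind`).
#' @param window Length-2 numeric measurement window in t0.
#' @return An object of class `dwell_record`: per-kind lifetime vectors,
#'   binding/unbinding event counts in the window, censored counts, and the
#'   window.
#' @export
build_dwell_record <- function(records, window) {
  stopifnot(length(window) == 2L, window[2] >= window[1])
  inw <- records$bind >= window[1] & records$bind <= window[2]
  rec <- records[inw, , drop = FALSE]
  complete <- !is.na(rec$unbind) & rec$unbind <= window[2]
  lt <- rec$unbind - rec$bind
  lifetimes <- lapply(.kind_names, function(k) lt[complete & rec$kind == k])
  names(lifetimes) <- .kind_names
  censored <- vapply(.kind_names, function(k) sum(!complete & rec$kind == k),
                     integer(1))
  bind_counts <- vapply(.kind_names, function(k) sum(rec$kind == k),
                        integer(1))
  unbind_counts <- vapply(.kind_names, function(k)
    sum(complete & rec$kind == k), integer(1))
  structure(list(lifetimes = lifetimes, bind_counts = bind_counts,
                 unbind_counts = unbind_counts, censored = censored,
                 window = window),
            class = "dwell_record")
}

#' @export
print.dwell_record <- function(x, ...) {
  cat(sprintf("Dwell record, window [%g, %g] t0\n",
              x$window[1], x$window[2]))
  for (k in names(x$lifetimes)) {
    n <- length(x$lifetimes[[k]])
    cat(sprintf("  %-12s %5d lifetimes%s, %d censored\n", k, n,
                if (n) sprintf(" (mean %.1f t0)", mean(x$lifetimes[[k]]))
                else "", x$censored[[k]]))
  }
  invisible(x)
}

#' Mean bond dwell time
#'
#' @param dwell A `dwell_record`.
#' @param kinds Complex kinds to pool (default: both TCR/pMHC kinds).
#' @return Mean lifetime in t0 (`NaN` if no complete lifetimes).
#' @export
mean_dwell <- function(dwell, kinds = c("tcr_self", "tcr_foreign")) {
  mean(unlist(dwell$lifetimes[kinds], use.names = FALSE))
}

# ---------------------------------------------------------------------------

#' Run a full Monte Carlo trajectory
#'
#' Runs `n_steps` MC steps from an initial state, sampling one conformation
#' row every `sampling_interval` steps, and assembles the dwell-time record
#' over the measurement window (by default the second half of the
#' trajectory, matching how complex lifetimes are measured in the study
#' protocol). Equilibrium observables should be computed after discarding
#' the equilibration part with [discard_equilibration()]. Identical seed,
#' parameters and initial state give bit-identical output.
#'
#' @param p An `adhesion_params` object.
#' @param initial A `membrane_state`; defaults to a random state on
#'   `c(14.5, 40.5)` drawn with seed `seed`.
#' @param seed Engine seed (default `p$seed`).
#' @param n_steps,sampling_interval Override the schedule in `p`.
#' @param dwell_window Measurement window for dwell statistics in t0
#'   (default second half: `c(n_steps / 2, n_steps)`).
#' @return List of class `adhesion_trajectory`: `series` (the sampled
#'   event series), `dwell` (a `dwell_record`), `bond_records`, `counters`,
#'   `final_state`, `params`.
#' @export
run_trajectory <- function(p, initial = NULL, seed = p$seed,
                           n_steps = p$n_steps,
                           sampling_interval = p$sampling_interval,
                           dwell_window = NULL) {
  sim <- simulation(p, state = initial, seed = seed)
  series <- run_steps(sim, n_steps, sampling_interval)
  start <- get_state(sim)$step - n_steps
  if (is.null(dwell_window))
    dwell_window <- c(start + n_steps / 2, start + n_steps)
  recs <- bond_records(sim)
  structure(list(series = series,
                 dwell = build_dwell_record(recs, dwell_window),
                 bond_records = recs,
                 counters = move_counters(sim),
                 final_state = get_state(sim),
                 params = p),
            class = "adhesion_trajectory")
}

#' @export
print.adhesion_trajectory <- function(x, ...) {
  cat(sprintf("Adhesion trajectory: %d sampled conformations on a %d x %d lattice\n",
              nrow(x$series), x$params$nx, x$params$ny))
  print(x$dwell)
  invisible(x)
}

#' Measure TCR/pMHC bond dwell times for one apposing pair
#'
#' Places a single TCR and a single peptide-MHC two patches apart on a flat
#' membrane at the TCR/pMHC rest length and runs the full move schedule.
#' Bonds form by diffusion, and lifetimes (formation to rupture, t0) are
#' collected until `target_events` ruptures have been recorded. The run is
#' split into fresh episodes of `episode_steps` MC steps with child seeds:
#' without the LFA-1/ICAM-1 complexes that anchor the membrane in the full
#' adhesion scenarios, a free membrane slowly diffuses away from the binding
#' window during long unbound stretches, and restarting the (memoryless)
#' waiting process keeps the membrane flat-ish near 15 nm without touching
#' the bound-state kinetics that the lifetimes measure. The mean lifetimes
#' of this setup probe the model's exponential lifetime law: they grow as
#' `exp(U)` with the binding energy `U`.
#'
#' @param u Binding energy of the complex in kBT.
#' @param nx,ny Lattice size (default 20 x 20).
#' @param target_events Number of rupture events to collect (default 200).
#' @param episode_steps Length of one episode in t0 (default 2e4, two
#'   orders of magnitude above the longest mean lifetimes probed).
#' @param max_episodes Hard cap on the number of episodes.
#' @param seed Master seed; episode seeds are derived with [child_seed()].
#' @param foreign Use a foreign-pMHC (`TRUE`) or self-pMHC partner; only the
#'   label differs, the dynamics depend on `u` alone.
#' @return List: `lifetimes` (t0), `mean_lifetime`, `n_events`, `steps` run
#'   in total.
#' @export
dwell_time_experiment <- function(u, nx = 20L, ny = 20L,
                                  target_events = 200L,
                                  episode_steps = 2e4, max_episodes = 500L,
                                  seed = 1L, foreign = FALSE) {
  p <- model_parameters(nx = nx, ny = ny,
                        u_self = if (foreign) 4 else u,
                        u_foreign = if (foreign) u else 12,
                        n_tcr = 1L, n_lfa = 0L,
                        n_self = if (foreign) 0L else 1L,
                        n_foreign = if (foreign) 1L else 0L,
                        n_icam = 0L,
                        n_steps = episode_steps, equilibration = 0,
                        sampling_interval = episode_steps, seed = seed)
  ctr <- c(floor(nx / 2) + 1L, floor(ny / 2) + 1L)
  st <- membrane_state(matrix(p$tcr_rest, nx, ny))
  st <- place_protein(st, 1, ctr[1], ctr[2], "TCR")
  st <- place_protein(st, 2, ctr[1], (ctr[2] + 2L - 1L) %% ny + 1L,
                      if (foreign) "FMHC" else "SMHC")
  lifetimes <- numeric(0)
  steps <- 0
  for (ep in seq_len(max_episodes)) {
    sim <- simulation(p, state = st, seed = child_seed(seed, ep))
    steps <- steps + sim_run_until_unbind(
      sim$ptr, episode_steps, target_events - length(lifetimes))
    dw <- build_dwell_record(bond_records(sim), c(0, episode_steps))
    lifetimes <- c(lifetimes,
                   unlist(dw$lifetimes[c("tcr_self", "tcr_foreign")],
                          use.names = FALSE))
    if (length(lifetimes) >= target_events) break
  }
  list(lifetimes = lifetimes, mean_lifetime = mean(lifetimes),
       n_events = length(lifetimes), steps = steps)
}
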