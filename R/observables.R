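# Equilibrium observables: close-contact event segmentation, zone
# probability/lifetime/area, complex concentrations, the dwell-time
# regression, and the analytic companions (segregation threshold, K2D).

#' Drop the equilibration part of an event series
#'
#' @param series An event series (from [run_steps()] or
#'   `run_trajectory()$series`).
#' @param equilibration Steps to discard (default: the `equilibration`
#'   entry of the series' parameters).
#' @return The series restricted to `step > equilibration`.
#' @export
discard_equilibration <- function(series, equilibration = NULL) {
  if (is.null(equilibration))
    equilibration <- attr(series, "params")$equilibration
  out <- series[series$step > equilibration, , drop = FALSE]
  attributes(out)[c("sampling_interval", "params")] <-
    attributes(series)[c("sampling_interval", "params")]
  class(out) <- class(series)
  out
}

.series_interval <- function(series, p = NULL) {
  iv <- attr(series, "sampling_interval")
  if (!is.null(iv)) return(iv)
  if (nrow(series) > 1) return(series$step[2] - series$step[1])
  if (!is.null(p)) p$sampling_interval else stop("unknown sampling interval")
}

#' Segment close-contact events from an event series
#'
#' A close-contact event is a maximal contiguous run of sampled
#' conformations that each contain at least one apposing patch pair with
#' separation below the contact threshold (20 nm by default). An event
#' qualifies as a close-contact-zone event if at least one conformation in
#' the run contains at least one TCR/peptide-MHC complex; this tolerates the
#' complex count of a small zone briefly dropping to zero through binding
#' fluctuations.
#'
#' @param series An event series sampled at a constant interval.
#' @param p An `adhesion_params` object (used for the sampling interval if
#'   the series carries none).
#' @return Data frame of events: sample indices `start`/`end`, `n_samples`,
#'   `duration` in t0, `qualifying`, and boundary-censoring flags
#'   `censored_start`/`censored_end`.
#' @export
segment_contact_events <- function(series, p = NULL) {
  if (nrow(series) == 0L) stop("empty event series")
  interval <- .series_interval(series, p)
  contact <- series$n_contact >= 1
  tcr <- (series$n_tcr_self + series$n_tcr_foreign) >= 1
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  qual <- mapply(function(s, e) any(tcr[s:e]), starts, ends)
  data.frame(start = starts, end = ends,
             n_samples = ends - starts + 1L,
             duration = (ends - starts + 1L) * interval,
             qualifying = as.logical(qual),
             censored_start = starts == 1L,
             censored_end = ends == nrow(series))
}

#' Probability of close-contact zones
#'
#' The fraction of sampled conformations that are part of qualifying
#' close-contact events.
#'
#' @param series The event series the events were segmented from.
#' @param events Data frame from [segment_contact_events()].
#' @return Probability in `[0, 1]`.
#' @export
zone_probability <- function(series, events) {
  q <- events[events$qualifying, , drop = FALSE]
  sum(q$n_samples) / nrow(series)
}

#' Mean lifetime of close-contact zones
#'
#' Unweighted mean duration of the qualifying events. A single event
#' spanning the whole equilibrated window of length To reports lifetime To.
#' Boundary-censored events (touching the window edges) are included by
#' default, since a continuously present zone is reported with lifetime To
#' in exactly this way.
#'
#' @param events Data frame from [segment_contact_events()].
#' @param To Length of the equilibrated measurement window in t0 (for the
#'   `fraction` entry).
#' @param include_censored Include boundary-censored events in the mean.
#' @return List: `lifetime` (t0), `fraction` (of To), `n_events`, `empty`
#'   flag. No events gives lifetime 0 with `empty = TRUE`.
#' @export
zone_lifetime <- function(events, To = NULL, include_censored = TRUE) {
  q <- events[events$qualifying, , drop = FALSE]
  if (!include_censored)
    q <- q[!(q$censored_start | q$censored_end), , drop = FALSE]
  if (nrow(q) == 0L)
    return(list(lifetime = 0, fraction = if (is.null(To)) NA_real_ else 0,
                n_events = 0L, empty = TRUE))
  lt <- mean(q$duration)
  list(lifetime = lt,
       fraction = if (is.null(To)) NA_real_ else lt / To,
       n_events = nrow(q), empty = FALSE)
}

#' Mean area of close-contact zones
#'
#' Mean, over conformations inside qualifying events, of the number of
#' apposing patch pairs with separation below the contact threshold times
#' the patch area. All sub-threshold patch pairs are counted (no
#' connected-component labelling).
#'
#' @param series The event series.
#' @param events Data frame from [segment_contact_events()].
#' @param p An `adhesion_params` object (patch size).
#' @param units `"nm2"` or `"um2"`.
#' @return Mean zone area; 0 if there are no qualifying events.
#' @export
zone_area <- function(series, events, p, units = c("nm2", "um2")) {
  units <- match.arg(units)
  q <- events[events$qualifying, , drop = FALSE]
  if (nrow(q) == 0L) return(0)
  idx <- unlist(mapply(seq, q$start, q$end, SIMPLIFY = FALSE))
  area <- mean(series$n_contact[idx]) * p$patch_size^2
  if (units == "um2") area * 1e-6 else area
}

#' Equilibrium complex concentration
#'
#' Mean bond count of one complex kind over the series, divided by the
#' projected membrane area.
#'
#' @param series An (equilibrated) event series.
#' @param kind `"tcr_self"`, `"tcr_foreign"`, `"lfa_icam"`, or `"tcr"` for
#'   both TCR/pMHC kinds pooled.
#' @param p An `adhesion_params` object.
#' @return Concentration in complexes per square micron.
#' @export
complex_concentration <- function(series, kind, p) {
  n <- switch(kind,
              tcr_self = series$n_tcr_self,
              tcr_foreign = series$n_tcr_foreign,
              lfa_icam = series$n_lfa_icam,
              tcr = series$n_tcr_self + series$n_tcr_foreign,
              stop("unknown complex kind"))
  mean(n) / membrane_area(p, "um2")
}

#' Fit the dwell-time regression constant
#'
#' Least-squares fit of `log(tau) = c + U` with the slope fixed at 1, i.e.
#' the single-parameter regression of log mean bond lifetime (t0) on binding
#' energy (kBT). The solution is the mean residual `mean(log(tau) - U)`.
#'
#' @param u Binding energies in kBT.
#' @param tau Mean dwell times in t0 (positive).
#' @return List: `c_reg`, `stderr` (NA for a single point), `n`.
#' @export
fit_lifetime_prefactor <- function(u, tau) {
  stopifnot(length(u) == length(tau), length(u) >= 1)
  if (any(tau <= 0)) stop("dwell times must be positive")
  res <- log(tau) - u
  list(c_reg = mean(res),
       stderr = if (length(res) > 1) stats::sd(res) / sqrt(length(res))
                else NA_real_,
       n = length(res))
}

#' Critical concentration for curvature-mediated segregation
#'
#' Long and short complexes segregate when the concentration of the long
#' complexes exceeds `c * kBT / (kappa * dl^2)`, with `dl` the rest-length
#' mismatch and `c` a numerical prefactor of 0.65 +/- 0.15. At the model's
#' `kappa = 20 kBT` and `dl = 25 nm` this threshold is about 50 complexes
#' per square micron.
#'
#' @param kappa Effective bending rigidity in kBT.
#' @param delta_l Rest-length mismatch in nm.
#' @param prefactor Dimensionless prefactor (default 0.65).
#' @return Threshold concentration in complexes per square micron.
#' @export
segregation_threshold <- function(kappa, delta_l, prefactor = 0.65) {
  stopifnot(kappa > 0, delta_l > 0, prefactor > 0)
  prefactor / (kappa * delta_l^2) * 1e6
}

#' Two-dimensional binding constant from a separation distribution
#'
#' `K2D = integral of k2D(l) P(l) dl`, where the local binding constant
#' `k2D(l)` equals `a^2 * exp(U)` for separations inside the TCR/pMHC
#' binding window and 0 outside. For a discrete separation histogram this is
#' (probability mass inside the window) `* a^2 * exp(U)`.
#'
#' @param P Separation histogram: data frame with columns `l` (bin
#'   midpoints, nm) and `p` (probabilities summing to 1).
#' @param u Binding energy in kBT.
#' @param p An `adhesion_params` object (patch size and binding window).
#' @return K2D in square microns.
#' @export
binding_constant_2d <- function(P, u, p) {
  stopifnot(is.data.frame(P), all(c("l", "p") %in% names(P)))
  if (abs(sum(P$p) - 1) > 1e-6) stop("separation histogram is not normalized")
  lo <- p$tcr_rest - p$tcr_halfwidth
  hi <- p$tcr_rest + p$tcr_halfwidth
  mass <- sum(P$p[P$l >= lo & P$l <= hi])
  mass * p$patch_size^2 * exp(u) * 1e-6
}

#' Fraction of patch pairs inside the TCR/pMHC binding window
#'
#' Averaged over conformations inside qualifying close-contact events. With
#' `within_zone = TRUE` (default) the fraction is taken over the patch pairs
#' of the close-contact zone (separation below the contact threshold),
#' matching the statement that in large close-contact zones about 20% of the
#' membrane patches lie within the binding range; with `within_zone = FALSE`
#' it is taken over all patch pairs.
#'
#' @param series The event series.
#' @param events Data frame from [segment_contact_events()].
#' @param p An `adhesion_params` object.
#' @param within_zone Restrict the denominator to sub-threshold patch pairs.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
binding_window_fraction <- function(series, events, p,
                                    within_zone = TRUE) {
  q <- events[events$qualifying, , drop = FALSE]
  if (nrow(q) == 0L) stop("no close-contact samples in the series")
  idx <- unlist(mapply(seq, q$start, q$end, SIMPLIFY = FALSE))
  if (within_zone) {
    idx <- idx[series$n_contact[idx] > 0]
    mean(series$n_window[idx] / series$n_contact[idx])
  } else {
    mean(series$n_window[idx] / (p$nx * p$ny))
  }
}

#' Separation histogram of a membrane state
#'
#' @param s A `membrane_state`.
#' @param breaks Bin breaks in nm; default 0.25 nm bins spanning the field.
#' @return Data frame with bin midpoints `l` and probabilities `p`.
#' @export
separation_histogram <- function(s, breaks = NULL) {
  x <- as.vector(s$l)
  if (is.null(breaks))
    breaks <- seq(floor(min(x)), ceiling(max(x)) + 0.25, by = 0.25)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  data.frame(l = (breaks[-length(breaks)] + breaks[-1]) / 2,
             p = counts / length(x))
}

#' Summarize an equilibrated trajectory
#'
#' One-row summary of the standard observables: zone probability, lifetime
#' (t0 and fraction of the equilibrated window To), area, complex
#' concentrations, and dwell statistics when present.
#'
#' @param traj An `adhesion_trajectory` from [run_trajectory()].
#' @return One-row data frame.
#' @export
summarize_run <- function(traj) {
  p <- traj$params
  ser <- discard_equilibration(traj$series)
  To <- nrow(ser) * .series_interval(ser, p)
  ev <- segment_contact_events(ser, p)
  lt <- zone_lifetime(ev, To)
  tau <- mean_dwell(traj$dwell)
  data.frame(
    u_self = p$u_self, u_foreign = p$u_foreign,
    n_tcr_pmhc = mean(ser$n_tcr_self + ser$n_tcr_foreign),
    zone_probability = zone_probability(ser, ev),
    zone_lifetime_t0 = lt$lifetime,
    zone_lifetime_To = lt$fraction,
    zone_area_um2 = zone_area(ser, ev, p, "um2"),
    conc_tcr_um2 = complex_concentration(ser, "tcr", p),
    conc_li_um2 = complex_concentration(ser, "lfa_icam", p),
    mean_dwell_t0 = tau,
    n_dwell_events = sum(traj$dwell$unbind_counts[c("tcr_self",
                                                    "tcr_foreign")]))
}
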