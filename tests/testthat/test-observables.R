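# Event segmentation, zone statistics, regression and analytic formulas.

make_series <- function(n_contact, n_tcr, interval = 2e5) {
  df <- data.frame(step = seq_along(n_contact) * interval,
                   n_tcr_self = n_tcr, n_tcr_foreign = 0L,
                   n_lfa_icam = 0L, n_contact = n_contact,
                   n_window = 0L, min_separation = 15,
                   e_bend = 0, e_bind = 0)
  attr(df, "sampling_interval") <- interval
  df
}

test_that("contact events are maximal runs qualified by any TCR bond", {
  # all samples in contact, bonds throughout: one event, probability 1
  ser <- make_series(rep(5L, 8), rep(2L, 8))
  ev <- segment_contact_events(ser)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$qualifying)
  expect_equal(zone_probability(ser, ev), 1)
  # no contact samples: no events
  ser <- make_series(rep(0L, 8), rep(0L, 8))
  expect_equal(nrow(segment_contact_events(ser)), 0L)
  # a 5-sample contact run with a bond only in its third sample qualifies
  # as a whole; a bond-free run does not
  ser <- make_series(c(0L, 1L, 3L, 2L, 1L, 1L, 0L, 2L, 1L, 0L),
                     c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  ev <- segment_contact_events(ser)
  expect_equal(ev$start, c(2L, 8L))
  expect_equal(ev$end, c(6L, 9L))
  expect_equal(ev$qualifying, c(TRUE, FALSE))
  expect_equal(ev$n_samples, c(5L, 2L))
  expect_equal(zone_probability(ser, ev), 0.5)
  expect_error(segment_contact_events(ser[0, ]), "empty")
})

test_that("segmentation agrees with the brute-force oracle on random series", {
  set.seed(77)
  for (k in 1:40) {
    n <- sample(5:60, 1)
    contact <- runif(n) < runif(1, 0.2, 0.8)
    tcr <- contact & (runif(n) < 0.3)
    ser <- make_series(as.integer(contact) * sample(1:9, n, TRUE),
                       as.integer(tcr))
    ev <- segment_contact_events(ser)
    or <- oracle_segment(contact, tcr)
    expect_equal(ev$start, or$start)
    expect_equal(ev$end, or$end)
    expect_equal(ev$qualifying, or$qualifying)
    # conservation: probability * samples = sum of qualifying event samples
    expect_equal(zone_probability(ser, ev) * n,
                 sum(ev$n_samples[ev$qualifying]))
  }
})

test_that("zone lifetime reports To for a full-window event and means else", {
  interval <- 2e5
  To <- 800 * interval
  ser <- make_series(rep(1L, 800), rep(1L, 800), interval)
  lt <- zone_lifetime(segment_contact_events(ser), To)
  expect_equal(lt$lifetime, To)
  expect_equal(lt$fraction, 1)
  # two events of 10 and 30 samples: mean 20 * 2e5 = 4e6 t0
  contact <- c(rep(1L, 10), 0L, rep(1L, 30), 0L)
  tcr <- as.integer(contact > 0)
  lt <- zone_lifetime(segment_contact_events(make_series(contact, tcr)))
  expect_equal(lt$lifetime, 4e6)
  expect_equal(lt$n_events, 2L)
  # no events
  lt <- zone_lifetime(segment_contact_events(make_series(rep(0L, 5),
                                                         rep(0L, 5))))
  expect_true(lt$empty)
  expect_equal(lt$lifetime, 0)
})

test_that("zone area counts sub-threshold patch pairs times patch area", {
  p <- model_parameters()  # 100x100, a = 15 nm
  # flat field at 15 nm: all 10^4 pairs in contact, full membrane 2.25 um^2
  ser <- make_series(rep(10000L, 4), rep(1L, 4))
  ev <- segment_contact_events(ser)
  expect_equal(zone_area(ser, ev, p, "um2"), 2.25)
  # flat at 40 nm: no contact, area 0
  ser0 <- make_series(rep(0L, 4), rep(0L, 4))
  expect_equal(zone_area(ser0, segment_contact_events(ser0), p), 0)
  # 37 sub-threshold pairs -> 37 * 225 nm^2
  ser37 <- make_series(rep(37L, 4), rep(1L, 4))
  expect_equal(zone_area(ser37, segment_contact_events(ser37), p), 37 * 225)
})

test_that("complex concentrations divide mean bond counts by area", {
  p <- model_parameters()
  ser <- make_series(rep(1L, 4), rep(0L, 4))
  ser$n_lfa_icam <- rep(225L, 4)
  expect_equal(complex_concentration(ser, "lfa_icam", p), 100)
  ser$n_lfa_icam <- 0L
  expect_equal(complex_concentration(ser, "lfa_icam", p), 0)
  # scaled 30x30 lattice: 20.25 mean bonds on 0.2025 um^2 is again 100/um^2
  p30 <- model_parameters(nx = 30, ny = 30, n_tcr = 24, n_lfa = 24,
                          n_self = 24, n_foreign = 0, n_icam = 24)
  ser$n_lfa_icam <- rep(c(20L, 20.5), 2)
  expect_equal(complex_concentration(ser, "lfa_icam", p30),
               20.25 / 0.2025)
})

test_that("lifetime regression with unit slope recovers the constant", {
  u <- c(4, 5, 6, 7)
  fit <- fit_lifetime_prefactor(u, exp(-0.9 + u))
  expect_equal(fit$c_reg, -0.9)
  expect_equal(fit$stderr, 0)
  # single point: slope fixed, c identified
  fit1 <- fit_lifetime_prefactor(5, exp(4.1))
  expect_equal(fit1$c_reg, -0.9)
  expect_true(is.na(fit1$stderr))
  expect_error(fit_lifetime_prefactor(c(4, 5), c(10, -1)), "positive")
  # multiplicative noise: truth within ~3 standard errors
  set.seed(123)
  u <- rep(4:8, each = 6)
  tau <- exp(-0.945 + u + rnorm(length(u), 0, 0.2))
  fit <- fit_lifetime_prefactor(u, tau)
  expect_lt(abs(fit$c_reg + 0.945), 4 * fit$stderr)
})

test_that("segregation threshold follows c kBT / (kappa dl^2)", {
  # kappa = 20 kBT, dl = 25 nm, c = 0.65: 52 complexes/um^2 (about 50)
  expect_equal(segregation_threshold(20, 25, 0.65), 52)
  expect_equal(segregation_threshold(20, 25, 0.5), 40)
  expect_equal(segregation_threshold(20, 50, 0.65),
               segregation_threshold(20, 25, 0.65) / 4)
  expect_error(segregation_threshold(-1, 25), "kappa")
})

test_that("K2D integrates the local binding constant over P(l)", {
  p <- model_parameters()
  # all probability mass inside the window, U = 0: a^2 = 225 nm^2
  P <- data.frame(l = c(14.8, 15.2), p = c(0.5, 0.5))
  expect_equal(binding_constant_2d(P, 0, p), 225e-6)
  # 20% mass in-window at U = 12.5: about 12 um^2
  P <- data.frame(l = c(15, 30), p = c(0.2, 0.8))
  expect_equal(binding_constant_2d(P, 12.5, p),
               0.2 * 225 * exp(12.5) * 1e-6, tolerance = 1e-12)
  expect_gt(binding_constant_2d(P, 12.5, p), 10)
  expect_lt(binding_constant_2d(P, 12.5, p), 13)
  # no mass in-window (LFA-1/ICAM-1 domains): K2D = 0
  P <- data.frame(l = c(39.5, 40.5), p = c(0.5, 0.5))
  expect_equal(binding_constant_2d(P, 12.5, p), 0)
  expect_error(binding_constant_2d(data.frame(l = 15, p = 0.7), 5, p),
               "normalized")
})

test_that("binding-window fraction averages over in-event conformations", {
  p <- model_parameters(nx = 10, ny = 10, n_tcr = 1, n_lfa = 0, n_self = 1,
                        n_foreign = 0, n_icam = 0)
  ser <- make_series(rep(100L, 4), rep(1L, 4))
  ser$n_window <- rep(100L, 4)     # flat field at exactly 15 nm
  ev <- segment_contact_events(ser)
  expect_equal(binding_window_fraction(ser, ev, p), 1)
  expect_equal(binding_window_fraction(ser, ev, p, within_zone = FALSE), 1)
  ser$n_window <- rep(0L, 4)       # flat field at 19 nm: contact, no binding
  expect_equal(binding_window_fraction(ser, ev, p), 0)
  ser$n_window <- rep(20L, 4)      # 20 of 100 patches inside the window
  expect_equal(binding_window_fraction(ser, ev, p, within_zone = FALSE), 0.2)
  ser0 <- make_series(rep(0L, 4), rep(0L, 4))
  expect_error(binding_window_fraction(ser0, segment_contact_events(ser0), p),
               "no close-contact")
})

test_that("separation histograms are normalized and locate the field", {
  st <- membrane_state(matrix(c(rep(15, 20), rep(40, 80)), 10, 10))
  h <- separation_histogram(st)
  expect_equal(sum(h$p), 1)
  expect_equal(sum(h$p[h$l > 14 & h$l < 16]), 0.2)
  expect_equal(sum(h$p[h$l > 39 & h$l < 41]), 0.8)
})
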