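test_that("forward model handles trivial and closed-form cases", {
  tt <- seq(0, 120, by = 2)
  io <- test_outer(tt)
  expect_equal(forward_model(0, 0.05, io)$values, rep(0, length(tt)))
  silent <- time_signal_curve(tt, rep(0, length(tt)))
  expect_equal(forward_model(0.1, 0.05, silent)$values, rep(0, length(tt)))
  # sampled step input: exact against (k1/k2)(1 - e^{-k2 t}) at every sample
  step <- time_signal_curve(tt, rep(1, length(tt)))
  got <- forward_model(0.1, 0.05, step)$values
  expect_equal(got, (0.1 / 0.05) * (1 - exp(-0.05 * tt)), tolerance = 1e-12)
  expect_equal(got[tt == 60], 1.900426, tolerance = 1e-6)
  # k2 = 0 reduces to a plain running integral
  ramp <- time_signal_curve(tt, tt)
  expect_equal(forward_model(0.1, 0, ramp)$values, 0.1 * tt^2 / 2,
               tolerance = 1e-10)
})

test_that("forward model agrees with RK4 integration of the ODE", {
  set.seed(41)
  tt <- seq(0, 360, by = 9)
  io <- test_outer(tt)
  for (i in 1:5) {
    k1 <- runif(1, 0.005, 0.1); k2 <- runif(1, 0.005, 0.1)
    conv <- forward_model(k1, k2, io)$values
    ode <- generate_inner_from_outer(io, k1, k2, refine = 10)$values
    expect_lt(l2norm(conv - ode) / l2norm(ode), 1e-6)
  }
})

test_that("rates are recovered exactly on noise-free pairs", {
  tt <- test_grid()
  io <- test_outer(tt)
  for (k in list(c(0.005, 0.005), c(0.02, 0.012), c(0.1, 0.05),
                 c(0.01, 0.1))) {
    pair <- curve_pair(io, forward_model(k[1], k[2], io))
    fit <- fit_exchange_rates(pair)
    expect_lt(abs(fit$k1 - k[1]) / k[1], 0.01)
    expect_lt(abs(fit$k2 - k[2]) / k[2], 0.01)
    expect_true(fit$usable)
  }
})

test_that("degenerate flat inner curve yields k1 = 0 and unusable fit", {
  tt <- test_grid()
  io <- test_outer(tt)
  pair <- curve_pair(io, time_signal_curve(tt, rep(0, length(tt))))
  fit <- fit_exchange_rates(pair)
  expect_equal(fit$k1, 0)
  expect_true(is.na(fit$k2))
  expect_false(fit$usable)
  expect_match(fit$note, "flat inner")
})

test_that("fitted rates and NER are invariant to joint curve scaling", {
  tt <- test_grid()
  io <- test_outer(tt)
  inn <- forward_model(0.03, 0.02, io)
  f1 <- fit_exchange_rates(curve_pair(io, inn))
  io2 <- time_signal_curve(tt, io$values * 50)
  inn2 <- time_signal_curve(tt, inn$values * 50)
  f2 <- fit_exchange_rates(curve_pair(io2, inn2))
  expect_equal(f2$k1, f1$k1, tolerance = 1e-4)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-4)
  expect_equal(f2$NER, f1$NER, tolerance = 1e-4)
  expect_equal(f2$V_out, 50 * f1$V_out, tolerance = 1e-9)
  expect_equal(f2$V_in, 50 * f1$V_in, tolerance = 1e-9)
})

test_that("volumes and NER follow the defining identities", {
  tt <- test_grid()
  io <- test_outer(tt)
  inn <- forward_model(0.02, 0.01, io)
  pair <- curve_pair(io, inn)
  vol <- exchange_volumes(pair, 0.02, 0.01)
  expect_equal(vol$V_out, trapz(tt, io$values))
  expect_equal(vol$V_out_to_in, 0.02 * vol$V_out)
  expect_equal(vol$V_in_to_out, 0.01 * vol$V_in)
  expect_equal(vol$NER, vol$V_in_to_out / vol$V_out_to_in)
  # symmetric case: identical curves and equal rates give NER = 1
  sym <- curve_pair(io, io)
  expect_equal(exchange_volumes(sym, 0.05, 0.05)$NER, 1)
  # direct formula arithmetic: NER = (0.01*100)/(0.02*200) = 0.25 shape
  expect_equal((0.01 * 100) / (0.02 * 200), 0.25)
  ner_direct <- exchange_volumes(pair, 0.02, 0.01)
  expect_equal(ner_direct$NER,
               (0.01 * ner_direct$V_in) / (0.02 * ner_direct$V_out))
})

test_that("NER approaches 1 as the experiment lengthens (washout limit)", {
  k1 <- 0.05; k2 <- 0.04
  ners <- sapply(c(360, 1440, 5760), function(T) {
    tt <- seq(0, T, length.out = 2000)
    io <- gamma_variate_input(10, 20, 2, 30, tt)
    inn <- forward_model(k1, k2, io)
    k2 * trapz(tt, inn$values) / (k1 * trapz(tt, io$values))
  })
  expect_true(all(diff(ners) > 0))
  expect_gt(ners[3], 0.999)
})

test_that("QC gate flags small volumes without touching fitted values", {
  tt <- test_grid()
  io <- test_outer(tt)
  fits <- lapply(c(1, 1, 1, 0.01), function(sc) {
    sio <- time_signal_curve(tt, io$values * sc)
    fit_exchange_rates(curve_pair(sio, forward_model(0.02, 0.016, sio)))
  })
  gated <- qc_cohort(fits, frac = 0.05)
  expect_true(all(vapply(gated[1:3], `[[`, TRUE, "usable")))
  expect_false(gated[[4]]$usable)
  # thresholds change flags only, never values
  for (thr in c(0, 1, 1e6)) {
    g <- qc_gate(fits[[1]], thr)
    expect_equal(g$k1, fits[[1]]$k1)
    expect_equal(g$NER, fits[[1]]$NER)
  }
  expect_false(qc_gate(fits[[1]], 1e6)$usable)
  # V_in = 0 is always unusable
  zero <- fit_exchange_rates(curve_pair(io, time_signal_curve(tt, rep(0, 40))))
  expect_false(qc_gate(zero, 0)$usable)
})

test_that("thickness search recovers a planted shell and reports a profile", {
  tt <- test_grid()
  io <- test_outer(tt)
  inn <- generate_inner_from_outer(io, 0.02, 0.016)
  ph <- build_shell_phantom(3, 13, io, inn)
  res <- thickness_search(ph$dyn, ph$lab, 1, s_range = 1:5)
  expect_equal(res$optimal_s, 3)
  expect_equal(nrow(res$profile), 5)
  expect_true(all(diff(res$profile$outer_fraction) > 0))
  # single-candidate range returns that s
  res1 <- thickness_search(ph$dyn, ph$lab, 1, s_range = 2)
  expect_equal(res1$optimal_s, 2)
  # all-degenerate range errors
  expect_error(thickness_search(ph$dyn, ph$lab, 1, s_range = 7), "degenerate")
})
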