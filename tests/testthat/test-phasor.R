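test_that("concatenated-signal normalisation is a scale-invariant unit-sum map that leaves phasors unchanged", {
  cfg <- small_config()
  irf <- small_irf(cfg)
  t <- (0:148) * cfg$dt_ns
  ch <- lapply(1:3, function(i)
    (4 - i) * 100 * conv_trunc(irf$traces[[i]], biexp_fir(t, 0.6, 1, 4)) *
      cfg$dt_ns)
  cc <- pad_and_concatenate(ch)
  n1 <- normalize_concat(cc)
  expect_equal(sum(n1), 1, tolerance = 1e-12)
  expect_equal(normalize_concat(100 * cc), n1)
  expect_true(all(is.na(normalize_concat(rep(0, 447)))))
  cirf <- concat_irf(irf)
  expect_equal(frequency_deconvolve(n1, cirf),
               frequency_deconvolve(cc, cirf), tolerance = 1e-12)
})

test_that("the concatenated IRF has length 3M and recoverable channel segments", {
  cfg <- acquisition_config(rows = 4, cols = 4, n_samples = c(120, 149, 130))
  irf <- generate_irf(cfg)
  cirf <- concat_irf(irf)
  expect_length(cirf, 447)
  segs <- split_concat(cirf, 149)
  expect_equal(segs[[1]][1:120], irf$traces[[1]])
  expect_equal(segs[[1]][121:149], rep(0, 29))
  expect_equal(segs[[3]][1:130], irf$traces[[3]])
})

test_that("deconvolving the IRF from itself gives unit response at every harmonic", {
  irf <- small_irf()
  cirf <- concat_irf(irf)
  # raw DFT-ratio reference: the algebraic identity Y = U  =>  P = 1
  P <- frequency_deconvolve(cirf, cirf, phase_ref = "left")
  expect_equal(Mod(P - 1), rep(0, 9), tolerance = 1e-9)
  # the midpoint phase reference only rotates by the documented half-sample
  Pm <- frequency_deconvolve(cirf, cirf)
  expect_equal(Pm, P * exp(1i * pi * (1:9) / 447), tolerance = 1e-12)
})

test_that("identical per-channel IRFs make the spectral division ill-posed at off-grid harmonics", {
  cfg <- small_config()
  irf_same <- generate_irf(cfg, t0_ns = c(3, 3, 3))
  t <- (0:148) * cfg$dt_ns
  ch <- lapply(1:3, function(i)
    conv_trunc(irf_same$traces[[i]], exp(-t / 3)) * cfg$dt_ns)
  expect_error(frequency_deconvolve(pad_and_concatenate(ch),
                                    concat_irf(irf_same)),
               "ill-posed")
})

test_that("monoexponential decays land on the universal semicircle at all nine harmonics", {
  cfg <- small_config()
  irf <- small_irf(cfg)
  cirf <- concat_irf(irf)
  t <- (0:148) * cfg$dt_ns
  w <- 2 * pi * harmonic_frequencies(cfg) * 1e-9  # rad/ns
  for (tau in c(1.5, 3, 6)) {
    ch <- lapply(1:3, function(i)
      800 * conv_trunc(irf$traces[[i]], exp(-t / tau)) * cfg$dt_ns)
    P <- frequency_deconvolve(pad_and_concatenate(ch), cirf)
    expect_lt(max(abs((Re(P) - 0.5)^2 + Im(P)^2 - 0.25)), 5e-3)
    expect_true(all(Im(P) > 0))   # phasor sign convention
    # phasor lifetime at the fundamental matches the generating lifetime
    expect_equal(Im(P[1]) / (w[1] * Re(P[1])), tau, tolerance = 0.01)
  }
})

test_that("biexponential phasors are the intensity-weighted mixture of the component phasors", {
  cfg <- small_config()
  irf <- small_irf(cfg)
  cirf <- concat_irf(irf)
  t <- (0:148) * cfg$dt_ns
  a <- 0.7; tf <- 0.8; ts <- 2.5
  mono_P <- function(tau) {
    ch <- lapply(1:3, function(i)
      conv_trunc(irf$traces[[i]], exp(-t / tau)) * cfg$dt_ns)
    frequency_deconvolve(pad_and_concatenate(ch), cirf)
  }
  ch <- lapply(1:3, function(i)
    conv_trunc(irf$traces[[i]], biexp_fir(t, a, tf, ts)) * cfg$dt_ns)
  P <- frequency_deconvolve(pad_and_concatenate(ch), cirf)
  # intensity fraction of the fast component on the sampled time base
  If <- a * sum(exp(-t / tf))
  Is <- (1 - a) * sum(exp(-t / ts))
  wf <- If / (If + Is)
  expect_equal(P, wf * mono_P(tf) + (1 - wf) * mono_P(ts), tolerance = 1e-9)
})

test_that("frequency-domain deconvolution recovers the generating FIR's normalised response", {
  cfg <- small_config()
  irf <- small_irf(cfg)
  t <- (0:148) * cfg$dt_ns
  h <- biexp_fir(t, 0.65, 0.7, 2.2)
  ch <- lapply(1:3, function(i) conv_trunc(irf$traces[[i]], h) * cfg$dt_ns)
  P <- frequency_deconvolve(pad_and_concatenate(ch), concat_irf(irf))
  # oracle: DFT of the zero-padded sampled FIR, same phase reference
  Hd <- stats::fft(c(h, rep(0, 298)))
  oracle <- Conj(Hd[2:10] / Hd[1]) * exp(1i * pi * (1:9) / 447)
  expect_lt(max(Mod(P - oracle)), 1e-6)
})

test_that("bivariate Gaussian fits recover moments, degenerate clouds, and rotation equivariance", {
  pts <- matrix(rep(c(0.4, 0.2), each = 5), 5, 2)
  g <- fit_phasor_gaussian(pts)
  expect_equal(g$mean, c(0.4, 0.2))
  expect_equal(g$cov, matrix(0, 2, 2))
  expect_error(fit_phasor_gaussian(pts[1:2, ]), "at least 3")
  set.seed(11)
  mu <- c(0.5, 0.3)
  A <- matrix(c(0.04, 0.01, 0, 0.02), 2, 2)
  sigma <- A %*% t(A)
  X <- matrix(rnorm(2e4), 1e4, 2) %*% t(A)
  X <- sweep(X, 2, mu, "+")
  g <- fit_phasor_gaussian(X)
  expect_equal(g$mean, mu, tolerance = 0.05)
  expect_equal(g$cov, sigma, tolerance = 0.05)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  gr <- fit_phasor_gaussian(X %*% t(R))
  expect_equal(gr$mean, as.vector(R %*% g$mean), tolerance = 1e-10)
  expect_equal(gr$cov, R %*% g$cov %*% t(R), tolerance = 1e-10)
})

test_that("pairwise phasor features behave on hand-computable cases", {
  g <- function(mean, cov) list(mean = mean, cov = cov)
  gA <- g(c(0.2, 0.1), diag(c(4, 1)))
  expect_equal(phasor_pair_features(gA, gA),
               c(distance = 0, spread = 0, angle = 0, symmetry = 0))
  gB <- g(c(0.5, 0.5), diag(c(4, 1)))
  expect_equal(phasor_pair_features(gA, gB)[["distance"]], 0.5)
  gC <- g(c(0.2, 0.1), diag(c(1, 4)))  # 90-degree rotation of gA's ellipse
  pf <- phasor_pair_features(gA, gC)
  expect_equal(pf[["angle"]], 90)
  expect_equal(pf[["spread"]], 0)
  expect_equal(pf[["symmetry"]], 0)
  # matrix-norm spread variant
  expect_equal(phasor_pair_features(gA, gC, spread_method = "norm")[["spread"]],
               norm(diag(c(3, -3)), "F"))
  # flat (rank-1) covariance flags symmetry as NA
  gD <- g(c(0, 0), diag(c(1, 0)))
  expect_true(is.na(phasor_pair_features(gD, gA)[["symmetry"]]))
})

test_that("the phasor pool has 36 named features, vanishing for identical regions, and extracts faster than reconvolution fitting", {
  cfg <- small_config(12, 12)
  irf <- small_irf(cfg)
  p <- default_surround_params()
  flat <- generate_lesion_image(scene_spec(region1 = p, region2 = p,
                                           noise = list(type = "none"),
                                           seed = 1), cfg, irf)
  pre0 <- preprocess_with_masks(flat, half_masks(12, 12))
  ph0 <- extract_phasor_pool(pre0, irf)
  expect_named(ph0$features, phasor_feature_names(cfg))
  expect_length(ph0$features, 36)
  expect_equal(max(abs(ph0$features)), 0, tolerance = 1e-6)
  # runtime ordering on a noisy image (the fitting-free path is the point)
  img <- generate_lesion_image(scene_spec(seed = 3), cfg, irf)
  pre <- preprocess_image(img)
  t_ph <- system.time(extract_phasor_pool(pre, irf))[3]
  t_td <- system.time(extract_td_pools(pre, irf))[3]
  expect_lt(t_ph, t_td)
})

test_that("time- and frequency-domain lifetimes agree on monoexponential fixtures", {
  cfg <- small_config()
  irf <- small_irf(cfg)
  cirf <- concat_irf(irf)
  t <- (0:148) * cfg$dt_ns
  w1 <- 2 * pi * harmonic_frequencies(cfg, 1) * 1e-9
  for (tau in c(1.5, 2.5, 4, 6)) {
    y <- 700 * conv_trunc(irf$traces[[1]], exp(-t / tau)) * cfg$dt_ns
    fit_tau <- fit_biexponential(y, irf$traces[[1]], cfg$dt_ns,
                                 n_exp = 1)$tau_fast
    ch <- lapply(1:3, function(i)
      700 * conv_trunc(irf$traces[[i]], exp(-t / tau)) * cfg$dt_ns)
    P <- frequency_deconvolve(pad_and_concatenate(ch), cirf, harmonics = 1)
    phasor_tau <- Im(P) / (w1 * Re(P))
    expect_equal(phasor_tau, fit_tau, tolerance = 0.01)
  }
})
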