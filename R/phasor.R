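# Fitting-free frequency-domain analysis: deconvolution of the concatenated
# three-channel decay by spectral division, phasor representation at the
# first nine harmonics, bivariate-Gaussian region fits, and the
# distance/spread/angle/symmetry global feature set.

#' Normalise concatenated decays to unit sum
#'
#' @param signal Length-3M vector or `3M x npix` matrix.
#' @return Same shape, each pixel's samples divided by their sum.  Pixels with
#'   a non-positive sum are flagged invalid by returning `NA` samples.
#' @export
normalize_concat <- function(signal) {
  m <- if (is.null(dim(signal))) matrix(signal, ncol = 1) else signal
  tot <- colSums(m)
  bad <- !(tot > 0)
  out <- sweep(m, 2, ifelse(bad, NA_real_, tot), "/")
  if (is.null(dim(signal))) drop(out) else out
}

#' Concatenate the per-channel IRFs
#'
#' Tail-pads each channel IRF to the longest channel length M and concatenates
#' in band order, mirroring the signal-path concatenation so that the
#' concatenated measurement is (approximately) the concatenated IRF convolved
#' with the effective three-channel impulse response.
#'
#' @param irf A `maflim_irf`.
#' @return Length-3M numeric vector.
#' @export
concat_irf <- function(irf) {
  stopifnot(inherits(irf, "maflim_irf"))
  pad_and_concatenate(irf$traces)
}

#' Frequency-domain deconvolution at the harmonic bins
#'
#' Estimates the normalised fluorescence frequency response
#' `P(w) = Y(w) U(0) / (U(w) Y(0))` at the requested harmonics of the
#' 3M-point discrete Fourier transform, replacing iterative time-domain
#' deconvolution by a division in the frequency domain.  `P(0) = 1` by
#' construction, and `(Re P, Im P) = (G, S)` are the phasor coordinates,
#' reported in the FLIM phasor sign convention (`S >= 0` for decays): the
#' raw DFT ratio is conjugated, so a monoexponential maps near
#' `1 / (1 + i w tau)` on the upper universal semicircle.
#'
#' @param concat Concatenated decay(s): length-3M vector or `3M x npix`
#'   matrix.
#' @param cirf Concatenated IRF (length 3M, from [concat_irf()]).
#' @param harmonics Integer harmonic indices k (DFT bins `k + 1`); default
#'   `1:9`.
#' @param u_tol Relative tolerance on `|U(w)|`: harmonics where the IRF
#'   spectrum falls below `u_tol * |U(0)|` make the division ill-posed and
#'   raise an error.
#' @param phase_ref `"midpoint"` (default) references the DFT phase to the
#'   sample-bin midpoints, compensating the half-sample phase bias that
#'   left-endpoint time stamping imprints on the spectrum of a sampled decay
#'   (without it, monoexponential phasors rotate off the universal
#'   semicircle by about `S * w * dt / 2`); `"left"` returns the raw DFT
#'   ratio.
#' @return Complex matrix, `length(harmonics) x npix` (a vector input gives a
#'   vector).  Pixels with non-positive DC response are `NA`.
#' @export
frequency_deconvolve <- function(concat, cirf, harmonics = 1:9,
                                 u_tol = 1e-9,
                                 phase_ref = c("midpoint", "left")) {
  phase_ref <- match.arg(phase_ref)
  m <- if (is.null(dim(concat))) matrix(concat, ncol = 1) else concat
  if (nrow(m) != length(cirf))
    stop("concatenated signal and IRF must have equal length (3M)")
  stopifnot(all(harmonics >= 1), all(harmonics < length(cirf)))
  U <- stats::fft(as.numeric(cirf))
  U0 <- U[1]
  Uk <- U[harmonics + 1L]
  if (any(Mod(Uk) < u_tol * Mod(U0)))
    stop("IRF spectrum vanishes at a requested harmonic: division ill-posed")
  Yf <- stats::mvfft(m)
  Y0 <- Yf[1, ]
  Yk <- Yf[harmonics + 1L, , drop = FALSE]
  bad <- !(Re(Y0) > 0)
  P <- Conj(sweep(Yk, 2, Y0, "/") * (U0 / Uk))
  if (phase_ref == "midpoint")
    P <- P * exp(1i * pi * harmonics / length(cirf))
  P[, bad] <- NA_complex_
  if (is.null(dim(concat))) drop(P) else P
}

#' Fit a bivariate Gaussian to a phasor point cloud
#'
#' Maximum-likelihood fit of a bivariate normal: the sample mean and the
#' (1/n-normalised) sample covariance of the `(G, S)` points.
#'
#' @param points `n x 2` matrix of phasor coordinates, `n >= 3`.
#' @return List with `mean` (length 2) and `cov` (2 x 2 symmetric PSD).
#' @export
fit_phasor_gaussian <- function(points) {
  pts <- as.matrix(points)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 phasor points for a Gaussian fit")
  mu <- colMeans(pts)
  centred <- sweep(pts, 2, mu)
  sigma <- crossprod(centred) / nrow(pts)
  list(mean = mu, cov = (sigma + t(sigma)) / 2)
}

#' Pairwise phasor-distribution features for two regions
#'
#' Given the bivariate Gaussian fits of the two regions' phasor distributions
#' at one frequency, computes:
#' * distance: Euclidean norm of the mean difference;
#' * spread: absolute difference of the covariance determinants (a matrix
#'   Frobenius-norm variant is available via `spread_method = "norm"`);
#' * angle: acute angle in degrees between the leading eigenvectors
#'   (directions of maximum variance);
#' * symmetry: absolute difference of the eccentricity ratios
#'   `s = lambda_max / lambda_min` of the two covariances.
#'
#' All four are symmetric in the two regions, hence invariant to the
#' arbitrary region labelling.
#'
#' @param g1,g2 Gaussian fits from [fit_phasor_gaussian()].
#' @param spread_method `"det"` (default) or `"norm"`.
#' @param eps Absolute eigenvalue floor (phasor coordinates are order one):
#'   a covariance whose leading eigenvalue falls below `eps` is treated as a
#'   point distribution (no orientation, unit eccentricity ratio), so
#'   numerically identical regions give exact zeros instead of noise-driven
#'   eigenvector directions.
#' @return Named numeric: `distance`, `spread`, `angle`, `symmetry`.  A zero
#'   trailing eigenvalue (flat, rank-1 cloud) leaves `symmetry` as `NA`
#'   (flagged, excluded downstream).
#' @export
phasor_pair_features <- function(g1, g2, spread_method = c("det", "norm"),
                                 eps = 1e-12) {
  spread_method <- match.arg(spread_method)
  d <- sqrt(sum((g1$mean - g2$mean)^2))
  spread <- switch(spread_method,
    det = abs(det(g1$cov) - det(g2$cov)),
    norm = norm(g1$cov - g2$cov, type = "F"))
  e1 <- eigen(g1$cov, symmetric = TRUE)
  e2 <- eigen(g2$cov, symmetric = TRUE)
  point1 <- e1$values[1] <= eps
  point2 <- e2$values[1] <= eps
  if (point1 || point2) {
    angle <- 0
  } else {
    cosang <- abs(sum(e1$vectors[, 1] * e2$vectors[, 1]))
    angle <- acos(min(max(cosang, -1), 1)) * 180 / pi
  }
  sym_ratio <- function(ev, point) {
    if (point) return(1)
    if (ev$values[2] <= eps * ev$values[1]) return(NA_real_)
    ev$values[1] / ev$values[2]
  }
  s1 <- sym_ratio(e1, point1)
  s2 <- sym_ratio(e2, point2)
  c(distance = d, spread = spread, angle = angle,
    symmetry = if (is.na(s1) || is.na(s2)) NA_real_ else abs(s1 - s2))
}

#' Canonical names of the phasor feature pool (36 features)
#'
#' `{distance, spread, angle, symmetry}_{f}` over the first `n_harmonics`
#' harmonic frequencies, labelled in MHz (e.g. `distance_50.4MHz`).
#' @param config A `maflim_config`.
#' @param n_harmonics Number of harmonics (default 9).
#' @export
phasor_feature_names <- function(config = acquisition_config(),
                                 n_harmonics = 9) {
  labs <- harmonic_labels(config, n_harmonics)
  as.vector(t(outer(c("distance", "spread", "angle", "symmetry"),
                    labs, paste, sep = "_")))
}

#' Extract the phasor global feature pool for one lesion
#'
#' Deconvolves the concatenated IRF from every valid pixel's concatenated
#' decay in the frequency domain, maps each pixel to its phasor at the first
#' `n_harmonics` harmonics, fits a bivariate Gaussian to each region's phasor
#' distribution, and computes the four pairwise features per frequency
#' (4 x 9 = 36 features).
#'
#' @param pre A `maflim_preprocessed`.
#' @param irf The acquisition `maflim_irf`.
#' @param n_harmonics Number of harmonics (default 9).
#' @param spread_method Passed to [phasor_pair_features()].
#' @return List with `features` (named numeric, 36 entries) and `phasors`
#'   (per-harmonic list of the two regions' Gaussian fits).
#' @export
extract_phasor_pool <- function(pre, irf, n_harmonics = 9,
                                spread_method = "det") {
  stopifnot(inherits(pre, "maflim_preprocessed"))
  valid <- as.vector(pre$masks$valid)
  cirf <- concat_irf(irf)
  if (length(cirf) != nrow(pre$concat))
    stop("IRF channel lengths do not match the signal path")
  P <- frequency_deconvolve(pre$concat[, valid, drop = FALSE], cirf,
                            harmonics = seq_len(n_harmonics))
  r1 <- as.vector(pre$masks$region1)[valid]
  r2 <- as.vector(pre$masks$region2)[valid]
  labs <- harmonic_labels(pre$config, n_harmonics)
  feats <- numeric(0)
  fits <- vector("list", n_harmonics)
  for (k in seq_len(n_harmonics)) {
    pts <- cbind(Re(P[k, ]), Im(P[k, ]))
    g1 <- fit_phasor_gaussian(pts[r1, , drop = FALSE])
    g2 <- fit_phasor_gaussian(pts[r2, , drop = FALSE])
    pf <- phasor_pair_features(g1, g2, spread_method)
    names(pf) <- paste(names(pf), labs[k], sep = "_")
    feats <- c(feats, pf)
    fits[[k]] <- list(region1 = g1, region2 = g2)
  }
  feats <- feats[phasor_feature_names(pre$config, n_harmonics)]
  list(features = feats, phasors = fits)
}
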