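# Synthetic maFLIM data generation: per-pixel biexponential fluorescence
# impulse responses convolved with a Gaussian instrument response, two spatial
# regions per lesion image (lesion / surround), channel-dependent intensities,
# configurable noise, and patient-grouped benign/malignant cohorts.

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Biexponential fluorescence impulse response
#'
#' `h(t) = alpha_fast * exp(-t / tau_fast) + (1 - alpha_fast) * exp(-t / tau_slow)`,
#' the two-component decay model used throughout: the fast and slow component
#' weights sum to one, so a single weight parameterises the mixture.
#'
#' @param t Time points (ns).
#' @param alpha_fast Fast-component weight in `[0, 1]`.
#' @param tau_fast,tau_slow Fast and slow lifetimes (ns), `tau_fast <= tau_slow`.
#' @return `h(t)` evaluated at `t` (unit amplitude at `t = 0`).
#' @export
biexp_fir <- function(t, alpha_fast, tau_fast, tau_slow) {
  stopifnot(alpha_fast >= 0, alpha_fast <= 1, tau_fast > 0,
            tau_fast <= tau_slow)
  alpha_fast * exp(-t / tau_fast) + (1 - alpha_fast) * exp(-t / tau_slow)
}

#' Per-region biexponential decay parameters
#'
#' One set of decay parameters per emission channel (390, 452, 500 nm):
#' fast-component weight, fast/slow lifetimes and an intensity scale.
#'
#' @param alpha_fast Length-3 fast-component weights in `[0, 1]`.
#' @param tau_fast,tau_slow Length-3 lifetimes in ns, `tau_fast <= tau_slow`
#'   per channel.
#' @param intensity Length-3 non-negative intensity scales (arbitrary counts).
#' @return An object of class `region_params`.
#' @export
region_params <- function(alpha_fast, tau_fast, tau_slow, intensity) {
  stopifnot(length(alpha_fast) == 3, length(tau_fast) == 3,
            length(tau_slow) == 3, length(intensity) == 3)
  if (any(!is.finite(c(alpha_fast, tau_fast, tau_slow, intensity))))
    stop("region parameters must be finite")
  if (any(alpha_fast < 0 | alpha_fast > 1))
    stop("alpha_fast must lie in [0, 1]")
  if (any(tau_fast <= 0) || any(tau_fast > tau_slow))
    stop("lifetimes must satisfy 0 < tau_fast <= tau_slow")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  structure(list(alpha_fast = alpha_fast, tau_fast = tau_fast,
                 tau_slow = tau_slow, intensity = intensity),
            class = "region_params")
}

#' Scene specification for one synthetic lesion image
#'
#' Defines the two-region geometry (a centred lesion disc within healthy
#' surround), the decay parameters of each region, the noise model, a
#' per-channel baseline offset, and optional acquisition artifacts
#' (saturated pixels, dark hair stripes).
#'
#' @param region1,region2 `region_params` for the lesion disc (region 1) and
#'   the surround (region 2).
#' @param lesion_frac Fraction of the field of view covered by the lesion disc
#'   (default 0.30).
#' @param noise `list(type = "gaussian", snr_db = ...)` for additive Gaussian
#'   noise at a per-pixel peak SNR in dB, `list(type = "poisson",
#'   peak_counts = ...)` for shot noise, or `list(type = "none")`.
#' @param offset Per-channel constant baseline offset in counts (length 1 or 3).
#' @param adc_max Digitiser full-scale level; generated decays are clipped here.
#' @param saturated_frac Fraction of pixels forced into saturation (artifact).
#' @param hair_rows Integer rows rendered as dark stripes (hair artifact).
#' @param seed Integer seed making image generation deterministic.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(region1 = default_lesion_params(),
                       region2 = default_surround_params(),
                       lesion_frac = 0.30,
                       noise = list(type = "gaussian", snr_db = 25),
                       offset = 10,
                       adc_max = 4095,
                       saturated_frac = 0,
                       hair_rows = integer(0),
                       seed = 1L) {
  stopifnot(inherits(region1, "region_params"), inherits(region2, "region_params"),
            lesion_frac > 0, lesion_frac < 1,
            saturated_frac >= 0, saturated_frac < 1)
  noise$type <- match.arg(noise$type, c("gaussian", "poisson", "none"))
  if (length(offset) == 1) offset <- rep(offset, 3)
  structure(list(region1 = region1, region2 = region2,
                 lesion_frac = lesion_frac, noise = noise,
                 offset = offset, adc_max = adc_max,
                 saturated_frac = saturated_frac,
                 hair_rows = as.integer(hair_rows), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default decay parameters for healthy surround skin
#'
#' Lifetimes and weights in the range reported for the dominant skin
#' fluorophores at the three bands (collagen at 390 nm, NADH at 452 nm,
#' FAD at 500 nm).
#' @export
default_surround_params <- function() {
  region_params(alpha_fast = c(0.55, 0.65, 0.60),
                tau_fast = c(1.00, 0.70, 0.80),
                tau_slow = c(5.0, 3.5, 4.0),
                intensity = c(1500, 1200, 900))
}

#' Default decay parameters for a (benign) lesion region
#'
#' Mildly shifted from the surround so that the two regions are separable by
#' clustering even without any malignant effect.
#' @export
default_lesion_params <- function() {
  region_params(alpha_fast = c(0.62, 0.70, 0.64),
                tau_fast = c(0.90, 0.65, 0.75),
                tau_slow = c(5.5, 3.8, 4.3),
                intensity = c(1350, 1000, 950))
}

shift_params <- function(p, d_alpha = 0, d_tau_fast = 0, d_tau_slow = 0,
                         intensity_scale = 1) {
  a <- pmin(0.99, pmax(0.01, p$alpha_fast + d_alpha))
  tf <- pmax(0.1, p$tau_fast + d_tau_fast)
  ts <- pmax(tf + 0.05, p$tau_slow + d_tau_slow)
  region_params(a, tf, ts, pmax(0, p$intensity * intensity_scale))
}

#' Generate a per-channel instrument response function
#'
#' Models the measured reflection of the excitation pulse as a Gaussian of
#' given full width at half maximum centred at `t0_ns`, sampled on the
#' configuration time base and normalised to unit area (`sum * dt = 1`) per
#' channel. A vanishing `fwhm_ns` yields a single-sample impulse.
#'
#' The default peak times are staggered across the three channels
#' (3.0 / 3.4 / 3.8 ns), emulating the channel-dependent optical and detector
#' path delays of a real multispectral instrument.  This matters for the
#' concatenated frequency-domain path: with three *identical* channel IRFs
#' the concatenated IRF spectrum vanishes exactly at every harmonic not
#' divisible by three (the channel phase factors sum as cube roots of unity),
#' and the spectral division becomes ill-posed there.
#'
#' @param config A `maflim_config`.
#' @param fwhm_ns Pulse full width at half maximum in ns (default 1.0;
#'   length 1 or 3).
#' @param t0_ns Pulse peak time in ns per channel (default `c(3.0, 3.4,
#'   3.8)`, leaving a pre-pulse baseline used by the SNR estimator).
#' @return An object of class `maflim_irf`: a list with per-channel traces.
#' @export
generate_irf <- function(config, fwhm_ns = 1.0, t0_ns = c(3.0, 3.4, 3.8)) {
  stopifnot(all(fwhm_ns >= 0), all(t0_ns >= 0))
  if (length(fwhm_ns) == 1) fwhm_ns <- rep(fwhm_ns, 3)
  if (length(t0_ns) == 1) t0_ns <- rep(t0_ns, 3)
  dt <- config$dt_ns
  traces <- vector("list", 3L)
  for (ch in 1:3) {
    n <- config$n_samples[ch]
    t <- (seq_len(n) - 1) * dt
    if (t0_ns[ch] > t[n]) stop("t0_ns lies outside the channel time window")
    if (fwhm_ns[ch] < dt / 10) {
      u <- numeric(n)
      u[round(t0_ns[ch] / dt) + 1L] <- 1 / dt
    } else {
      sigma <- fwhm_ns[ch] / (2 * sqrt(2 * log(2)))
      u <- exp(-0.5 * ((t - t0_ns[ch]) / sigma)^2)
      if (u[n] > 1e-6 * max(u))
        stop("IRF truncated by the acquisition window; reduce t0_ns or fwhm_ns")
      u <- u / (sum(u) * dt)
    }
    traces[[ch]] <- u
  }
  structure(list(config = config, traces = traces,
                 fwhm_ns = fwhm_ns, t0_ns = t0_ns),
            class = "maflim_irf")
}

# Noiseless measured decay for one channel: intensity * (IRF (*) h) * dt,
# truncated to the acquisition window.
decay_template <- function(irf_trace, params, ch, dt) {
  n <- length(irf_trace)
  t <- (seq_len(n) - 1) * dt
  h <- biexp_fir(t, params$alpha_fast[ch], params$tau_fast[ch],
                 params$tau_slow[ch])
  params$intensity[ch] * conv_trunc(irf_trace, h) * dt
}

#' Lesion/surround region map for a scene
#'
#' @param scene A `scene_spec`.
#' @param config A `maflim_config`.
#' @return Logical `rows x cols` matrix, `TRUE` inside the lesion disc.
#' @export
scene_region_map <- function(scene, config) {
  r0 <- (config$rows + 1) / 2
  c0 <- (config$cols + 1) / 2
  radius <- sqrt(scene$lesion_frac * config$rows * config$cols / pi)
  outer(seq_len(config$rows), seq_len(config$cols),
        function(i, j) (i - r0)^2 + (j - c0)^2 <= radius^2)
}

#' Generate one synthetic maFLIM lesion image
#'
#' Forward model: for every pixel and channel the noiseless decay is the
#' channel IRF convolved with that pixel's region biexponential impulse
#' response, scaled by the region intensity; noise and a constant baseline
#' offset are added and the result is clipped at the declared ADC full scale.
#' Deterministic for a fixed `scene$seed`.
#'
#' @param scene A `scene_spec`.
#' @param config A `maflim_config`.
#' @param irf A `maflim_irf` on the same configuration.
#' @return An object of class `maflim_image`: per-channel decay cubes
#'   (`rows x cols x n_samples[ch]`), the ADC level, and the ground-truth
#'   region map under `$truth`.
#' @export
generate_lesion_image <- function(scene, config, irf) {
  stopifnot(inherits(scene, "scene_spec"), inherits(config, "maflim_config"),
            inherits(irf, "maflim_irf"))
  lesion <- scene_region_map(scene, config)
  npix <- config$rows * config$cols
  with_seed(scene$seed, {
    channels <- vector("list", 3L)
    for (ch in 1:3) {
      n <- config$n_samples[ch]
      tmpl1 <- decay_template(irf$traces[[ch]], scene$region1, ch, config$dt_ns)
      tmpl2 <- decay_template(irf$traces[[ch]], scene$region2, ch, config$dt_ns)
      # n x npix matrix of noiseless decays
      y <- matrix(tmpl2, n, npix)
      y[, as.vector(lesion)] <- tmpl1
      # the electronic noise floor follows the unattenuated signal level, so
      # hair-shadowed (attenuated) pixels genuinely lose SNR
      if (scene$noise$type == "gaussian")
        sigma_col <- apply(y, 2, max) / 10^(scene$noise$snr_db / 20)
      if (length(scene$hair_rows)) {
        hair <- matrix(FALSE, config$rows, config$cols)
        hair[scene$hair_rows, ] <- TRUE
        y[, as.vector(hair)] <- y[, as.vector(hair)] * 0.02
      }
      y <- switch(scene$noise$type,
        gaussian = {
          sigma <- matrix(sigma_col, n, npix, byrow = TRUE)
          y + matrix(stats::rnorm(n * npix), n, npix) * sigma
        },
        poisson = {
          scale <- scene$noise$peak_counts / max(y)
          matrix(stats::rpois(n * npix, pmax(0, y * scale)), n, npix) / scale
        },
        none = y
      )
      y <- y + scene$offset[ch]
      channels[[ch]] <- array(pmin(y, scene$adc_max),
                              dim = c(n, config$rows, config$cols))
      channels[[ch]] <- aperm(channels[[ch]], c(2, 3, 1))
    }
    if (scene$saturated_frac > 0) {
      nsat <- max(1L, round(scene$saturated_frac * npix))
      sat <- sample.int(npix, nsat)
      for (ch in 1:3) {
        flat <- matrix(aperm(channels[[ch]], c(3, 1, 2)),
                       config$n_samples[ch], npix)
        flat[seq_len(min(20L, nrow(flat))), sat] <- scene$adc_max
        channels[[ch]] <- aperm(array(flat, c(config$n_samples[ch],
                                              config$rows, config$cols)),
                                c(2, 3, 1))
      }
    }
    structure(list(config = config, channels = channels,
                   adc_max = scene$adc_max,
                   truth = list(region_map = lesion, scene = scene)),
              class = "maflim_image")
  })
}

#' Patient-grouped cohort specification
#'
#' Defines a cohort of patients each contributing one or more lesions with a
#' benign/malignant label, the malignant effect on the lesion-region decay
#' parameters, and the spread of per-patient random offsets. The default
#' `patients` table mirrors a 30-patient / 60-lesion clinical distribution
#' with 41 benign and 19 malignant lesions, grouped by diagnosis so every
#' patient's lesions share one label.
#'
#' @param patients Data frame with columns `patient_id`, `n_lesions`, `label`
#'   (`"benign"` or `"malignant"`).
#' @param effect Malignant-class shifts applied to the lesion-region
#'   parameters: a list with length-3 per-channel entries `d_alpha_fast`,
#'   `d_tau_fast`, `d_tau_slow` (ns). Set all zero for a null cohort.
#' @param inter_patient_sd Spread of per-patient random parameter offsets:
#'   list with `alpha`, `tau` (ns) and `intensity_frac` entries.
#' @param seed Integer seed for cohort generation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(patients = default_cohort_patients(),
                        effect = default_malignant_effect(),
                        inter_patient_sd = list(alpha = 0.02, tau = 0.10,
                                                intensity_frac = 0.05),
                        seed = 1L) {
  stopifnot(is.data.frame(patients),
            all(c("patient_id", "n_lesions", "label") %in% names(patients)))
  if (sum(patients$n_lesions) < 1) stop("cohort must contain at least one lesion")
  if (!all(patients$label %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  structure(list(patients = patients, effect = effect,
                 inter_patient_sd = inter_patient_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default patient table: 30 patients, 60 lesions, 41 benign / 19 malignant
#'
#' Mirrors the clinical distribution of pigmented lesion diagnoses: solar
#' lentigo (2 patients / 10 lesions) and seborrheic keratosis (15/31) as
#' benign; superficial BCC (2/6), nodular BCC (5/5) and melanoma (6/8) as
#' malignant.
#' @export
default_cohort_patients <- function() {
  groups <- list(
    list(diag = "solar_lentigo", label = "benign", lesions = c(5, 5)),
    list(diag = "pSK", label = "benign", lesions = c(rep(2, 14), 3)),
    list(diag = "superficial_BCC", label = "malignant", lesions = c(3, 3)),
    list(diag = "nodular_BCC", label = "malignant", lesions = rep(1, 5)),
    list(diag = "melanoma", label = "malignant", lesions = c(2, 2, 1, 1, 1, 1))
  )
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(diagnosis = g$diag, label = g$label, n_lesions = g$lesions)))
  out$patient_id <- sprintf("P%02d", seq_len(nrow(out)))
  out[, c("patient_id", "diagnosis", "n_lesions", "label")]
}

#' Default malignant effect on lesion-region decay parameters
#'
#' Malignant transformation is emulated as an increased fast-component weight
#' in all bands (free-NADH shift and collagen remodelling), a shortened NADH
#' fast lifetime at 452 nm, and lengthened slow lifetimes.
#' @export
default_malignant_effect <- function() {
  list(d_alpha_fast = c(0.10, 0.12, 0.08),
       d_tau_fast = c(0.00, -0.25, 0.00),
       d_tau_slow = c(0.80, 0.30, 0.30))
}

#' Null (zero) malignant effect
#' @export
null_effect <- function() {
  list(d_alpha_fast = c(0, 0, 0), d_tau_fast = c(0, 0, 0),
       d_tau_slow = c(0, 0, 0))
}

#' Generate a patient-grouped synthetic lesion cohort
#'
#' Every patient receives one random offset vector (drawn with spread
#' `inter_patient_sd`) applied identically to both regions of all their
#' lesions; malignant lesions additionally receive the class effect on the
#' lesion region. Deterministic for a fixed `cohort$seed`.
#'
#' @param cohort A `cohort_spec`.
#' @param scene_template A `scene_spec` providing geometry, baseline region
#'   parameters, noise and artifacts.
#' @param config A `maflim_config`.
#' @param irf A `maflim_irf`.
#' @return An object of class `maflim_cohort`: `$lesions` (list of
#'   `list(image, lesion_id, patient_id, label)`) and `$manifest` (data frame
#'   of lesion_id, patient_id, label).
#' @export
generate_cohort <- function(cohort, scene_template = scene_spec(),
                            config = acquisition_config(), irf = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (is.null(irf)) irf <- generate_irf(config)
  pts <- cohort$patients
  sdp <- cohort$inter_patient_sd
  with_seed(cohort$seed, {
    lesions <- list()
    manifest <- list()
    lesion_no <- 0L
    for (i in seq_len(nrow(pts))) {
      d_alpha <- stats::rnorm(3, 0, sdp$alpha)
      d_tau <- stats::rnorm(3, 0, sdp$tau)
      i_scale <- exp(stats::rnorm(3, 0, sdp$intensity_frac))
      for (k in seq_len(pts$n_lesions[i])) {
        lesion_no <- lesion_no + 1L
        r1 <- shift_params(scene_template$region1, d_alpha, d_tau, d_tau, i_scale)
        r2 <- shift_params(scene_template$region2, d_alpha, d_tau, d_tau, i_scale)
        if (pts$label[i] == "malignant") {
          ef <- cohort$effect
          r1 <- shift_params(r1, ef$d_alpha_fast, ef$d_tau_fast, ef$d_tau_slow)
        }
        sc <- scene_template
        sc$region1 <- r1
        sc$region2 <- r2
        sc$seed <- sample.int(.Machine$integer.max, 1L)
        img <- generate_lesion_image(sc, config, irf)
        lesion_id <- sprintf("L%03d", lesion_no)
        lesions[[lesion_no]] <- list(image = img, lesion_id = lesion_id,
                                     patient_id = pts$patient_id[i],
                                     label = pts$label[i])
        manifest[[lesion_no]] <- data.frame(lesion_id = lesion_id,
                                            patient_id = pts$patient_id[i],
                                            label = pts$label[i])
      }
    }
    structure(list(lesions = lesions, manifest = do.call(rbind, manifest),
                   config = config, irf = irf),
              class = "maflim_cohort")
  })
}

#' @export
print.maflim_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("maFLIM synthetic cohort: %d lesions from %d patients (%d benign / %d malignant)\n",
              nrow(m), length(unique(m$patient_id)),
              sum(m$label == "benign"), sum(m$label == "malignant")))
  invisible(x)
}
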