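# Pixel- and image-level preprocessing of maFLIM decay stacks: baseline
# offset subtraction, spatial averaging, SNR/saturation masking, tail
# zero-padding with channel concatenation, and two-region K-means clustering
# of the concatenated decays.

# rows x cols x T array <-> T x npix matrix (pixels in column-major order)
decay_matrix <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2])
}
decay_array <- function(mat, rows, cols) {
  aperm(array(mat, c(nrow(mat), rows, cols)), c(2, 3, 1))
}

#' Subtract the baseline offset from fluorescence decays
#'
#' The constant/slowly varying baseline is estimated by a least-squares
#' straight line fitted jointly through the first and last `n_edge` time
#' points of each decay, evaluated over the full time vector and subtracted.
#'
#' @param decay Numeric vector (one decay) or matrix with time along rows and
#'   pixels along columns.
#' @param n_edge Number of samples taken from each end (default 5).
#' @return Offset-subtracted decay(s), same shape as the input.
#' @export
subtract_offset <- function(decay, n_edge = 5) {
  vec <- is.null(dim(decay))
  y <- if (vec) matrix(decay, ncol = 1) else decay
  n <- nrow(y)
  if (n < 2 * n_edge)
    stop("decay must have at least 2 * n_edge samples")
  idx <- c(seq_len(n_edge), seq(n - n_edge + 1, n))
  tt <- seq_len(n) - 1
  X <- cbind(1, tt[idx])
  beta <- solve(crossprod(X), crossprod(X, y[idx, , drop = FALSE]))
  out <- y - cbind(1, tt) %*% beta
  if (vec) drop(out) else out
}

# box mean over an (2r+1) x (2r+1) neighbourhood with in-bounds
# normalisation at the image borders, via summed-area tables
box_mean <- function(mat, r) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  S <- apply(apply(mat, 2, cumsum), 1, cumsum)  # S is nc x nr (transposed)
  S <- t(S)
  pad <- matrix(0, nr + 1, nc + 1)
  pad[-1, -1] <- S
  i1 <- pmax(seq_len(nr) - r, 1)
  i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1)
  j2 <- pmin(seq_len(nc) + r, nc)
  tot <- pad[i2 + 1, j2 + 1, drop = FALSE] - pad[i1, j2 + 1, drop = FALSE] -
    pad[i2 + 1, j1, drop = FALSE] + pad[i1, j1, drop = FALSE]
  cnt <- outer(i2 - i1 + 1, j2 - j1 + 1)
  tot / cnt
}

#' Spatially average a maFLIM image
#'
#' Each pixel's decay is replaced, per time sample, by the mean over its
#' `order` x `order` spatial neighbourhood (order 5 by default), increasing
#' the per-pixel SNR.  At image borders the mean runs over the in-bounds
#' neighbours only, so border decays are not darkened.
#'
#' @param x A `maflim_image`, or a `rows x cols x T` numeric array.
#' @param order Odd window size (default 5).
#' @return Same type as the input, spatially averaged.
#' @export
spatial_average <- function(x, order = 5) {
  if (order < 1 || order %% 2 == 0) stop("averaging order must be odd and >= 1")
  r <- (order - 1L) / 2L
  avg_arr <- function(arr) {
    if (r == 0) return(arr)
    out <- arr
    for (t in seq_len(dim(arr)[3])) out[, , t] <- box_mean(arr[, , t], r)
    out
  }
  if (inherits(x, "maflim_image")) {
    x$channels <- lapply(x$channels, avg_arr)
    x
  } else {
    avg_arr(x)
  }
}

#' Per-pixel SNR estimate in dB
#'
#' SNR = 20 log10(peak of the offset-subtracted decay / noise standard
#' deviation), computed on the channel with the largest peak.  The noise
#' level is estimated robustly from the decay's second differences
#' (`1.4826 * median(|d2|) / sqrt(6)`), which uses the full record and is
#' insensitive to the smooth decay shape and to the few high-curvature
#' samples around the excitation pulse.
#'
#' @param image A `maflim_image`.
#' @param n_edge Edge samples used for offset subtraction (default 5).
#' @return `rows x cols` matrix of SNR values in dB (`-Inf` where the decay
#'   has no positive peak, `Inf` where the record is noiseless).
#' @export
estimate_snr_db <- function(image, n_edge = 5) {
  peak_best <- NULL
  sd_best <- NULL
  for (ch in 1:3) {
    y <- subtract_offset(decay_matrix(image$channels[[ch]]), n_edge)
    n <- nrow(y)
    pk <- apply(y, 2, max)
    d2 <- y[3:n, , drop = FALSE] - 2 * y[2:(n - 1), , drop = FALSE] +
      y[1:(n - 2), , drop = FALSE]
    ns <- 1.4826 * apply(abs(d2), 2, stats::median) / sqrt(6)
    if (is.null(peak_best)) {
      peak_best <- pk
      sd_best <- ns
    } else {
      take <- pk > peak_best
      peak_best[take] <- pk[take]
      sd_best[take] <- ns[take]
    }
  }
  snr <- ifelse(peak_best <= 0, -Inf,
                ifelse(sd_best == 0, Inf, 20 * log10(peak_best / sd_best)))
  matrix(snr, image$config$rows, image$config$cols)
}

#' Validity mask from saturation and SNR thresholds
#'
#' A pixel is invalid if any sample in any channel reaches the ADC full-scale
#' level, or if its estimated SNR falls below `snr_db_min` (15 dB by default).
#'
#' @param image A `maflim_image` (raw, before offset subtraction).
#' @param snr_db_min Minimum acceptable SNR in dB.
#' @param adc_max ADC full-scale level (defaults to the image's declared one).
#' @param n_edge Passed to [estimate_snr_db()].
#' @return `rows x cols` logical matrix, `TRUE` for valid pixels.
#' @export
mask_pixels <- function(image, snr_db_min = 15, adc_max = image$adc_max,
                        n_edge = 5) {
  npix <- image$config$rows * image$config$cols
  saturated <- rep(FALSE, npix)
  if (is.finite(adc_max)) {
    for (ch in 1:3) {
      y <- decay_matrix(image$channels[[ch]])
      saturated <- saturated | apply(y, 2, max) >= adc_max
    }
  }
  snr <- estimate_snr_db(image, n_edge)
  matrix(!saturated, image$config$rows, image$config$cols) & (snr >= snr_db_min)
}

#' Zero-pad channels to a common length and concatenate
#'
#' Each channel decay is padded with zeros at its tail up to the longest
#' channel length M, then the three channels are concatenated in band order
#' (390, 452, 500 nm), producing a 3*M-sample signal per pixel.  Operating on
#' the concatenated signal lets clustering and frequency-domain deconvolution
#' use all three bands at once.
#'
#' @param channels List of three per-channel decays: `rows x cols x T_ch`
#'   arrays, or `T_ch x npix` matrices, or plain vectors.
#' @return Concatenated signal in the corresponding shape
#'   (`rows x cols x 3M` array, `3M x npix` matrix, or length-3M vector).
#' @export
pad_and_concatenate <- function(channels) {
  stopifnot(length(channels) == 3L)
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1)
    else if (length(dim(x)) == 3) decay_matrix(x)
    else x
  }
  mats <- lapply(channels, as_mat)
  M <- max(vapply(mats, nrow, 1L))
  padded <- lapply(mats, function(m) {
    rbind(m, matrix(0, M - nrow(m), ncol(m)))
  })
  out <- do.call(rbind, padded)
  x1 <- channels[[1]]
  if (is.null(dim(x1))) drop(out)
  else if (length(dim(x1)) == 3) decay_array(out, dim(x1)[1], dim(x1)[2])
  else out
}

#' Slice a concatenated signal back into its three channel segments
#'
#' @param concat Length-3M vector or `3M x npix` matrix.
#' @param M Per-channel segment length.
#' @return List of three segments (each padded to length M).
#' @export
split_concat <- function(concat, M) {
  m <- if (is.null(dim(concat))) matrix(concat, ncol = 1) else concat
  stopifnot(nrow(m) == 3 * M)
  out <- lapply(0:2, function(k) m[(k * M + 1):((k + 1) * M), , drop = FALSE])
  if (is.null(dim(concat))) lapply(out, drop) else out
}

#' Two-region K-means clustering of concatenated decays
#'
#' Groups the valid pixels of an image into two regions (lesion / surround,
#' in arbitrary label order) by K-means with k = 2 on the concatenated
#' three-channel decay used as the per-pixel feature vector.  Downstream
#' global features are invariant to the arbitrary labelling.
#'
#' @param concat `3M x npix` matrix (or `rows x cols x 3M` array) of
#'   concatenated, preprocessed decays.
#' @param valid Logical validity mask (`rows x cols` matrix or length-npix
#'   vector).
#' @param seed Integer seed for the K-means restarts.
#' @param nstart Number of random restarts (default 10).
#' @return An object of class `region_masks`: logical `valid`, `region1`,
#'   `region2` of the input's pixel shape; regions partition the valid mask.
#' @export
cluster_regions <- function(concat, valid, seed = 1L, nstart = 10) {
  shape <- if (is.matrix(valid)) dim(valid) else NULL
  vvalid <- as.vector(valid)
  cmat <- if (length(dim(concat)) == 3) decay_matrix(concat) else concat
  if (ncol(cmat) != length(vvalid))
    stop("concat and valid mask disagree on pixel count")
  if (sum(vvalid) < 2) stop("need at least 2 valid pixels to cluster")
  feats <- t(cmat[, vvalid, drop = FALSE])
  km <- with_seed(seed, tryCatch(
    stats::kmeans(feats, centers = 2, nstart = nstart),
    error = function(e) stop("degenerate clustering: ", conditionMessage(e),
                             call. = FALSE)))
  if (any(km$size == 0) || length(unique(km$cluster)) < 2)
    stop("degenerate clustering: all valid pixels fell in one cluster; ",
         "the image may lack two distinguishable regions")
  r1 <- r2 <- rep(FALSE, length(vvalid))
  r1[vvalid] <- km$cluster == 1
  r2[vvalid] <- km$cluster == 2
  reshape <- function(v) if (is.null(shape)) v else matrix(v, shape[1], shape[2])
  structure(list(valid = reshape(vvalid), region1 = reshape(r1),
                 region2 = reshape(r2)),
            class = "region_masks")
}

#' Full preprocessing chain for one maFLIM image
#'
#' Applies, in order: offset subtraction, spatial averaging, SNR/saturation
#' masking (saturation detected on the raw decays, SNR estimated on the raw
#' offset-subtracted decays), tail zero-padding with channel concatenation,
#' and two-region K-means clustering of the valid concatenated decays.
#'
#' @param image A `maflim_image`.
#' @param n_edge Edge samples for the offset line (default 5).
#' @param avg_order Spatial averaging order (default 5).
#' @param snr_db_min SNR masking threshold in dB (default 15).
#' @param adc_max ADC full scale (defaults to the image's declared level).
#' @param seed Seed for the clustering restarts.
#' @return An object of class `maflim_preprocessed`: per-channel processed
#'   decay matrices (`$channels`, time x pixels), the concatenated matrix
#'   (`$concat`, 3M x pixels), `$masks` (a `region_masks`), `$M` and the
#'   configuration.
#' @export
preprocess_image <- function(image, n_edge = 5, avg_order = 5,
                             snr_db_min = 15, adc_max = image$adc_max,
                             seed = 1L) {
  stopifnot(inherits(image, "maflim_image"))
  valid <- mask_pixels(image, snr_db_min, adc_max, n_edge = n_edge)
  proc <- lapply(image$channels, function(arr) {
    sub <- subtract_offset(decay_matrix(arr), n_edge)
    avg <- spatial_average(decay_array(sub, dim(arr)[1], dim(arr)[2]), avg_order)
    decay_matrix(avg)
  })
  concat <- pad_and_concatenate(proc)
  M <- max(vapply(proc, nrow, 1L))
  masks <- cluster_regions(concat, valid, seed = seed)
  structure(list(config = image$config, channels = proc, concat = concat,
                 masks = masks, M = M, truth = image$truth),
            class = "maflim_preprocessed")
}
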