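# Internal spectral machinery.
#
# All per-frame spectral quantities are computed from a single Hann window
# (default 1024 samples) centered in each 50 ms frame. Frames are
# noise-like, so one centered window estimates the frame spectrum well at a
# fraction of the cost of transforming all 2205 samples; pairs of real
# frames are packed into complex columns so each FFT does two frames.

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# real-input FFT power of each column of X (L x m) -> (L/2 + 1) x m
rfft_power <- function(X) {
  Z <- mvfft(X)
  nb <- nrow(X) %/% 2L + 1L
  Zk <- Z[seq_len(nb), , drop = FALSE]
  Re(Zk)^2 + Im(Zk)^2
}

# Cached analysis geometry for a given window length.
spectral_env <- new.env(parent = emptyenv())

spectral_setup <- function(window = 1024L) {
  key <- as.character(window)
  if (!is.null(spectral_env[[key]])) return(spectral_env[[key]])
  L <- as.integer(window)
  if (L > ACU_FRAME) abort("analysis window cannot exceed the 2205-sample frame")
  nb <- L %/% 2L + 1L
  freqs <- (seq_len(nb) - 1L) * ACU_RATE / L
  w <- hann_window(L)
  off <- (ACU_FRAME - L) %/% 2L
  rows <- off + seq_len(L)

  # 4 broad band-energy ratio bands (Hz)
  band_edges <- c(50, 300, 1000, 2000, 8000)
  band_mat <- t(vapply(seq_len(4), function(i) {
    as.numeric(freqs >= band_edges[i] & freqs < band_edges[i + 1])
  }, numeric(nb)))

  # 24 log-spaced bands (50 Hz - 10 kHz) for cepstral coefficients
  ncep_bands <- 24L
  edges <- exp(seq(log(50), log(10000), length.out = ncep_bands + 1L))
  cep_bands <- t(vapply(seq_len(ncep_bands), function(i) {
    as.numeric(freqs >= edges[i] & freqs < edges[i + 1])
  }, numeric(nb)))
  # DCT-II basis, coefficients 1..8 (DC excluded)
  dct <- t(vapply(seq_len(8), function(k) {
    cos(pi * k * (seq_len(ncep_bands) - 0.5) / ncep_bands)
  }, numeric(ncep_bands)))

  # 64 log-spaced bands + lower-triangular cumulator for spectral roll-off
  nro <- 64L
  ro_edges <- exp(seq(log(30), log(ACU_RATE / 2), length.out = nro + 1L))
  ro_bands <- t(vapply(seq_len(nro), function(i) {
    as.numeric(freqs >= ro_edges[i] & freqs < ro_edges[i + 1])
  }, numeric(nb)))
  ro_upper <- ro_edges[-1]
  ro_cum <- matrix(0, nro, nro)
  ro_cum[lower.tri(ro_cum, diag = TRUE)] <- 1

  env <- list(
    L = L, nb = nb, freqs = freqs, w = w, rows = rows, wsq = sum(w^2),
    band_mat = band_mat, cep_bands = cep_bands, dct = dct,
    ro_bands = ro_bands, ro_cum = ro_cum, ro_upper = ro_upper
  )
  spectral_env[[key]] <- env
  env
}

# frames (2205 x m) -> list(P = power spectra (nb x m), win = windowed rows)
epoch_spectra <- function(frames, window = 1024L) {
  sp <- spectral_setup(window)
  Fw <- frames[sp$rows, , drop = FALSE] * sp$w
  list(P = rfft_power(Fw), win = frames[sp$rows, , drop = FALSE], sp = sp)
}

# mean-square amplitude (power) per frame from half-spectrum power
frame_power_from_spectra <- function(P, sp) {
  tot <- 2 * colSums(P) - P[1, ] - P[nrow(P), ]
  pmax(tot, 0) / (sp$L * sp$wsq)
}

power_to_db <- function(p, floor_db = ACU_DB_FLOOR) {
  pmax(10 * log10(p + 1e-12), floor_db)
}
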