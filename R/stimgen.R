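#' Vowel continuum specification
#'
#' Describes a two-formant-endpoint vowel continuum in which only the first
#' formant (F1) varies, in exactly equidistant steps, while the fundamental
#' (F0) and the higher formants (F2, F3) are shared by all tokens. The
#' defaults give a 7-step /u/-/a/ continuum: F1 from 430 to 730 Hz, F0 100 Hz,
#' F2 1090 Hz, F3 2350 Hz, 100 ms tokens with 10 ms raised-cosine on/off
#' ramps, sampled at 48828 Hz.
#'
#' @param n_steps number of continuum tokens (>= 2).
#' @param f1_start,f1_end F1 of the first and last token, Hz (`f1_start <
#'   f1_end`).
#' @param f0 fundamental frequency, Hz.
#' @param f2,f3 second and third formant frequencies, Hz.
#' @param duration_ms token duration, ms.
#' @param ramp_ms onset/offset ramp duration, ms (`2 * ramp_ms <=
#'   duration_ms`).
#' @param sample_rate sampling rate, Hz.
#' @param rms_target linear RMS amplitude after normalization, in (0, 1].
#' @param bandwidths formant bandwidths (B1, B2, B3), Hz; Klatt-style
#'   defaults.
#' @return an object of class `continuum_spec`.
#' @export
#' @examples
#' spec <- continuum_spec()
#' token_f1(spec, 4) # 580 Hz
continuum_spec <- function(n_steps = 7L, f1_start = 430, f1_end = 730,
                           f0 = 100, f2 = 1090, f3 = 2350,
                           duration_ms = 100, ramp_ms = 10,
                           sample_rate = 48828, rms_target = 0.1,
                           bandwidths = c(60, 90, 150)) {
  spec <- structure(
    list(n_steps = as.integer(n_steps), f1_start = f1_start, f1_end = f1_end,
         f0 = f0, f2 = f2, f3 = f3, duration_ms = duration_ms,
         ramp_ms = ramp_ms, sample_rate = sample_rate,
         rms_target = rms_target, bandwidths = bandwidths),
    class = "continuum_spec")
  validate_continuum_spec(spec)
  spec
}

validate_continuum_spec <- function(spec) {
  if (spec$n_steps < 2L) stop("continuum_spec: n_steps must be >= 2")
  if (!(spec$f1_start < spec$f1_end))
    stop("continuum_spec: f1_start must be < f1_end")
  if (2 * spec$ramp_ms > spec$duration_ms)
    stop("continuum_spec: 2 * ramp_ms exceeds duration_ms")
  if (spec$rms_target <= 0 || spec$rms_target > 1)
    stop("continuum_spec: rms_target must lie in (0, 1]")
  invisible(spec)
}

#' @export
print.continuum_spec <- function(x, ...) {
  cat(sprintf("%d-step vowel continuum: F1 %g-%g Hz, F0 %g Hz, F2 %g Hz, F3 %g Hz\n",
              x$n_steps, x$f1_start, x$f1_end, x$f0, x$f2, x$f3))
  cat(sprintf("  %g ms tokens (%g ms ramps), fs %g Hz, RMS %g\n",
              x$duration_ms, x$ramp_ms, x$sample_rate, x$rms_target))
  invisible(x)
}

#' First-formant frequency of a continuum token
#'
#' Tokens are spaced on an exactly equidistant F1 grid:
#' `f1_start + (k - 1) * (f1_end - f1_start) / (n_steps - 1)`.
#'
#' @param spec a [continuum_spec()].
#' @param token_index token number in `1..n_steps`.
#' @return F1 in Hz.
#' @export
token_f1 <- function(spec, token_index) {
  check_token_index(spec, token_index)
  spec$f1_start + (token_index - 1) * (spec$f1_end - spec$f1_start) /
    (spec$n_steps - 1)
}

check_token_index <- function(spec, token_index) {
  if (any(token_index < 1 | token_index > spec$n_steps |
            token_index != round(token_index)))
    stop(sprintf("token_index must be an integer in 1..%d", spec$n_steps))
  invisible(TRUE)
}

# ---- waveform container -----------------------------------------------------

#' Construct a waveform
#'
#' A minimal mono audio container: a numeric sample vector plus its sampling
#' rate.
#'
#' @param samples numeric vector of amplitudes (nominally in `[-1, 1]`).
#' @param sample_rate sampling rate, Hz.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f ms), RMS %.4g\n",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate, rms(x)))
  invisible(x)
}

#' Root-mean-square amplitude
#' @param w a [waveform()] or numeric vector.
#' @return RMS as a scalar.
#' @export
rms <- function(w) {
  s <- if (inherits(w, "waveform")) w$samples else w
  sqrt(mean(s^2))
}

#' Normalize a waveform to a target RMS
#'
#' Scales the samples so that the root-mean-square amplitude equals
#' `target`. Idempotent: normalizing an already-normalized waveform is a
#' no-op up to floating-point roundoff.
#'
#' @param w a [waveform()].
#' @param target desired RMS (linear amplitude).
#' @return the rescaled waveform.
#' @export
rms_normalize <- function(w, target) {
  r <- rms(w)
  if (r == 0) stop("cannot RMS-normalize an all-zero waveform")
  waveform(w$samples * (target / r), w$sample_rate)
}

# single Klatt-style digital resonator (cascade element)
klatt_resonator <- function(x, f, bw, fs) {
  C <- -exp(-2 * pi * bw / fs)
  B <- 2 * exp(-pi * bw / fs) * cos(2 * pi * f / fs)
  A <- 1 - B - C
  as.numeric(stats::filter(A * x, c(B, C), method = "recursive"))
}

#' Synthesize one continuum token
#'
#' Cascade formant synthesis: an impulse-train glottal source at F0 is passed
#' through three cascaded second-order resonators at the token's F1 and the
#' shared F2/F3 (bandwidths from the spec), then shaped with raised-cosine
#' onset/offset ramps and RMS-normalized. Impulse positions use cumulative
#' rounding so the long-term F0 is exact even when the period is a
#' non-integer number of samples.
#'
#' @param spec a [continuum_spec()].
#' @param token_index token number in `1..n_steps`.
#' @return a [waveform()] of `round(duration_ms * sample_rate / 1000)`
#'   samples.
#' @export
#' @examples
#' w <- synthesize_vowel(continuum_spec(), 1)
#' length(w$samples) # 4883
synthesize_vowel <- function(spec, token_index) {
  validate_continuum_spec(spec)
  check_token_index(spec, token_index)
  fs <- spec$sample_rate
  n <- round(spec$duration_ms * fs / 1000)
  src <- numeric(n)
  k <- 0:ceiling((n - 1) * spec$f0 / fs)
  pos <- round(k * fs / spec$f0) + 1
  src[pos[pos <= n]] <- 1
  y <- klatt_resonator(src, token_f1(spec, token_index), spec$bandwidths[1], fs)
  y <- klatt_resonator(y, spec$f2, spec$bandwidths[2], fs)
  y <- klatt_resonator(y, spec$f3, spec$bandwidths[3], fs)
  nr <- round(spec$ramp_ms * fs / 1000)
  if (nr > 1) {
    ramp <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / (nr - 1)))
    y[1:nr] <- y[1:nr] * ramp
    y[(n - nr + 1):n] <- y[(n - nr + 1):n] * rev(ramp)
  }
  rms_normalize(waveform(y, fs), spec$rms_target)
}

#' Synthesize the full continuum
#'
#' @param spec a [continuum_spec()].
#' @return a list of [waveform()]s, one per token.
#' @export
synthesize_continuum <- function(spec) {
  lapply(seq_len(spec$n_steps), function(k) synthesize_vowel(spec, k))
}

# ---- spectral estimation ----------------------------------------------------

#' Welch power spectral density estimate
#'
#' Hann-windowed averaged periodogram with 50% segment overlap; one-sided.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate, Hz.
#' @param nfft segment length (samples).
#' @return a list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nfft = 4096) {
  if (length(x) < nfft) nfft <- 2^floor(log2(length(x)))
  hop <- nfft %/% 2
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / (nfft - 1)))
  u <- sum(win^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * win
    X <- fft(seg)[1:(nfft %/% 2 + 1)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * u * fs)
  psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]
  list(freq = (0:(nfft %/% 2)) * fs / nfft, psd = psd)
}

#' Smooth a PSD into fractional-octave bands
#'
#' Averages power over 1/`frac`-octave bands between `f_lo` and `f_hi`; used
#' to compare noise spectra against a target long-term power spectrum.
#'
#' @param freq,psd frequency grid (Hz) and PSD values.
#' @param f_lo,f_hi band-center limits, Hz.
#' @param frac bands per octave (3 = third-octave).
#' @return data.frame with `center` (Hz) and `level_db`.
#' @export
band_levels <- function(freq, psd, f_lo = 100, f_hi = 8000, frac = 3) {
  centers <- f_lo * 2^(seq(0, log2(f_hi / f_lo), by = 1 / frac))
  half <- 2^(1 / (2 * frac))
  lev <- vapply(centers, function(fc) {
    sel <- freq >= fc / half & freq <= fc * half
    10 * log10(mean(psd[sel]))
  }, numeric(1))
  data.frame(center = centers, level_db = lev)
}

#' Build speech-shaped (LTPS) masking noise
#'
#' Generates Gaussian noise whose spectrum matches the long-term power
#' spectrum of a vowel set: seeded white noise is shaped in the frequency
#' domain by the square root of the Welch PSD (4096-point segments, 50%
#' overlap) of the concatenated vowels, then RMS-normalized to the mean vowel
#' RMS. Deterministic given the seed.
#'
#' @param vowels list of [waveform()]s sharing one sample rate.
#' @param duration_ms noise duration, ms.
#' @param seed integer seed.
#' @return a [waveform()].
#' @export
build_ltps_noise <- function(vowels, duration_ms, seed) {
  if (length(vowels) == 0) stop("build_ltps_noise: empty vowel list")
  fs <- vowels[[1]]$sample_rate
  if (!all(vapply(vowels, function(v) v$sample_rate, numeric(1)) == fs))
    stop("build_ltps_noise: vowels have mixed sample rates")
  concat <- unlist(lapply(vowels, `[[`, "samples"))
  target <- welch_psd(concat, fs)
  n <- round(duration_ms * fs / 1000)
  white <- with_seed(seed, rnorm(n))
  nf <- n %/% 2 + 1
  fgrid <- (0:(nf - 1)) * fs / n
  # interpolate the PSD in the log domain: harmonic line skirts must decay
  # geometrically into the inter-harmonic valleys, not linearly
  floor_psd <- max(target$psd) * 1e-30
  log_mag <- approx(target$freq, 0.5 * log(pmax(target$psd, floor_psd)),
                    xout = fgrid, rule = 2)$y
  mag <- exp(log_mag)
  X <- fft(white)
  shape <- c(mag, rev(mag[2:(n - nf + 1)]))
  y <- Re(fft(X * shape, inverse = TRUE)) / n
  target_rms <- mean(vapply(vowels, rms, numeric(1)))
  rms_normalize(waveform(y, fs), target_rms)
}

#' Mix speech into noise at an exact SNR
#'
#' Rescales a masker segment so that `20 * log10(rms(speech) / rms(noise))`
#' equals `snr_db` exactly; the speech is left untouched. The masker is
#' treated as continuous: `offset` selects which segment backs the speech.
#' If the mixture exceeds full scale it is rescaled globally (which preserves
#' the SNR); the applied factor is recorded in attribute `"clip_scale"`.
#'
#' @param speech,noise [waveform()]s at the same sample rate; the noise must
#'   be at least as long as the speech.
#' @param snr_db target signal-to-noise ratio, dB.
#' @param offset 0-based sample offset of the masker segment.
#' @return a [waveform()] of the same length as `speech`, with attributes
#'   `"snr_db"`, `"noise_scale"` and `"clip_scale"`.
#' @export
mix_at_snr <- function(speech, noise, snr_db, offset = 0) {
  if (speech$sample_rate != noise$sample_rate)
    stop("mix_at_snr: sample rates differ")
  ns <- length(speech$samples)
  if (length(noise$samples) < ns + offset)
    stop("mix_at_snr: noise shorter than speech (plus offset)")
  seg <- noise$samples[(offset + 1):(offset + ns)]
  rs <- rms(speech$samples)
  rn <- rms(seg)
  if (rs == 0 || rn == 0) stop("mix_at_snr: zero-energy input")
  scale <- rs / (rn * 10^(snr_db / 20))
  mix <- speech$samples + seg * scale
  clip_scale <- 1
  peak <- max(abs(mix))
  if (peak > 1) {
    clip_scale <- 1 / peak
    mix <- mix * clip_scale
  }
  out <- waveform(mix, speech$sample_rate)
  attr(out, "snr_db") <- snr_db
  attr(out, "noise_scale") <- scale
  attr(out, "clip_scale") <- clip_scale
  out
}

#' Measure the SNR realized by [mix_at_snr()] components
#'
#' @param speech speech [waveform()].
#' @param noise_segment the scaled masker segment (same length).
#' @return SNR in dB.
#' @export
measure_snr <- function(speech, noise_segment) {
  20 * log10(rms(speech) / rms(noise_segment))
}

# ---- acoustic verification --------------------------------------------------

#' Estimate formant frequencies by linear prediction
#'
#' Covariance-method LPC on the steady-state portion of a voiced token (the
#' central region, ramps excluded), with one robustness pass: prediction rows
#' dominated by glottal excitation (the largest residuals) are dropped and
#' the coefficients re-estimated, which removes the bias the excitation
#' impulses induce on the pole locations. Formants are the angles of the
#' complex prediction-polynomial roots with bandwidth below `bw_max`.
#'
#' @param w a [waveform()].
#' @param n_formants number of formants to return.
#' @param order LPC order (2 poles per expected resonance).
#' @param steady fraction `[lo, hi]` of the token analyzed.
#' @param trim fraction of highest-residual rows dropped in the second pass.
#' @param f_min,f_max,bw_max root-acceptance limits, Hz.
#' @return numeric vector of formant frequencies, ascending, Hz (padded with
#'   `NA` if fewer than `n_formants` are found).
#' @export
#' @examples
#' lpc_formants(synthesize_vowel(continuum_spec(), 1))[1] # ~430
lpc_formants <- function(w, n_formants = 3, order = 2 * n_formants,
                         steady = c(0.15, 0.85), trim = 0.02,
                         f_min = 80, f_max = 3000, bw_max = 500) {
  x <- w$samples
  n <- length(x)
  x <- x[max(1, round(steady[1] * n)):round(steady[2] * n)]
  m <- length(x)
  if (m <= 4 * order) stop("lpc_formants: waveform too short")
  X <- vapply(seq_len(order), function(k) x[(order + 1 - k):(m - k)],
              numeric(m - order))
  y <- x[(order + 1):m]
  a <- qr.solve(X, y)
  res <- abs(y - X %*% a)
  keep <- res <= quantile(res, 1 - trim)
  a <- qr.solve(X[keep, , drop = FALSE], y[keep])
  rt <- polyroot(c(1, -a))
  fs <- w$sample_rate
  f <- Arg(rt) * fs / (2 * pi)
  bw <- -log(pmin(Mod(rt), 1 - 1e-12)) * fs / pi
  f <- sort(f[f > f_min & f < f_max & bw < bw_max])
  out <- rep(NA_real_, n_formants)
  out[seq_len(min(n_formants, length(f)))] <- f[seq_len(min(n_formants, length(f)))]
  out
}

#' Estimate the fundamental frequency by autocorrelation
#'
#' Peak-picking on the raw autocorrelation of the central portion of the
#' token, with parabolic interpolation of the peak lag.
#'
#' @param w a [waveform()].
#' @param f_min,f_max search range, Hz.
#' @param central fraction of the waveform (centered) analyzed.
#' @return estimated F0 in Hz.
#' @export
estimate_f0 <- function(w, f_min = 50, f_max = 300, central = 0.8) {
  x <- w$samples
  n <- length(x)
  drop <- floor(n * (1 - central) / 2)
  x <- x[(drop + 1):(n - drop)]
  fs <- w$sample_rate
  lags <- floor(fs / f_max):ceiling(fs / f_min)
  m <- length(x)
  ac <- vapply(lags, function(L) sum(x[1:(m - L)] * x[(L + 1):m]), numeric(1))
  i <- which.max(ac)
  d <- 0
  if (i > 1 && i < length(lags)) {
    denom <- ac[i - 1] - 2 * ac[i] + ac[i + 1]
    if (denom != 0) d <- 0.5 * (ac[i - 1] - ac[i + 1]) / denom
  }
  fs / (lags[i] + d)
}

# ---- WAV input/output -------------------------------------------------------

#' Write a waveform as a 32-bit float mono WAV file
#'
#' @param w a [waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  data_bytes <- 4L * n
  fs <- as.integer(round(w$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(4 + 24 + 12 + 8 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("fact", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(w$samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float mono WAV file
#'
#' Companion reader for [write_wav()]; parses RIFF chunks and returns the
#' sample data.
#'
#' @param path file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("read_wav: not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("read_wav: not a WAVE file")
  fs <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8)
    } else if (id == "data") {
      if (is.null(fmt) || fmt != 3L)
        stop("read_wav: only IEEE float WAV is supported")
      samples <- readBin(con, numeric(), n = sz %/% 4, size = 4,
                         endian = "little")
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(samples)) stop("read_wav: no data chunk found")
  waveform(samples, fs)
}

#' Synthesize and write the full stimulus set
#'
#' Writes `tok01.wav ... tokNN.wav` and `ltps_noise.wav` (float32 mono) plus
#' a JSON sidecar recording the continuum parameters, noise seed and file
#' names.
#'
#' @param spec a [continuum_spec()].
#' @param out_dir output directory (created if needed).
#' @param noise_duration_ms duration of the masker file, ms.
#' @param seed seed for the noise generator.
#' @return invisibly, a list with the vowel waveforms, the noise waveform and
#'   the sidecar path.
#' @export
write_stimulus_set <- function(spec, out_dir, noise_duration_ms = 5000,
                               seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vowels <- synthesize_continuum(spec)
  files <- sprintf("tok%02d.wav", seq_len(spec$n_steps))
  for (k in seq_len(spec$n_steps))
    write_wav(vowels[[k]], file.path(out_dir, files[k]))
  noise <- build_ltps_noise(vowels, noise_duration_ms, seed)
  write_wav(noise, file.path(out_dir, "ltps_noise.wav"))
  sidecar <- file.path(out_dir, "stimuli.json")
  meta <- c(unclass(spec),
            list(noise_duration_ms = noise_duration_ms, noise_seed = seed,
                 token_files = files, noise_file = "ltps_noise.wav",
                 token_f1 = vapply(seq_len(spec$n_steps),
                                   function(k) token_f1(spec, k), numeric(1))))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(vowels = vowels, noise = noise, sidecar = sidecar))
}
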