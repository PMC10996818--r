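#' Welch-style averaged periodogram
#'
#' One-sided power spectral density estimated by averaging modified
#' periodograms over 50%-overlapping rectangular-window segments. The DC bin
#' is excluded. Used by the channel quality-control rule: heavy averaging
#' makes the white-noise sampling distribution of the PSD tight, so a flat
#' spectrum yields a small quartile coefficient of dispersion, while any
#' channel with genuine spectral structure keeps a dispersed PSD.
#'
#' @param x numeric time series.
#' @param fs sampling rate (Hz).
#' @param segment_length samples per segment; shorter segments mean heavier
#'   averaging (tighter white-noise PSD distribution) at coarser frequency
#'   resolution.
#' @return data.frame with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, segment_length = 24) {
  n <- length(x)
  L <- min(segment_length, 2^floor(log2(n)))
  .assert(L >= 8, "series too short for spectral estimation")
  step <- L %/% 2
  starts <- seq(1, n - L + 1, by = step)
  acc <- numeric(L %/% 2)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- seg - mean(seg)
    p <- Mod(fft(seg))^2 / (L * fs)
    acc <- acc + p[2:(L %/% 2 + 1)]  # one-sided, DC excluded
  }
  data.frame(freq = (1:(L %/% 2)) * fs / L, psd = acc / length(starts))
}

#' Quartile coefficient of dispersion of a channel's power spectrum
#'
#' `QCoD = (Q3 - Q1) / (Q3 + Q1)` over the one-sided PSD values. Values below
#' about 0.1 indicate a spectrum as flat as white noise.
#'
#' @param x numeric time series.
#' @param fs sampling rate (Hz).
#' @param segment_length see [welch_psd()].
#' @return scalar QCoD.
#' @export
spectral_qcod <- function(x, fs, segment_length = 24) {
  p <- welch_psd(x, fs, segment_length)$psd
  q <- quantile(p, c(0.25, 0.75), names = FALSE, type = 7)
  (q[2] - q[1]) / (q[2] + q[1])
}

# longest run (in samples) at/above a level
.max_run <- function(x, level) {
  r <- rle(x >= level)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Channel quality control for raw fNIRS intensities
#'
#' Flags a channel unusable if (a) detector saturation persists for more than
#' `max_saturation_s` seconds (any contiguous run at/above `saturation_level`
#' at either wavelength), or (b) its power spectrum resembles white noise
#' (QCoD of the PSD below `qcod_threshold` at either wavelength). QC only
#' flags; it never modifies data.
#'
#' @param raw a `raw_intensity` object (see [simulate_raw_intensity()]).
#' @param saturation_level intensity treated as saturated; defaults to 0.99 of
#'   the recording's ADC ceiling.
#' @param max_saturation_s permissible saturation duration (seconds); the rule
#'   is "more than", so a run of exactly this length is still usable.
#' @param qcod_threshold white-noise cutoff on the spectral QCoD.
#' @return data.frame (class `"channel_qc_report"`): `channel`, `usable`,
#'   `reason` (`ok`/`saturation`/`white_noise`), `qcod`,
#'   `max_saturation_run_s`.
#' @export
qc_channels <- function(raw, saturation_level = NULL, max_saturation_s = 2,
                        qcod_threshold = 0.1) {
  .assert(inherits(raw, "raw_intensity"), "raw must be a raw_intensity")
  .assert(raw$sampling_rate > 0, "sampling_rate must be positive")
  if (is.null(saturation_level)) saturation_level <- 0.99 * raw$adc_ceiling
  nch <- dim(raw$intensity)[2]
  out <- data.frame(channel = seq_len(nch), usable = TRUE, reason = "ok",
                    qcod = NA_real_, max_saturation_run_s = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in seq_len(nch)) {
    runs <- vapply(1:2, function(w)
      .max_run(raw$intensity[w, ch, ], saturation_level), numeric(1))
    qcods <- vapply(1:2, function(w)
      spectral_qcod(raw$intensity[w, ch, ], raw$sampling_rate), numeric(1))
    out$max_saturation_run_s[ch] <- max(runs) / raw$sampling_rate
    out$qcod[ch] <- min(qcods)
    if (out$max_saturation_run_s[ch] > max_saturation_s) {
      out$usable[ch] <- FALSE
      out$reason[ch] <- "saturation"
    } else if (out$qcod[ch] < qcod_threshold) {
      out$usable[ch] <- FALSE
      out$reason[ch] <- "white_noise"
    }
  }
  class(out) <- c("channel_qc_report", "data.frame")
  out
}

#' Trim and concatenate recording segments by condition
#'
#' Extracts the samples covered by each event of the requested condition (in
#' event order) and concatenates them, e.g. to build one continuous political
#' or neutral-video time course per recording.
#'
#' @param recording channels x time numeric matrix.
#' @param events data.frame with `onset_s`, `duration_s`, `condition`.
#' @param condition the condition to keep.
#' @param sampling_rate Hz.
#' @return channels x time matrix of the concatenated segments.
#' @export
trim_concatenate <- function(recording, events, condition, sampling_rate) {
  if (is.vector(recording)) recording <- matrix(recording, nrow = 1)
  ev <- events[events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events of condition '", condition, "'", call. = FALSE)
  segs <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- round(ev$onset_s[i] * sampling_rate) + 1
    i1 <- i0 + round(ev$duration_s[i] * sampling_rate) - 1
    if (i0 < 1 || i1 > ncol(recording)) {
      stop("event ", i, " of condition '", condition,
           "' is outside the recording", call. = FALSE)
    }
    recording[, i0:i1, drop = FALSE]
  })
  do.call(cbind, segs)
}

#' Zero-phase bandpass filter
#'
#' Order-3 Butterworth high-pass and low-pass stages applied forward and
#' backward ([signal::filtfilt()]), so the filter introduces no group delay.
#' Running the two stages in cascade keeps the recursion numerically stable at
#' the very low high-pass edge relative to the sampling rate.
#'
#' @param ts numeric vector or channels x time matrix.
#' @param low,high band edges in Hz (defaults 0.005-0.5, the hemodynamic band).
#' @param sampling_rate Hz.
#' @param order filter order per stage.
#' @return filtered series, same shape as `ts`.
#' @export
bandpass <- function(ts, low = 0.005, high = 0.5, sampling_rate, order = 3) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("invalid band: need 0 < low < high < sampling_rate/2", call. = FALSE)
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  # demeaning first removes the DC component exactly and keeps the recursive
  # high-pass stage free of large edge transients
  f1 <- function(x) signal::filtfilt(lp, signal::filtfilt(hp, x - mean(x)))
  if (is.matrix(ts)) t(apply(ts, 1, f1)) else f1(ts)
}

#' PCA-based motion-artifact correction
#'
#' Removes leading principal components of the channels x time matrix, in
#' order of explained variance, until the removed set first reaches
#' `variance_fraction` of total variance. Motion artifacts load on components
#' shared across channels, so truncating the dominant components suppresses
#' them. `variance_fraction = 0` removes nothing; at most `n_channels - 1`
#' components are removed.
#'
#' @param ts channels x time matrix.
#' @param variance_fraction in `[0, 1)`.
#' @return corrected matrix, same shape.
#' @export
pca_motion_correct <- function(ts, variance_fraction = 0.8) {
  .assert(is.matrix(ts), "ts must be a channels x time matrix")
  .assert(variance_fraction >= 0 && variance_fraction < 1,
          "variance_fraction must be in [0, 1)")
  if (nrow(ts) < 2) {
    warning("single channel: PCA correction is a no-op")
    return(ts)
  }
  if (variance_fraction == 0) return(ts)
  mu <- rowMeans(ts)
  X <- ts - mu
  sv <- svd(X)
  varexp <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(varexp) >= variance_fraction)[1]
  if (is.na(k)) k <- length(varexp)
  k <- min(k, nrow(ts) - 1)
  recon <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  ts - recon
}

#' Modified Beer-Lambert Law inversion
#'
#' Converts dual-wavelength light intensities to haemoglobin concentration
#' changes relative to baseline. Per channel and time point,
#' `dOD(lambda, t) = -log10(I(lambda, t) / I0(lambda))` and the 2 x 2 linear
#' system `dOD(lambda) / (d * DPF(lambda)) = eps(lambda, ) %*% c(dHbO, dHbR)`
#' is solved. The baseline `I0` defaults to the temporal *geometric* mean of
#' each channel/wavelength over positive samples — the mean in optical-
#' density units, which recovers the true baseline exactly whenever the
#' concentration changes average to zero over the record. Non-positive
#' samples are flagged and returned as `NA`.
#'
#' @param raw a `raw_intensity` object.
#' @param distance source-detector separation (cm).
#' @param dpf differential pathlength factor per wavelength.
#' @param extinction 2 x 2 extinction matrix (wavelength x `HbO`,`HbR`).
#' @param baseline optional wavelength x channel baseline intensity matrix.
#' @return list with `hbo` and `hbr` channels x time matrices.
#' @export
mbll <- function(raw, distance = 3, dpf = c(6, 6),
                 extinction = default_extinction(), baseline = NULL) {
  .assert(inherits(raw, "raw_intensity"), "raw must be a raw_intensity")
  .assert(abs(det(extinction)) > 1e-12, "extinction matrix is singular")
  nch <- dim(raw$intensity)[2]; T <- dim(raw$intensity)[3]
  Einv <- solve(extinction)
  hbo <- matrix(NA_real_, nch, T); hbr <- matrix(NA_real_, nch, T)
  for (ch in seq_len(nch)) {
    od <- matrix(NA_real_, 2, T)
    for (w in 1:2) {
      I <- raw$intensity[w, ch, ]
      ok <- I > 0
      lod <- -log10(I[ok])
      lod0 <- if (is.null(baseline)) mean(lod) else -log10(baseline[w, ch])
      od[w, ok] <- (lod - lod0) / (distance * dpf[w])
    }
    conc <- Einv %*% od
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  list(hbo = hbo, hbr = hbr)
}

#' Standardised total-haemoglobin signal
#'
#' Per-channel z-score of `HbO - HbR`, using the population standard
#' deviation (1/T denominator) so that the squared Euclidean distance between
#' two standardised channels of length T equals `2 T (1 - r)` exactly.
#' Channels whose difference is constant carry no usable signal; they are
#' excluded with a warning.
#'
#' @param hbo,hbr channels x time matrices of equal shape.
#' @return list with `total` (usable channels x time, mean 0, sd 1 per
#'   channel) and `channels` (retained channel indices).
#' @export
total_hb_signal <- function(hbo, hbr) {
  .assert(all(dim(hbo) == dim(hbr)), "hbo/hbr shape mismatch")
  d <- hbo - hbr
  sds <- apply(d, 1, sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < nrow(d)) {
    warning(sprintf("%d degenerate channel(s) with constant HbO - HbR excluded",
                    nrow(d) - length(keep)))
  }
  .assert(length(keep) > 0, "no usable channels: all HbO - HbR are constant")
  total <- t(apply(d[keep, , drop = FALSE], 1, function(x) {
    xc <- x - mean(x)
    xc / sqrt(mean(xc^2))
  }))
  list(total = total, channels = keep)
}

#' Full preprocessing chain for one subject
#'
#' Fixed stage order: trim/concatenate by condition, channel QC, bandpass
#' filter, PCA motion correction (all on optical density / intensity-derived
#' signals), MBLL conversion, and z-scored total haemoglobin. The order is
#' recorded in the returned provenance and cannot be rearranged.
#'
#' @param raw a `raw_intensity` object.
#' @param events optional event table for [trim_concatenate()].
#' @param condition condition to keep when `events` is supplied.
#' @param qc_params,filter_band,pca_variance_fraction,distance,dpf,extinction
#'   stage parameters; see the individual stage functions.
#' @return list (class `"hemo_timecourse"`): `hbo`, `hbr`, `total`,
#'   `channels` (retained indices), `qc`, `sampling_rate`, `provenance`.
#' @export
preprocess_subject <- function(raw, events = NULL, condition = NULL,
                               qc_params = list(), filter_band = c(0.005, 0.5),
                               pca_variance_fraction = 0.8,
                               distance = 3, dpf = c(6, 6),
                               extinction = default_extinction()) {
  fs <- raw$sampling_rate
  prov <- character(0)
  if (!is.null(events)) {
    for (w in 1:2) {
      seg <- trim_concatenate(raw$intensity[w, , , drop = TRUE], events,
                              condition, fs)
      if (w == 1) {
        newI <- array(NA_real_, c(2, nrow(seg), ncol(seg)))
      }
      newI[w, , ] <- seg
    }
    raw$intensity <- newI
    prov <- c(prov, sprintf("trim_concatenate(condition=%s)", condition))
  }
  qc <- do.call(qc_channels, c(list(raw = raw), qc_params))
  prov <- c(prov, "qc_channels")
  usable <- qc$channel[qc$usable]
  .assert(length(usable) > 0, "no usable channels after QC")
  # optical-density changes per wavelength on the usable channels; the filter
  # and the PCA correction operate on optical data, conversion comes last
  T <- dim(raw$intensity)[3]
  od <- lapply(1:2, function(w) {
    m <- matrix(NA_real_, length(usable), T)
    for (i in seq_along(usable)) {
      I <- raw$intensity[w, usable[i], ]
      ok <- I > 0
      lod <- -log10(I[ok])
      m[i, ok] <- lod - mean(lod)  # geometric-mean baseline
    }
    m
  })
  od <- lapply(od, function(m) bandpass(m, filter_band[1], filter_band[2], fs))
  prov <- c(prov, sprintf("bandpass(%g-%g Hz)", filter_band[1], filter_band[2]))
  if (length(usable) >= 2 && pca_variance_fraction > 0) {
    od <- lapply(od, pca_motion_correct, variance_fraction = pca_variance_fraction)
    prov <- c(prov, sprintf("pca_motion_correct(%g)", pca_variance_fraction))
  }
  Einv <- solve(extinction)
  hbo <- matrix(NA_real_, length(usable), T)
  hbr <- matrix(NA_real_, length(usable), T)
  for (i in seq_along(usable)) {
    odn <- rbind(od[[1]][i, ] / (distance * dpf[1]),
                 od[[2]][i, ] / (distance * dpf[2]))
    conc <- Einv %*% odn
    hbo[i, ] <- conc[1, ]; hbr[i, ] <- conc[2, ]
  }
  prov <- c(prov, "mbll")
  tot <- total_hb_signal(hbo, hbr)
  prov <- c(prov, "total_hb_signal(z-score)")
  structure(list(hbo = hbo, hbr = hbr, total = tot$total,
                 channels = usable[tot$channels], qc = qc,
                 sampling_rate = fs, provenance = prov),
            class = "hemo_timecourse")
}
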