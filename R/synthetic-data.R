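#' Specification of a shared-response cohort simulation
#'
#' Each subject's channel time course follows the shared-response decomposition
#' `X_A(t) = alpha_A * C(t) + beta_A * id_A(t) + eps_A(t)`: a stimulus-driven
#' component `C(t)` common to all subjects, an idiosyncratic component
#' `id_A(t)` independent across subjects, and white measurement noise. `C(t)`
#' and `id_A(t)` are unit-variance processes; with `Var(C) = 1` the expected
#' pairwise correlation between two subjects is
#' `alpha_i * alpha_j / sqrt((alpha_i^2 + beta_i^2 + sd^2)(alpha_j^2 + beta_j^2 + sd^2))`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_timepoints samples per channel (>= 2).
#' @param sampling_rate Hz; default 7.8, typical of continuous-wave fNIRS.
#' @param shared_weights scalar or per-subject `alpha_A`.
#' @param idio_weights scalar or per-subject `beta_A`.
#' @param noise_sd white-noise standard deviation (>= 0).
#' @param shared_signal_kind `"smoothed-noise"` (Gaussian noise low-pass
#'   filtered below 0.5 Hz, mimicking the hemodynamic band) or
#'   `"band-limited"` (random-phase sinusoid mixture on 0.01-0.5 Hz).
#' @param n_channels independent channels to simulate (each gets its own
#'   `C(t)`, idiosyncratic signals, and noise).
#' @param seed integer RNG seed.
#' @return object of class `"shared_response_spec"`.
#' @export
shared_response_spec <- function(n_subjects, n_timepoints, sampling_rate = 7.8,
                                 shared_weights = 1, idio_weights = 0,
                                 noise_sd = 1,
                                 shared_signal_kind = c("smoothed-noise",
                                                        "band-limited"),
                                 n_channels = 1L, seed = 1L) {
  shared_signal_kind <- match.arg(shared_signal_kind)
  .assert(n_subjects >= 2, "n_subjects must be >= 2")
  .assert(n_timepoints >= 2, "n_timepoints must be >= 2")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")
  shared_weights <- rep_len(shared_weights, n_subjects)
  idio_weights <- rep_len(idio_weights, n_subjects)
  .assert(all(is.finite(shared_weights)) && all(is.finite(idio_weights)),
          "weights must be finite")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 sampling_rate = sampling_rate,
                 shared_weights = shared_weights,
                 idio_weights = idio_weights,
                 noise_sd = noise_sd,
                 shared_signal_kind = shared_signal_kind,
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "shared_response_spec")
}

# Unit-variance stationary signal in the hemodynamic band. With
# `shape = FALSE` the same RNG draws are consumed but the (deterministic,
# possibly costly) shaping is skipped and zeros are returned — used to keep
# the RNG stream identical across calls that zero out a component.
.shared_signal <- function(n, fs, kind, shape = TRUE) {
  if (kind == "smoothed-noise") {
    x <- rnorm(n)
    if (!shape) return(numeric(n))
    if (fs / 2 > 0.5) {
      bf <- signal::butter(3, 0.5 / (fs / 2), type = "low")
      x <- signal::filtfilt(bf, x)
    }
  } else {
    freqs <- seq(0.01, 0.5, by = 0.01)
    ph <- runif(length(freqs), 0, 2 * pi)
    if (!shape) return(numeric(n))
    tt <- seq_len(n) / fs
    x <- rowSums(vapply(seq_along(freqs),
                        function(k) sin(2 * pi * freqs[k] * tt + ph[k]),
                        numeric(n)))
  }
  as.numeric((x - mean(x)) / sd(x))
}

#' Simulate a shared-response cohort
#'
#' Draws `C(t)` once per channel (identical across subjects within one call),
#' then independent idiosyncratic signals and white noise per subject, and
#' combines them with the per-subject weights of the spec. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [shared_response_spec()].
#' @param weights optional per-subject shared-weight override (used internally
#'   by the behaviour-coupled generator).
#' @return an [cohort()] object.
#' @export
simulate_shared_response <- function(spec, weights = NULL) {
  .assert(inherits(spec, "shared_response_spec"), "spec must be a shared_response_spec")
  alpha <- if (is.null(weights)) spec$shared_weights else weights
  .assert(length(alpha) == spec$n_subjects && all(is.finite(alpha)),
          "invalid shared weights")
  n <- spec$n_subjects; T <- spec$n_timepoints
  .with_seed(spec$seed, {
    data <- replicate(n, matrix(0, spec$n_channels, T), simplify = FALSE)
    for (ch in seq_len(spec$n_channels)) {
      C <- .shared_signal(T, spec$sampling_rate, spec$shared_signal_kind)
      for (a in seq_len(n)) {
        # the idio draw always consumes RNG so that changing beta (or the
        # shared-weight override) alters amplitudes only, never the draws
        idio <- spec$idio_weights[a] *
          .shared_signal(T, spec$sampling_rate, spec$shared_signal_kind,
                         shape = spec$idio_weights[a] != 0)
        eps <- rnorm(T, sd = spec$noise_sd)
        data[[a]][ch, ] <- alpha[a] * C + idio + eps
      }
    }
    cohort(data, sampling_rate = spec$sampling_rate)
  })
}

#' Specification of behaviour-coupled cohort simulation
#'
#' Couples the shared-response generator to per-subject behavioural scores
#' under one of two similarity structures. Under `"annak"` (Anna Karenina),
#' high scorers synchronise strongly while low scorers are idiosyncratic: the
#' shared weight becomes `alpha_A + kappa * (rank(score_A) - 0.5) / n`, a
#' monotone, bounded function of score rank that reduces to uniform weights
#' under ties. Under `"nn"` (Nearest Neighbor), subjects receive latent
#' signals whose cross-subject correlation decays as
#' `exp(-|score_i - score_j| / length_scale)`, so temporal similarity tracks
#' score proximity anywhere on the scale. `kappa = 0` (or `"none"`) reproduces
#' the base cohort exactly.
#'
#' @param scores per-subject behavioural scores on the 0-100 rating scale.
#' @param structure `"annak"`, `"nn"`, or `"none"`.
#' @param coupling_strength kappa >= 0.
#' @param base a [shared_response_spec()].
#' @param length_scale score-distance scale of the NN latent correlation.
#' @return object of class `"behavior_coupling_spec"`.
#' @export
behavior_coupling_spec <- function(scores, structure = c("annak", "nn", "none"),
                                   coupling_strength, base, length_scale = 20) {
  structure_ <- match.arg(structure)
  .assert(inherits(base, "shared_response_spec"), "base must be a shared_response_spec")
  .assert(length(scores) == base$n_subjects,
          "scores length must equal base$n_subjects")
  .assert(all(is.finite(scores)), "scores must be finite")
  .assert(coupling_strength >= 0, "coupling_strength must be >= 0")
  structure(list(scores = as.numeric(scores), structure = structure_,
                 coupling_strength = coupling_strength, base = base,
                 length_scale = length_scale),
            class = "behavior_coupling_spec")
}

#' Simulate a cohort whose synchrony structure follows behavioural scores
#'
#' @param spec a [behavior_coupling_spec()].
#' @return list with elements `cohort` and `scores`.
#' @export
simulate_coupled_cohort <- function(spec) {
  .assert(inherits(spec, "behavior_coupling_spec"),
          "spec must be a behavior_coupling_spec")
  base <- spec$base
  kappa <- spec$coupling_strength
  if (spec$structure == "none" || kappa == 0) {
    return(list(cohort = simulate_shared_response(base), scores = spec$scores))
  }
  n <- base$n_subjects
  if (spec$structure == "annak") {
    rk <- rank(spec$scores)  # average ranks under ties
    alpha <- base$shared_weights + kappa * (rk - 0.5) / n
    return(list(cohort = simulate_shared_response(base, weights = alpha),
                scores = spec$scores))
  }
  # NN: Gaussian-process-like latent basis along the score axis, added on top
  # of the base cohort so kappa -> 0 degrades gracefully to the base model.
  K <- exp(-abs(outer(spec$scores, spec$scores, "-")) / spec$length_scale)
  L <- t(chol(K + diag(1e-8, n)))
  base_cohort <- simulate_shared_response(base)
  coh <- .with_seed(base$seed + 1L, {
    data <- base_cohort$data
    for (ch in seq_len(base$n_channels)) {
      Z <- matrix(rnorm(n * base$n_timepoints), n, base$n_timepoints)
      lat <- L %*% Z
      for (a in seq_len(n)) data[[a]][ch, ] <- data[[a]][ch, ] + kappa * lat[a, ]
    }
    cohort(data, sampling_rate = base$sampling_rate)
  })
  list(cohort = coh, scores = spec$scores)
}

#' Tabulated haemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxygenated and deoxygenated haemoglobin at
#' the two standard continuous-wave fNIRS wavelengths (760 and 850 nm), in
#' 1/(mM cm), from the commonly used compiled absorption tables. Rows are
#' wavelengths, columns are `HbO` and `HbR`. The matrix is well conditioned
#' because the HbO/HbR ratio differs strongly between the two wavelengths.
#'
#' @param wavelengths numeric; currently 760 and 850 nm are tabulated.
#' @return 2 x 2 numeric matrix with dimnames.
#' @export
default_extinction <- function(wavelengths = c(760, 850)) {
  tab <- rbind("760" = c(HbO = 1.4866, HbR = 3.8437),
               "850" = c(HbO = 2.5264, HbR = 1.7986))
  idx <- match(as.character(wavelengths), rownames(tab))
  .assert(!anyNA(idx), "only 760 and 850 nm are tabulated; supply a matrix")
  m <- tab[idx, , drop = FALSE]
  rownames(m) <- as.character(wavelengths)
  m
}

#' Forward-simulate raw dual-wavelength light intensities
#'
#' Forward model of the Modified Beer-Lambert Law, enabling round-trip tests
#' of the inversion in [mbll()]: optical density
#' `OD(lambda, t) = (eps_HbO(lambda) dHbO(t) + eps_HbR(lambda) dHbR(t)) * d * DPF(lambda)`
#' and intensity `I(lambda, t) = I0(lambda) * 10^(-OD)`. Optional artifacts
#' (detector-saturation plateaus, white-noise channels) are injected after the
#' forward model, for exercising channel quality control.
#'
#' @param hbo,hbr channels x time matrices of concentration changes (mM).
#' @param distance source-detector separation in cm.
#' @param dpf differential pathlength factor per wavelength (length 2).
#' @param extinction 2 x 2 extinction matrix (wavelength x chromophore).
#' @param baseline_intensity baseline intensity per wavelength (length 2).
#' @param sampling_rate Hz.
#' @param adc_ceiling detector ceiling used when injecting saturation.
#' @param artifacts optional list with `saturation` (data.frame: channel,
#'   onset_s, duration_s) and/or `white_noise_channels` (integer vector).
#' @param seed RNG seed for artifact noise.
#' @return object of class `"raw_intensity"`: list with `wavelengths`,
#'   `intensity` (wavelength x channel x time array), `sampling_rate`,
#'   `channel_ids`, `adc_ceiling`.
#' @export
simulate_raw_intensity <- function(hbo, hbr, distance = 3,
                                   dpf = c(6, 6),
                                   extinction = default_extinction(),
                                   baseline_intensity = c(1, 1),
                                   sampling_rate = 7.8,
                                   adc_ceiling = 10,
                                   artifacts = NULL, seed = 1L) {
  if (is.vector(hbo)) hbo <- matrix(hbo, nrow = 1)
  if (is.vector(hbr)) hbr <- matrix(hbr, nrow = 1)
  .assert(all(dim(hbo) == dim(hbr)), "hbo/hbr shape mismatch")
  .assert(abs(det(extinction)) > 1e-12,
          "extinction matrix is singular (invalid geometry)")
  .assert(all(baseline_intensity > 0), "baseline intensities must be positive")
  nch <- nrow(hbo); T <- ncol(hbo)
  intensity <- array(NA_real_, dim = c(2, nch, T))
  for (w in 1:2) {
    od <- (extinction[w, "HbO"] * hbo + extinction[w, "HbR"] * hbr) *
      distance * dpf[w]
    intensity[w, , ] <- baseline_intensity[w] * 10^(-od)
  }
  raw <- structure(list(wavelengths = as.numeric(rownames(extinction)),
                        intensity = intensity,
                        sampling_rate = sampling_rate,
                        channel_ids = paste0("ch", seq_len(nch)),
                        adc_ceiling = adc_ceiling),
                   class = "raw_intensity")
  if (!is.null(artifacts)) {
    raw <- .with_seed(seed, {
      if (!is.null(artifacts$saturation)) {
        for (i in seq_len(nrow(artifacts$saturation))) {
          a <- artifacts$saturation[i, ]
          i0 <- round(a$onset_s * sampling_rate) + 1
          i1 <- i0 + round(a$duration_s * sampling_rate) - 1
          .assert(i1 <= T, "saturation segment out of bounds")
          raw$intensity[, a$channel, i0:i1] <- adc_ceiling
        }
      }
      if (!is.null(artifacts$white_noise_channels)) {
        for (chn in artifacts$white_noise_channels) {
          for (w in 1:2) {
            raw$intensity[w, chn, ] <- abs(rnorm(T, mean = baseline_intensity[w],
                                                 sd = 0.05 * baseline_intensity[w]))
          }
        }
      }
      raw
    })
  }
  raw
}

#' Specification of the two-part rating generator
#'
#' Generative twin of the two-part zero-inflated Gaussian mixed model used for
#' bounded 0-100 emotion ratings. For each subject x session x video cell, a
#' logistic mixed submodel (subject random intercept) draws whether the
#' response is *non-extreme*; extreme responses land exactly on the boundary
#' (raw 100 for negative emotions, raw 0 for joy). Non-extreme responses are
#' drawn from a Gaussian linear mixed submodel on the log-transformed scale
#' and back-transformed to 0-100. The success of the logistic part is coded as
#' "non-extreme", matching the fitting convention in [fit_two_part_zig()].
#'
#' @param n_subjects number of subjects.
#' @param n_videos_per_session videos rated per session (two sessions:
#'   pre = 0, post = 1).
#' @param logistic_fixed named numeric: `intercept`, `time`, `group`,
#'   `time_group` on the log-odds (non-extreme) scale.
#' @param gaussian_fixed same structure on the log-transformed rating scale.
#' @param random_intercept_sd length-2 named numeric `c(logistic=, gaussian=)`.
#' @param residual_sd Gaussian submodel residual sd.
#' @param emotion_polarity `"negative"` (extreme = raw 100) or `"positive"`
#'   (joy; extreme = raw 0).
#' @param emotion label stored in the output table.
#' @param seed RNG seed.
#' @return object of class `"ratings_gen_spec"`.
#' @export
ratings_gen_spec <- function(n_subjects = 72, n_videos_per_session = 8,
                             logistic_fixed = c(intercept = 2.2, time = -0.35,
                                                group = -0.2, time_group = -2.1),
                             gaussian_fixed = c(intercept = 2.78, time = 0.22,
                                                group = -0.05, time_group = 0.21),
                             random_intercept_sd = c(logistic = 1.8,
                                                     gaussian = 0.57),
                             residual_sd = 0.62,
                             emotion_polarity = c("negative", "positive"),
                             emotion = "anger", seed = 1L) {
  emotion_polarity <- match.arg(emotion_polarity)
  .assert(all(random_intercept_sd >= 0) && residual_sd >= 0, "sds must be >= 0")
  .assert(n_subjects >= 2 && n_videos_per_session >= 1, "invalid sizes")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_videos_per_session = as.integer(n_videos_per_session),
                 logistic_fixed = logistic_fixed,
                 gaussian_fixed = gaussian_fixed,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd,
                 emotion_polarity = emotion_polarity,
                 emotion = emotion, seed = as.integer(seed)),
            class = "ratings_gen_spec")
}

#' Simulate a discrete-emotion ratings table
#'
#' @param spec a [ratings_gen_spec()].
#' @return data.frame with columns `subject`, `session` (0 = pre, 1 = post),
#'   `group` (0/1), `video`, `emotion`, `value` (raw 0-100).
#' @export
simulate_ratings <- function(spec) {
  .assert(inherits(spec, "ratings_gen_spec"), "spec must be a ratings_gen_spec")
  n <- spec$n_subjects
  .with_seed(spec$seed, {
    group <- rep(0:1, length.out = n)[sample.int(n)]
    b_log <- rnorm(n, sd = spec$random_intercept_sd["logistic"])
    b_gau <- rnorm(n, sd = spec$random_intercept_sd["gaussian"])
    grid <- expand.grid(video = seq_len(spec$n_videos_per_session),
                        session = 0:1, subject = seq_len(n))
    g <- group[grid$subject]
    lf <- spec$logistic_fixed
    eta <- lf["intercept"] + lf["time"] * grid$session + lf["group"] * g +
      lf["time_group"] * grid$session * g + b_log[grid$subject]
    nonextreme <- rbinom(nrow(grid), 1, plogis(eta)) == 1
    gf <- spec$gaussian_fixed
    mu <- gf["intercept"] + gf["time"] * grid$session + gf["group"] * g +
      gf["time_group"] * grid$session * g + b_gau[grid$subject]
    tval <- rnorm(nrow(grid), mu, spec$residual_sd)
    # keep non-extreme draws strictly inside the transformed range so they
    # back-transform into [0, 100] without touching the extreme boundary
    tval <- pmin(pmax(tval, 1e-6), log(101))
    raw <- if (spec$emotion_polarity == "negative") {
      ifelse(nonextreme, pmin(pmax(101 - exp(tval), 0), 100), 100)
    } else {
      ifelse(nonextreme, pmin(pmax(exp(tval) - 1, 0), 100), 0)
    }
    data.frame(subject = grid$subject, session = grid$session,
               group = g, video = grid$video,
               emotion = spec$emotion, value = raw)
  })
}

#' Simulate fear-style ratings with no inflated boundary
#'
#' Plain Gaussian linear mixed structure on the raw 0-100 scale (fear showed
#' neither skew nor boundary inflation, so it is modelled without a two-part
#' split). Values are truncated to the scale.
#'
#' @param n_subjects,n_videos_per_session design sizes.
#' @param fixed named numeric `intercept`, `time`, `group`, `time_group`.
#' @param random_intercept_sd,residual_sd variance components (sd scale).
#' @param seed RNG seed.
#' @return ratings data.frame as in [simulate_ratings()], `emotion = "fear"`.
#' @export
simulate_fear_ratings <- function(n_subjects = 72, n_videos_per_session = 8,
                                  fixed = c(intercept = 51.63, time = -0.04,
                                            group = -6.59, time_group = 5.76),
                                  random_intercept_sd = sqrt(492.76),
                                  residual_sd = sqrt(333.88), seed = 1L) {
  .with_seed(seed, {
    group <- rep(0:1, length.out = n_subjects)[sample.int(n_subjects)]
    b <- rnorm(n_subjects, sd = random_intercept_sd)
    grid <- expand.grid(video = seq_len(n_videos_per_session),
                        session = 0:1, subject = seq_len(n_subjects))
    g <- group[grid$subject]
    mu <- fixed["intercept"] + fixed["time"] * grid$session + fixed["group"] * g +
      fixed["time_group"] * grid$session * g + b[grid$subject]
    raw <- pmin(pmax(rnorm(nrow(grid), mu, residual_sd), 0), 100)
    data.frame(subject = grid$subject, session = grid$session, group = g,
               video = grid$video, emotion = "fear", value = raw)
  })
}
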