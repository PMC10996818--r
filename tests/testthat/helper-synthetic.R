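# Shared fixtures, built in code at test time.

# one shared-response cohort split into two equally sized group cohorts with
# disjoint subject ids
make_split_cohorts <- function(n_per_group, n_timepoints, seed,
                               shared_weights = 1, noise_sd = 1) {
  spec <- shared_response_spec(2 * n_per_group, n_timepoints,
                               shared_weights = shared_weights,
                               noise_sd = noise_sd, seed = seed)
  coh <- simulate_shared_response(spec)
  idxA <- seq_len(n_per_group)
  idxB <- n_per_group + seq_len(n_per_group)
  list(A = cohort(coh$data[idxA], sampling_rate = coh$sampling_rate),
       B = cohort(setNames(coh$data[idxB], paste0("b", idxB)),
                  sampling_rate = coh$sampling_rate))
}

# two groups with orthogonal (independent) shared signals and little noise:
# a very strong within > between effect
make_strong_group_effect <- function(n_per_group = 6, n_timepoints = 400,
                                     seed = 1) {
  cohA <- simulate_shared_response(shared_response_spec(
    n_per_group, n_timepoints, shared_weights = 1, noise_sd = 0.1,
    seed = seed))
  cohB <- simulate_shared_response(shared_response_spec(
    n_per_group, n_timepoints, shared_weights = 1, noise_sd = 0.1,
    seed = seed + 5000L))
  cohB$subjects <- paste0("b", cohB$subjects)
  names(cohB$data) <- cohB$subjects
  list(A = cohA, B = cohB)
}

# flat-spectrum raw intensity channel for QC tests
make_white_noise_raw <- function(T = 4096, fs = 7.8, seed = 11) {
  hb0 <- matrix(0, 1, T)
  raw <- simulate_raw_intensity(hb0, hb0, sampling_rate = fs,
                                artifacts = list(white_noise_channels = 1),
                                seed = seed)
  raw
}
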