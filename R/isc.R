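#' Pairwise intersubject correlation matrix
#'
#' Pearson correlation of every pair of subjects' time courses on one
#' channel, the first-level estimate of stimulus-driven shared activity.
#' Subjects with a constant time course have no defined correlation and are
#' excluded with a warning.
#'
#' @param cohort an [cohort()] object.
#' @param channel channel index or id.
#' @return a [similarity_matrix()] of kind `"pearson_r"` (diagonal 1).
#' @export
pairwise_isc <- function(cohort, channel = 1) {
  X <- .channel_matrix(cohort, channel)
  sds <- apply(X, 1, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d subject(s) with constant time course",
                    sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  .assert(nrow(X) >= 2, "need >= 2 subjects with usable data")
  R <- cor(t(X))
  diag(R) <- 1
  similarity_matrix(R, "pearson_r", subjects = cohort$subjects[keep])
}

#' Leave-one-out intersubject correlation
#'
#' Per-subject ISC computed as the Pearson correlation between a subject's
#' time course and the element-wise mean of every *other* subject's time
#' course. With n = 2 this reduces exactly to the single pairwise
#' correlation.
#'
#' @inheritParams pairwise_isc
#' @return named numeric vector of per-subject ISC values.
#' @export
loo_isc <- function(cohort, channel = 1) {
  X <- .zscore_rows(.channel_matrix(cohort, channel))
  .assert(nrow(X) >= 2, "need >= 2 subjects")
  tot <- colSums(X)
  vals <- vapply(seq_len(nrow(X)), function(i) {
    ref <- (tot - X[i, ]) / (nrow(X) - 1)
    if (sd(X[i, ]) == 0 || sd(ref) == 0) return(NA_real_)
    cor(X[i, ], ref)
  }, numeric(1))
  names(vals) <- cohort$subjects
  vals
}

# per-subject standardisation (population sd) before any averaging across
# subjects: the leave-one-out reference is then an unweighted mean of unit-
# variance signals and the whole ISC machinery is invariant to per-subject
# affine rescaling; constant rows are left centered at zero
.zscore_rows <- function(X) {
  t(apply(X, 1, function(x) {
    xc <- x - mean(x)
    s <- sqrt(mean(xc^2))
    if (s > 0) xc / s else xc
  }))
}

# Gram matrix of standardised time courses; every Pearson correlation between
# a subject and any (sum of a) subset of subjects is then O(n) to evaluate,
# which makes subject-wise permutation nulls cheap.
.centered_gram <- function(X) {
  tcrossprod(.zscore_rows(X))
}

# cor(x_i, sum_{j in S} x_j) from the centered Gram matrix
.cor_with_subset_sum <- function(G, i, S) {
  num <- sum(G[i, S])
  den <- sqrt(G[i, i] * sum(G[S, S]))
  if (den <= 0) return(NA_real_)
  num / den
}

# within-minus-between statistic from a Gram matrix and two index sets;
# fully vectorised so permutation nulls cost O(n^2) each
.two_sample_stat_gram <- function(G, idxA, idxB) {
  one_group <- function(own, other) {
    Gown <- G[own, own, drop = FALSE]
    dg <- diag(Gown)
    rs <- rowSums(Gown)
    tot <- sum(rs)
    within <- (rs - dg) / sqrt(dg * (tot - 2 * rs + dg))
    numB <- rowSums(G[own, other, drop = FALSE])
    between <- numB / sqrt(dg * sum(G[other, other]))
    cbind(within, between)
  }
  wb <- rbind(one_group(idxA, idxB), one_group(idxB, idxA))
  wb[!is.finite(wb)] <- NA
  c(within = mean(wb[, 1], na.rm = TRUE),
    between = mean(wb[, 2], na.rm = TRUE))
}

#' Within- versus between-group ISC statistic
#'
#' Within-group ISC is the mean leave-one-out ISC of each subject against
#' their own group; between-group ISC is the mean correlation of each subject
#' with the *full* mean time course of the other group (leave-one-out has no
#' natural "leave" across groups). The test statistic is their difference.
#'
#' @param cohortA,cohortB cohorts for the two groups (same channel set,
#'   length, and sampling rate).
#' @param channel channel index or id.
#' @return named numeric: `within_mean`, `between_mean`, `difference`.
#' @export
two_sample_statistic <- function(cohortA, cohortB, channel = 1) {
  .assert(n_subjects(cohortA) >= 3 && n_subjects(cohortB) >= 3,
          "each group needs >= 3 subjects")
  XA <- .channel_matrix(cohortA, channel)
  XB <- .channel_matrix(cohortB, channel)
  .assert(ncol(XA) == ncol(XB), "groups must share recording length")
  G <- .centered_gram(rbind(XA, XB))
  st <- .two_sample_stat_gram(G, seq_len(nrow(XA)),
                              nrow(XA) + seq_len(nrow(XB)))
  c(within_mean = unname(st["within"]), between_mean = unname(st["between"]),
    difference = unname(st["within"] - st["between"]))
}

#' Subject-wise permutation test of within- vs between-group ISC
#'
#' Tests `H0: ISC_within = ISC_between` by randomly reassigning subjects to
#' groups (preserving group sizes) and recomputing the within-minus-between
#' statistic for each relabelling. The p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, one-sided for
#' within > between by default.
#'
#' @param cohortA,cohortB the two group cohorts; subject ids must not overlap.
#' @param channels channel indices (default: all).
#' @param n_perm permutation count (the conventional choice is 5000).
#' @param seed RNG seed; the null is bit-reproducible from `(seed, n_perm)`.
#' @param alternative `"greater"` (within > between) or `"two.sided"`.
#' @return data.frame (class `"isc_permutation_result"`): one row per channel
#'   with `channel`, `within_isc`, `between_isc`, `difference`, `p`,
#'   `null_q50`, `null_q95`, `n_perm`, `seed`, `scheme`.
#' @export
swp_two_sample_test <- function(cohortA, cohortB, channels = NULL,
                                n_perm = 5000, seed = 1L,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(n_subjects(cohortA) + n_subjects(cohortB) >= 6,
          "need >= 6 subjects combined")
  .assert(!any(cohortA$subjects %in% cohortB$subjects),
          "duplicate subject ids across groups")
  if (n_perm < 100) warning("n_perm < 100: p-values will be very coarse")
  if (is.null(channels)) channels <- seq_len(n_channels(cohortA))
  nA <- n_subjects(cohortA)
  nB <- n_subjects(cohortB)
  n <- nA + nB
  rows <- lapply(channels, function(ch) {
    G <- .centered_gram(rbind(.channel_matrix(cohortA, ch),
                              .channel_matrix(cohortB, ch)))
    obs <- .two_sample_stat_gram(G, seq_len(nA), nA + seq_len(nB))
    obs_d <- obs["within"] - obs["between"]
    null_d <- .with_seed(seed + .resolve_channel(cohortA, ch), {
      vapply(seq_len(n_perm), function(p) {
        # relabelings that reproduce the observed grouping carry no
        # information about the null and are excluded (redrawn)
        repeat {
          idxA <- sample.int(n, nA)
          same <- setequal(idxA, seq_len(nA)) ||
            (nA == nB && setequal(idxA, nA + seq_len(nB)))
          if (!same) break
        }
        st <- .two_sample_stat_gram(G, idxA, setdiff(seq_len(n), idxA))
        unname(st["within"] - st["between"])
      }, numeric(1))
    })
    exceed <- if (alternative == "greater") {
      sum(null_d >= obs_d)
    } else {
      sum(abs(null_d) >= abs(obs_d))
    }
    data.frame(channel = .resolve_channel(cohortA, ch),
               within_isc = unname(obs["within"]),
               between_isc = unname(obs["between"]),
               difference = unname(obs_d),
               p = (1 + exceed) / (n_perm + 1),
               null_q50 = unname(quantile(null_d, 0.5)),
               null_q95 = unname(quantile(null_d, 0.95)),
               n_perm = n_perm, seed = seed, scheme = "group_relabel")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("isc_permutation_result", "data.frame")
  out
}

#' One-sample test of within-group synchrony via circular shifts
#'
#' Tests whether mean leave-one-out ISC exceeds chance by building a null in
#' which each subject's time course is independently circularly shifted by a
#' random non-zero offset: shifting preserves each series' autocorrelation
#' while destroying time-locked alignment across subjects.
#'
#' @param cohort an [cohort()] object (>= 3 subjects).
#' @param channel channel index or id.
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return one-row data.frame (class `"isc_permutation_result"`) with
#'   `channel`, `statistic` (mean leave-one-out ISC), `p`, `null_q50`,
#'   `null_q95`, `n_perm`, `seed`, `scheme`.
#' @export
one_sample_isc_test <- function(cohort, channel = 1, n_perm = 5000, seed = 1L) {
  .assert(n_subjects(cohort) >= 3, "need >= 3 subjects")
  X <- .channel_matrix(cohort, channel)
  T <- ncol(X)
  .assert(T >= 100, "need >= 100 time points for the circular-shift null")
  if (n_perm < 100) warning("n_perm < 100: p-values will be very coarse")
  X <- .zscore_rows(X)
  mean_loo <- function(M) {
    tot <- colSums(M)
    mean(vapply(seq_len(nrow(M)), function(i) {
      ref <- tot - M[i, ]
      if (sd(M[i, ]) == 0 || sd(ref) == 0) return(NA_real_)
      cor(M[i, ], ref)
    }, numeric(1)), na.rm = TRUE)
  }
  obs <- mean_loo(X)
  null_s <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      offs <- sample.int(T - 1, nrow(X), replace = TRUE)  # offset 0 excluded
      Xs <- X
      for (i in seq_len(nrow(X))) {
        o <- offs[i]
        Xs[i, ] <- c(X[i, (T - o + 1):T], X[i, 1:(T - o)])
      }
      mean_loo(Xs)
    }, numeric(1))
  })
  out <- data.frame(channel = .resolve_channel(cohort, channel),
                    statistic = obs,
                    p = (1 + sum(null_s >= obs)) / (n_perm + 1),
                    null_q50 = unname(quantile(null_s, 0.5)),
                    null_q95 = unname(quantile(null_s, 0.95)),
                    n_perm = n_perm, seed = seed, scheme = "circular_shift")
  class(out) <- c("isc_permutation_result", "data.frame")
  out
}
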