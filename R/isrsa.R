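#' Squared-Euclidean (Nearest-Neighbor) distance matrix
#'
#' The Nearest-Neighbor similarity model assumes subjects adjacent on the
#' behavioural scale are most alike; it is operationalised by the squared
#' Euclidean distance `D(i, j) = sum_t (c_i(t) - c_j(t))^2` between time
#' courses, or `(s_i - s_j)^2` between scalar scores. On per-subject z-scored
#' time courses of length `T` the identity `D = 2 T (1 - r)` links this
#' distance to the pairwise Pearson ISC matrix.
#'
#' @param x per-subject scores (numeric vector) or a subjects x time matrix.
#' @return a [similarity_matrix()] of kind `"sq_euclidean"` (diagonal 0).
#' @export
nn_distance_matrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  .assert(is.numeric(x), "x must be numeric")
  D <- as.matrix(dist(x))^2
  similarity_matrix(D, "sq_euclidean")
}

#' Anna-Karenina similarity matrix
#'
#' The Anna-Karenina model assumes high scorers resemble each other while low
#' scorers are each idiosyncratic in their own way. Pair similarity is the
#' mean of the two subjects' ranks divided by the number of subjects:
#' `(rank_i + rank_j) / (2 n)`, ranks ascending with average-rank ties. Being
#' rank-based, the matrix is invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores per-subject behavioural scores (>= 2, not all tied).
#' @return a [similarity_matrix()] of kind `"annak_similarity"`
#'   (diagonal `rank_i / n`, values in (0, 1]).
#' @export
annak_similarity_matrix <- function(scores) {
  .assert(length(scores) >= 2 && all(is.finite(scores)),
          "need >= 2 finite scores")
  if (length(unique(scores)) == 1) {
    stop("degenerate input: all scores identical, AnnaK similarity is constant",
         call. = FALSE)
  }
  rk <- rank(scores)
  n <- length(scores)
  S <- outer(rk, rk, "+") / (2 * n)
  similarity_matrix(S, "annak_similarity")
}

# orient any similarity_matrix as "higher = more similar"; distances negated
.as_similarity_values <- function(m) {
  .assert(inherits(m, "similarity_matrix"),
          "expected a similarity_matrix (use nn_distance_matrix()/pairwise_isc())")
  if (m$kind == "sq_euclidean") -m$values else m$values
}

#' Correlation between neural and behavioural similarity structures
#'
#' Correlates the strictly-upper-triangle entries of a neural and a
#' behavioural (dis)similarity matrix. Distances are negated internally so
#' both matrices share the orientation "higher = more similar" before
#' correlating. Spearman rank correlation is the default, as usual for
#' IS-RSA; Pearson is available.
#'
#' @param neural,behavior [similarity_matrix()] objects over the same
#'   subjects in the same order.
#' @param method `"spearman"` or `"pearson"`.
#' @return scalar correlation.
#' @export
isrsa_correlation <- function(neural, behavior,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  nv <- .as_similarity_values(neural)
  bv <- .as_similarity_values(behavior)
  .assert(all(dim(nv) == dim(bv)), "matrices must have the same size")
  .assert(nrow(nv) >= 3, "need >= 3 subjects")
  un <- .upper_tri(nv); ub <- .upper_tri(bv)
  .assert(sd(un) > 0 && sd(ub) > 0,
          "degenerate input: constant upper triangle")
  cor(un, ub, method = method)
}

#' Subject-wise permutation test of an IS-RSA correlation
#'
#' Builds the null by jointly permuting rows and columns of the behavioural
#' matrix under random subject relabelings and recomputing the
#' upper-triangle correlation. Default p-value is two-sided on |r| with the
#' add-one rule; a one-sided (positive) option is exposed.
#'
#' @inheritParams isrsa_correlation
#' @param model label recorded in the result (`"annak"`, `"nn"`, or other).
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @param alternative `"two.sided"` or `"greater"`.
#' @return one-row data.frame (class `"isrsa_result"`): `model`, `r`, `p`,
#'   `n_perm`, `seed`, `method`.
#' @export
swp_isrsa_test <- function(neural, behavior, model = "annak", n_perm = 5000,
                           seed = 1L, method = c("spearman", "pearson"),
                           alternative = c("two.sided", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  nv <- .as_similarity_values(neural)
  bv <- .as_similarity_values(behavior)
  .assert(all(dim(nv) == dim(bv)), "matrices must have the same size")
  n <- nrow(nv)
  .assert(n >= 3, "need >= 3 subjects")
  un <- .upper_tri(nv)
  .assert(sd(un) > 0 && sd(.upper_tri(bv)) > 0,
          "degenerate input: constant upper triangle")
  obs <- cor(un, .upper_tri(bv), method = method)
  null_r <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      repeat {  # the identity relabeling is excluded from the null
        perm <- sample.int(n)
        if (any(perm != seq_len(n))) break
      }
      cor(un, .upper_tri(bv[perm, perm]), method = method)
    }, numeric(1))
  })
  exceed <- if (alternative == "two.sided") {
    sum(abs(null_r) >= abs(obs))
  } else {
    sum(null_r >= obs)
  }
  out <- data.frame(model = model, r = obs,
                    p = (1 + exceed) / (n_perm + 1),
                    n_perm = n_perm, seed = seed, method = method)
  class(out) <- c("isrsa_result", "data.frame")
  out
}

#' Mantel test between two (dis)similarity matrices
#'
#' Linear (Pearson) correlation of the strictly-upper triangles, tested by
#' jointly permuting rows and columns of the second matrix. Add-one p-value
#' rule; one-sided (positive association) by default, as conventional for
#' Mantel tests.
#'
#' @param m1,m2 symmetric numeric matrices or [similarity_matrix()] objects
#'   over the same subjects in the same order.
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 5000, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  v1 <- if (inherits(m1, "similarity_matrix")) m1$values else m1
  v2 <- if (inherits(m2, "similarity_matrix")) m2$values else m2
  .assert(is.matrix(v1) && is.matrix(v2) && all(dim(v1) == dim(v2)),
          "matrices must be square and of equal size")
  .assert(max(abs(v1 - t(v1))) <= 1e-8 && max(abs(v2 - t(v2))) <= 1e-8,
          "matrices must be symmetric")
  n <- nrow(v1)
  u1 <- .upper_tri(v1)
  obs <- cor(u1, .upper_tri(v2))
  null_r <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      repeat {  # identity relabeling excluded
        perm <- sample.int(n)
        if (any(perm != seq_len(n))) break
      }
      cor(u1, .upper_tri(v2[perm, perm]))
    }, numeric(1))
  })
  exceed <- if (alternative == "greater") sum(null_r >= obs) else
    sum(abs(null_r) >= abs(obs))
  list(r = obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm, seed = seed)
}

#' Compare Nearest-Neighbor and Anna-Karenina model fits across channels
#'
#' Paired t-test across channels on the difference of per-channel IS-RSA
#' correlations under the two similarity models. A positive t favours the
#' Anna-Karenina model. If every channel shows the identical non-zero
#' difference the t statistic is unbounded; this is reported via the
#' `consistent_difference` flag rather than a meaningless p-value.
#'
#' @param fits_annak,fits_nn per-channel IS-RSA correlations (equal length
#'   >= 2, same channel order).
#' @return list with `t_statistic`, `p`, `mean_difference`,
#'   `consistent_difference` flag, and `per_channel` table.
#' @export
compare_similarity_models <- function(fits_annak, fits_nn) {
  .assert(length(fits_annak) == length(fits_nn), "channel sets must match")
  .assert(length(fits_annak) >= 2, "need >= 2 channels")
  d <- fits_annak - fits_nn
  tab <- data.frame(channel = seq_along(d), r_annak = fits_annak,
                    r_nn = fits_nn, difference = d)
  if (sd(d) <= 1e-10 * max(1, max(abs(d)))) {
    return(list(t_statistic = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                p = if (all(d == 0)) 1 else NA_real_,
                mean_difference = mean(d),
                consistent_difference = !all(d == 0),
                per_channel = tab))
  }
  tt <- t.test(fits_annak, fits_nn, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p = tt$p.value,
       mean_difference = mean(d), consistent_difference = FALSE,
       per_channel = tab)
}

#' Per-channel IS-RSA under one similarity model
#'
#' Convenience wrapper running [swp_isrsa_test()] on every channel of a
#' cohort against one behavioural score vector, with the neural similarity
#' taken as the pairwise ISC matrix.
#'
#' @param cohort an [cohort()] object.
#' @param scores per-subject behavioural scores.
#' @param model `"annak"` or `"nn"`.
#' @param n_perm,seed,method,alternative passed to [swp_isrsa_test()].
#' @return data.frame with one row per channel.
#' @export
isrsa_by_channel <- function(cohort, scores, model = c("annak", "nn"),
                             n_perm = 5000, seed = 1L,
                             method = "spearman",
                             alternative = "two.sided") {
  model <- match.arg(model)
  .assert(length(scores) == n_subjects(cohort),
          "scores length must match cohort size")
  behavior <- if (model == "annak") annak_similarity_matrix(scores) else
    nn_distance_matrix(scores)
  rows <- lapply(seq_len(n_channels(cohort)), function(ch) {
    res <- swp_isrsa_test(pairwise_isc(cohort, ch), behavior, model = model,
                          n_perm = n_perm, seed = seed + ch,
                          method = method, alternative = alternative)
    cbind(channel = ch, res)
  })
  do.call(rbind, rows)
}
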