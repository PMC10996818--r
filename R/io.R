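#' Write a cohort as delimited text plus a JSON manifest
#'
#' One tab-separated file per subject (rows = channels, columns = samples)
#' and a `manifest.json` recording subject ids, file names, group labels,
#' channel ids, sampling rate, and the seed/parameters that produced the
#' data. Plain text keeps the format portable and diff-able.
#'
#' @param cohort an [cohort()] object.
#' @param dir output directory (created if needed).
#' @param extra named list merged into the manifest (e.g. generator seed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(cohort$subjects, ".tsv")
  for (i in seq_along(cohort$subjects)) {
    write.table(format(cohort$data[[i]], digits = 17, trim = TRUE,
                       scientific = TRUE),
                file.path(dir, files[i]), sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  manifest <- c(list(subjects = cohort$subjects, files = files,
                     group = cohort$group,
                     sampling_rate = cohort$sampling_rate,
                     channel_ids = cohort$channel_ids), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a JSON manifest
#'
#' Validates that every referenced per-subject matrix exists and that all
#' subjects share channel count and recording length; mismatches are rejected
#' with the offending subject named.
#'
#' @param manifest_path path to a `manifest.json` written by [write_cohort()].
#' @return an [cohort()] object.
#' @export
read_cohort <- function(manifest_path) {
  .assert(file.exists(manifest_path), paste("missing manifest:", manifest_path))
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  .assert(!anyDuplicated(man$subjects), "duplicate subject id in manifest")
  data <- vector("list", length(man$subjects))
  ref_dim <- NULL
  for (i in seq_along(man$subjects)) {
    f <- file.path(dir, man$files[i])
    .assert(file.exists(f), paste("missing data file for subject",
                                  man$subjects[i]))
    m <- as.matrix(read.table(f, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (is.null(ref_dim)) {
      ref_dim <- dim(m)
    } else if (!all(dim(m) == ref_dim)) {
      stop("shape mismatch for subject ", man$subjects[i],
           ": expected ", ref_dim[1], "x", ref_dim[2], ", got ",
           nrow(m), "x", ncol(m), call. = FALSE)
    }
    data[[i]] <- m
  }
  cohort(data, subjects = man$subjects,
         group = if (length(man$group)) man$group else NULL,
         sampling_rate = man$sampling_rate, channel_ids = man$channel_ids)
}

#' Write / read a long-format ratings table
#'
#' Comma-separated, UTF-8, header row, '.' decimal; one row per
#' subject x session x video x emotion.
#'
#' @param ratings ratings data.frame.
#' @param path CSV path.
#' @return `write_ratings` returns the path invisibly; `read_ratings` returns
#'   the data.frame.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  .assert(file.exists(path), paste("missing ratings file:", path))
  read.csv(path, fileEncoding = "UTF-8")
}

#' Validate a pipeline run configuration
#'
#' Every stochastic stage must carry an explicit seed so that reruns are
#' byte-identical; validation happens before any stage executes.
#'
#' @param config named list; see [run_pipeline()].
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  .assert(is.list(config), "config must be a list")
  for (field in c("seed", "n_perm", "out_dir")) {
    .assert(!is.null(config[[field]]),
            paste0("config is missing required field '", field, "'"))
  }
  .assert(is.numeric(config$seed) && config$seed == round(config$seed),
          "config$seed must be an integer")
  invisible(config)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in fixed order — simulate (cohorts and ratings), ISC
#' two-sample permutation test, per-channel IS-RSA under both similarity
#' models with model comparison, and the two-part emotion model — writing CSV
#' and JSON outputs plus a provenance log (package version, seeds,
#' parameters) to `config$out_dir`. Reruns with the same config are
#' byte-identical.
#'
#' @param config named list with at least `seed`, `n_perm`, `out_dir`;
#'   optional `n_subjects_per_group`, `n_timepoints`, `n_channels`,
#'   `n_videos_per_session`, `coupling` (`"annak"`/`"nn"`/`"none"`),
#'   `coupling_strength`, `emotion`, `verbose`.
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  cfg <- utils::modifyList(
    list(n_subjects_per_group = 12, n_timepoints = 600, n_channels = 4,
         n_videos_per_session = 8, coupling = "annak", coupling_strength = 2,
         emotion = "anger", verbose = TRUE), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage simulate: cohorts + ratings")
  n <- 2 * cfg$n_subjects_per_group
  sim <- stage("simulate", {
    scores <- .with_seed(cfg$seed, runif(n, 0, 100))
    base <- shared_response_spec(n, cfg$n_timepoints,
                                 shared_weights = 0, noise_sd = 1,
                                 n_channels = cfg$n_channels,
                                 seed = cfg$seed + 1L)
    cc <- simulate_coupled_cohort(behavior_coupling_spec(
      scores, cfg$coupling, cfg$coupling_strength, base))
    ratings <- simulate_ratings(ratings_gen_spec(
      n_subjects = n, n_videos_per_session = cfg$n_videos_per_session,
      emotion = cfg$emotion, seed = cfg$seed + 2L))
    list(cohort = cc$cohort, scores = cc$scores, ratings = ratings)
  })
  grp <- rep(c("A", "B"), each = cfg$n_subjects_per_group)
  outputs$cohort <- write_cohort(sim$cohort, file.path(cfg$out_dir, "cohort"),
                                 extra = list(seed = cfg$seed,
                                              coupling = cfg$coupling))
  outputs$ratings <- file.path(cfg$out_dir, "ratings.csv")
  write_ratings(sim$ratings, outputs$ratings)

  say("stage isc: two-sample subject-wise permutation test")
  isc_res <- stage("isc", {
    keepA <- which(grp == "A"); keepB <- which(grp == "B")
    cohA <- cohort(sim$cohort$data[keepA], sampling_rate = sim$cohort$sampling_rate)
    cohB <- cohort(setNames(sim$cohort$data[keepB],
                            paste0("b_", seq_along(keepB))),
                   sampling_rate = sim$cohort$sampling_rate)
    swp_two_sample_test(cohA, cohB, n_perm = cfg$n_perm, seed = cfg$seed + 3L)
  })
  outputs$isc <- file.path(cfg$out_dir, "isc_results.csv")
  write.csv(isc_res, outputs$isc, row.names = FALSE)

  say("stage isrsa: both similarity models per channel")
  isrsa_res <- stage("isrsa", {
    fits_a <- isrsa_by_channel(sim$cohort, sim$scores, "annak",
                               n_perm = cfg$n_perm, seed = cfg$seed + 4L)
    fits_n <- isrsa_by_channel(sim$cohort, sim$scores, "nn",
                               n_perm = cfg$n_perm, seed = cfg$seed + 4L)
    cmp <- compare_similarity_models(fits_a$r, fits_n$r)
    list(table = rbind(fits_a, fits_n), comparison = cmp)
  })
  outputs$isrsa <- file.path(cfg$out_dir, "isrsa.csv")
  write.csv(isrsa_res$table, outputs$isrsa, row.names = FALSE)

  say("stage emotions: two-part zero-inflated mixed model")
  fit <- stage("emotions", {
    fit_two_part_zig(transform_ratings(sim$ratings, cfg$emotion))
  })
  outputs$emotions <- file.path(cfg$out_dir, "emotion_fit.json")
  fit_json <- list(
    emotion = cfg$emotion,
    logistic = if (isTRUE(fit$logistic$skipped)) list(skipped = TRUE) else
      list(coefficients = fit$logistic$coefficients,
           tau00 = fit$logistic$tau00, sigma2 = fit$logistic$sigma2,
           icc = fit$logistic$icc),
    gaussian = list(coefficients = fit$gaussian$coefficients,
                    sigma2 = fit$gaussian$sigma2, tau00 = fit$gaussian$tau00,
                    icc = fit$gaussian$icc,
                    r2_marginal = fit$gaussian$r2_marginal,
                    r2_conditional = fit$gaussian$r2_conditional),
    n_subjects = fit$n_subjects, n_observations = fit$n_observations)
  jsonlite::write_json(fit_json, outputs$emotions, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  outputs$provenance <- file.path(cfg$out_dir, "provenance.json")
  jsonlite::write_json(
    list(package = "neurosync",
         version = as.character(utils::packageVersion("neurosync")),
         config = cfg[setdiff(names(cfg), "verbose")],
         model_comparison = list(
           t = isrsa_res$comparison$t_statistic,
           p = isrsa_res$comparison$p,
           mean_difference = isrsa_res$comparison$mean_difference)),
    outputs$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", cfg$out_dir)
  invisible(outputs)
}
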