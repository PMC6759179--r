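#' Experiment configuration
#'
#' Bundles everything one linkage experiment arm needs: the generator
#' config, the blocking variable (DOB for the primary arm, YOB for the
#' secondary), the run matrix, and the rank thresholds evaluated as
#' operating points.
#'
#' @param generator a [generator_config()].
#' @param block_var `"dob"` or `"yob"`.
#' @param profiles list of [run_profile()]s; default the 17-run matrix.
#' @param rank_thresholds rank operating points for the confusion metrics.
#' @param out_dir optional directory for CSV output.
#' @param seed experiment seed; overrides the generator's seed so one number
#'   drives all randomness.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              block_var = c("dob", "yob"),
                              profiles = default_run_matrix(),
                              rank_thresholds = c(1L, 2L),
                              out_dir = NULL,
                              seed = NULL) {
  block_var <- match.arg(block_var)
  stopifnot(inherits(generator, "generator_config"))
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  if (!all(vapply(profiles, inherits, logical(1L), "run_profile"))) {
    stop("`profiles` must be a list of run_profile objects", call. = FALSE)
  }
  nms <- vapply(profiles, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("run names must be unique", call. = FALSE)
  names(profiles) <- nms
  structure(list(generator = generator, block_var = block_var,
                 profiles = profiles,
                 rank_thresholds = as.integer(rank_thresholds),
                 out_dir = out_dir),
            class = "experiment_config")
}

# weights for one profile; EM profiles estimate their own parameters first
.run_weights <- function(profile, vec_exact, vec_inexact, params_fs,
                         params_epi) {
  vec <- if (profile$string_mode == "exact") vec_exact else vec_inexact
  w <- switch(profile$method,
    FS = fs_weight(vec, params_fs, profile),
    EM = {
      fit <- em_estimate(vec, profile = profile)
      fs_weight(vec, fit$params, profile)
    },
    EPI = as.numeric(epilink_weight(vec, params_epi)),
    DET = deterministic_weight(vec, threshold = profile$similarity_threshold,
                               fractional = profile$fractional),
    stop(sprintf("unknown weighting method '%s'", profile$method),
         call. = FALSE))
  if (profile$positive_only_output) w[w <= 0] <- NA_real_
  w
}

#' Run one end-to-end linkage experiment
#'
#' Generates the synthetic scenario, harmonizes and deduplicates the
#' inpatient dataset, blocks candidate pairs, builds exact and Jaro-Winkler
#' comparison vectors, computes all run-profile weight columns, scales and
#' dense-ranks them, forms the two ensembles, and evaluates everything
#' against the MRN gold standard and the latent truth. Fully deterministic
#' given the config seed. A failing run profile is recorded in
#' `run_errors` and its column left `NA`; the experiment continues.
#'
#' @param config an [experiment_config()].
#' @return object of class `linkage_experiment`: a list with the datasets,
#'   pair table, labels, weight/scaled/rank matrices, per-run summaries and
#'   metrics, AUCs, extreme-weight gold-agreement tables, correlations, PCA
#'   ratios, ensembles, and per-stage log counts.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  scen <- generate_scenario(config$generator)
  ipd <- harmonize(scen$ipd)
  opd <- harmonize(scen$opd)
  ipd <- deduplicate(ipd)
  log <- list(ipd_rows = nrow(ipd), opd_rows = nrow(opd),
              dedup = attr(ipd, "dedup_log"))

  pairs <- block_pairs(ipd, opd, config$block_var)
  log$n_pairs <- nrow(pairs)
  if (nrow(pairs) == 0L) stop("blocking produced no candidate pairs",
                              call. = FALSE)

  vec_exact <- build_comparison_vectors(pairs, ipd, opd, mode = "exact")
  vec_inexact <- build_comparison_vectors(pairs, ipd, opd, mode = "inexact")

  params_fs <- default_match_params(opd)
  params_epi <- epilink_from_match_params(params_fs)

  run_names <- names(config$profiles)
  W <- matrix(NA_real_, nrow(pairs), length(run_names),
              dimnames = list(NULL, run_names))
  run_errors <- list()
  for (nm in run_names) {
    res <- tryCatch(
      .run_weights(config$profiles[[nm]], vec_exact, vec_inexact,
                   params_fs, params_epi),
      error = function(e) e)
    if (inherits(res, "error")) {
      run_errors[[nm]] <- conditionMessage(res)
    } else {
      W[, nm] <- res
    }
  }
  ok <- setdiff(run_names, names(run_errors))

  scaled <- W
  ranks <- W
  for (nm in ok) {
    scaled[, nm] <- scale_weights(W[, nm])
    ranks[, nm] <- rank_weights(W[, nm])
  }

  gold <- gold_labels(pairs, ipd, opd)
  truth <- truth_labels(pairs, ipd, opd)

  summaries <- do.call(rbind, lapply(ok, function(nm) {
    cbind(run = nm, summarize_run(W[, nm]))
  }))

  metrics <- do.call(rbind, lapply(ok, function(nm) {
    do.call(rbind, lapply(config$rank_thresholds, function(k) {
      cm <- confusion_at_rank(ranks[, nm], gold, k)
      data.frame(run = nm, max_rank = k, as.data.frame(cm))
    }))
  }))

  auc <- do.call(rbind, lapply(ok, function(nm) {
    data.frame(run = nm,
               auc_gold = roc_auc(W[, nm], gold)$auc,
               auc_truth = roc_auc(W[, nm], truth)$auc)
  }))

  gold_top <- .extreme_agreement(ranks, gold, ok, highest = TRUE)
  gold_bottom <- .extreme_agreement(ranks, gold, ok, highest = FALSE)

  ens_avg <- ensemble_average(scaled[, ok, drop = FALSE])
  ens_vote <- ensemble_vote(ranks[, ok, drop = FALSE], k = 2L)
  ensembles <- list(
    average = ens_avg, vote = ens_vote,
    auc = data.frame(run = c("ENS/AVG", "ENS/VOTE"),
                     auc_gold = c(roc_auc(ens_avg, gold)$auc,
                                  roc_auc(ens_vote, gold)$auc),
                     auc_truth = c(roc_auc(ens_avg, truth)$auc,
                                   roc_auc(ens_vote, truth)$auc)))

  corr <- weight_correlations(W[, ok, drop = FALSE])
  pca <- weight_pca(scaled[, ok, drop = FALSE])

  out <- structure(list(config = config, ipd = ipd, opd = opd,
                        pairs = pairs, gold = gold, truth = truth,
                        params = params_fs, weights = W, scaled = scaled,
                        ranks = ranks, summaries = summaries,
                        metrics = metrics, auc = auc,
                        gold_top = gold_top, gold_bottom = gold_bottom,
                        ensembles = ensembles, correlations = corr,
                        pca = pca, run_errors = run_errors, log = log),
                   class = "linkage_experiment")
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

# gold-standard agreement among pairs at the extreme (top or bottom) one and
# two distinct weights of each run
.extreme_agreement <- function(ranks, gold, run_names, highest = TRUE) {
  do.call(rbind, lapply(run_names, function(nm) {
    r <- ranks[, nm]
    if (highest) {
      sel1 <- !is.na(r) & r <= 1L
      sel2 <- !is.na(r) & r <= 2L
    } else {
      mx <- max(r, na.rm = TRUE)
      sel1 <- !is.na(r) & r == mx
      sel2 <- !is.na(r) & r >= mx - 1L
    }
    data.frame(run = nm,
               n_extreme_gold_no = sum(sel1 & gold == 0L),
               n_extreme_gold_yes = sum(sel1 & gold == 1L),
               n_extreme2_gold_no = sum(sel2 & gold == 0L),
               n_extreme2_gold_yes = sum(sel2 & gold == 1L))
  }))
}

#' Write experiment outputs as CSV
#'
#' Writes the analysis file (one row per compared pair: identifiers, gold
#' and truth labels, raw/scaled/rank columns per run, ensemble columns),
#' the per-run weight summary, the confusion metrics, AUCs, extreme-weight
#' gold-agreement tables, and the effective configuration (YAML) for the
#' round trip.
#'
#' @param experiment a `linkage_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- experiment
  af <- data.frame(x$pairs[c("ipd_record_id", "opd_record_id")],
                   gold = x$gold, truth = x$truth,
                   x$weights,
                   stats::setNames(as.data.frame(x$scaled),
                                   paste0("scaled_", colnames(x$scaled))),
                   stats::setNames(as.data.frame(x$ranks),
                                   paste0("rank_", colnames(x$ranks))),
                   ensemble_avg = x$ensembles$average,
                   ensemble_vote = x$ensembles$vote,
                   check.names = FALSE)
  utils::write.csv(af, file.path(dir, "analysis_file.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(x$summaries, file.path(dir, "run_summaries.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(x$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(rbind(x$auc, x$ensembles$auc),
                   file.path(dir, "auc.csv"), row.names = FALSE, na = "")
  utils::write.csv(x$gold_top, file.path(dir, "gold_agreement_top.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(x$gold_bottom, file.path(dir, "gold_agreement_bottom.csv"),
                   row.names = FALSE, na = "")
  write_experiment_config(x$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Save / load an experiment configuration
#'
#' The effective configuration (defaults resolved) round-trips through YAML:
#' re-running from the loaded config reproduces the experiment exactly.
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `path` invisibly, or the loaded `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  gen <- unclass(config$generator)
  gen$reference_date <- as.character(gen$reference_date)
  # named vectors must be written as YAML maps, not bare sequences
  gen$mrn_error_split <- as.list(gen$mrn_error_split)
  gen$age_band_weights <- as.list(gen$age_band_weights)
  obj <- list(generator = gen,
              block_var = config$block_var,
              rank_thresholds = config$rank_thresholds,
              profiles = lapply(unname(config$profiles), unclass))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  gen <- obj$generator
  gen$mrn_error_split <- unlist(gen$mrn_error_split)
  gen$age_band_weights <- unlist(gen$age_band_weights)
  gen <- do.call(generator_config, gen)
  profiles <- lapply(obj$profiles, function(p) do.call(run_profile, p))
  experiment_config(generator = gen, block_var = obj$block_var,
                    profiles = profiles,
                    rank_thresholds = obj$rank_thresholds)
}

#' @export
print.linkage_experiment <- function(x, ...) {
  cat("Linkage experiment (block:", x$config$block_var, ")\n")
  cat(sprintf("  IPD rows: %d  OPD rows: %d  candidate pairs: %d\n",
              x$log$ipd_rows, x$log$opd_rows, x$log$n_pairs))
  cat(sprintf("  runs: %d (%d failed)  gold positives: %d\n",
              length(x$config$profiles), length(x$run_errors),
              sum(x$gold)))
  best <- x$auc[which.max(x$auc$auc_gold), ]
  cat(sprintf("  best single-run AUC (gold): %.4f (%s)\n",
              best$auc_gold, best$run))
  cat(sprintf("  ensemble AUC (gold): average %.4f, vote %.4f\n",
              x$ensembles$auc$auc_gold[1], x$ensembles$auc$auc_gold[2]))
  invisible(x)
}
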