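#' M/U match parameters
#'
#' Per-field M-probabilities (probability a field agrees given the pair is a
#' true match) and U-probabilities (probability it agrees given a non-match),
#' plus the match prevalence `p` used as a mixture weight by the EM
#' estimator.
#'
#' @param m,u named numeric vectors over the matching fields, each in (0, 1),
#'   with `u < m` for every informative field.
#' @param p match prevalence in (0, 1).
#' @return object of class `match_params`.
#' @export
match_params <- function(m, u, p = 0.01) {
  if (is.null(names(m)) || is.null(names(u)) ||
      !identical(sort(names(m)), sort(names(u)))) {
    stop("`m` and `u` must be named over the same fields", call. = FALSE)
  }
  u <- u[names(m)]
  if (any(m <= 0 | m >= 1) || any(u <= 0 | u >= 1)) {
    stop("m and u probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (any(u >= m)) {
    stop(sprintf("u must be < m for informative fields (offending: %s)",
                 paste(names(m)[u >= m], collapse = ", ")), call. = FALSE)
  }
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  structure(list(m = m, u = u, p = p), class = "match_params")
}

#' Default M/U parameters from a dataset
#'
#' The convention used by linkage packages run at their defaults: every
#' M-probability is 0.95 and every U-probability is the reciprocal of the
#' number of distinct non-missing values the field takes in the designated
#' dataset.
#'
#' @param dataset data.frame the distinct-value counts are taken from.
#' @param fields matching fields.
#' @param m default M-probability applied to every field.
#' @param p match prevalence (EM initialization).
#' @return a [match_params()] object.
#' @export
default_match_params <- function(dataset,
                                 fields = c("first_name", "last_name",
                                            "gender"),
                                 m = 0.95, p = 0.01) {
  stopifnot(nrow(dataset) > 0L, all(fields %in% names(dataset)))
  u <- vapply(fields, function(f) {
    k <- length(unique(dataset[[f]][!is.na(dataset[[f]])]))
    if (k <= 1L) {
      stop(sprintf(paste0("field '%s' has a single distinct value; ",
                          "u = 1 is uninformative - drop the field or set ",
                          "u manually"), f), call. = FALSE)
    }
    1 / k
  }, numeric(1L))
  mm <- rep(m, length(fields))
  names(mm) <- fields
  match_params(mm, u, p)
}

#' A linkage run profile
#'
#' Names one algorithm/dialect combination of the run matrix: string mode
#' (exact or Jaro-Winkler), weighting family (Fellegi-Sunter, EM, EpiLink,
#' deterministic), the missing-data policy, how similarities are converted
#' to weights, and whether only positive weights survive to the output (the
#' truncation one packaged tool exhibits).
#'
#' @param name unique run label, e.g. `"R/EX/FS"`.
#' @param string_mode `"exact"` or `"inexact"`.
#' @param method `"FS"`, `"EM"`, `"EPI"` or `"DET"`.
#' @param missing_policy `"zero_contribution"` (a missing field contributes
#'   zero weight, so an all-disagree pattern with a missing field ranks above
#'   one with nothing missing) or `"disagreement"` (missing is folded into
#'   disagreement, collapsing those two patterns).
#' @param inexact_conversion `"threshold_binary"` (similarity >= threshold
#'   counts as agreement) or `"interpolate"` (the field weight is linearly
#'   interpolated between its disagreement and agreement values by the
#'   similarity).
#' @param similarity_threshold threshold for `threshold_binary` and for the
#'   deterministic count in inexact mode.
#' @param positive_only_output drop weights `<= 0` from the output column
#'   (recorded as `NA`).
#' @param fractional deterministic dialect: sum similarities instead of
#'   counting threshold agreements (inexact mode only).
#' @return object of class `run_profile`.
#' @export
run_profile <- function(name,
                        string_mode = c("exact", "inexact"),
                        method = c("FS", "EM", "EPI", "DET"),
                        missing_policy = c("zero_contribution",
                                           "disagreement"),
                        inexact_conversion = c("threshold_binary",
                                               "interpolate"),
                        similarity_threshold = 0.95,
                        positive_only_output = FALSE,
                        fractional = FALSE) {
  string_mode <- match.arg(string_mode)
  method <- match.arg(method)
  missing_policy <- match.arg(missing_policy)
  inexact_conversion <- match.arg(inexact_conversion)
  if (method == "EPI" && string_mode != "exact") {
    stop("the EpiLink profile is defined for exact string matching only",
         call. = FALSE)
  }
  if (similarity_threshold < 0 || similarity_threshold > 1) {
    stop("`similarity_threshold` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, string_mode = string_mode, method = method,
                 missing_policy = missing_policy,
                 inexact_conversion = inexact_conversion,
                 similarity_threshold = similarity_threshold,
                 positive_only_output = positive_only_output,
                 fractional = fractional),
            class = "run_profile")
}

#' The default 17-run matrix
#'
#' Seventeen named algorithm/dialect combinations spanning four weighting
#' families (Fellegi-Sunter, EM, EpiLink, deterministic), exact and
#' Jaro-Winkler string matching, two missing-data policies, two
#' similarity-conversion dialects, and one positive-only-output truncation
#' pair — nine exact runs and eight inexact runs. Run names follow the
#' `package-style/string-mode/method` convention.
#'
#' @return named list of 17 [run_profile()] objects.
#' @export
default_run_matrix <- function() {
  p <- list(
    run_profile("R/EX/FS", "exact", "FS", "disagreement"),
    run_profile("R/EX/EM", "exact", "EM", "disagreement"),
    run_profile("R/EX/EPI", "exact", "EPI", "zero_contribution"),
    run_profile("MTB/EX/FS", "exact", "FS", "zero_contribution"),
    run_profile("MTB/EX/EM", "exact", "EM", "zero_contribution"),
    run_profile("MTB/EX/D", "exact", "DET", "zero_contribution"),
    run_profile("CU/EX/FS", "exact", "FS", "zero_contribution"),
    run_profile("LP/EX/FS", "exact", "FS", "zero_contribution"),
    run_profile("LP/EX/EM", "exact", "EM", "zero_contribution"),
    run_profile("R/INEX/FS", "inexact", "FS", "disagreement",
                "threshold_binary"),
    run_profile("R/INEX/EM", "inexact", "EM", "disagreement",
                "threshold_binary"),
    run_profile("MTB/INEX/FS", "inexact", "FS", "zero_contribution",
                "interpolate"),
    run_profile("MTB/INEX/EM", "inexact", "EM", "zero_contribution",
                "interpolate"),
    run_profile("MTB/INEX/D", "inexact", "DET", "zero_contribution",
                "interpolate", fractional = TRUE),
    run_profile("CU/INEX/FS", "inexact", "FS", "zero_contribution",
                "interpolate"),
    run_profile("LP/INEX/FS", "inexact", "FS", "zero_contribution",
                "interpolate", positive_only_output = TRUE),
    run_profile("LP/INEX/EM", "inexact", "EM", "zero_contribution",
                "interpolate", positive_only_output = TRUE))
  names(p) <- vapply(p, `[[`, character(1L), "name")
  p
}

# internal: comparison vectors -> numeric gamma matrix.
# exact trichotomy: agree -> 1, disagree -> 0, missing -> NA;
# inexact similarity columns pass through (NA = missing).
.gamma_matrix <- function(vectors,
                          fields = attr(vectors, "fields")) {
  if (is.null(fields)) {
    fields <- setdiff(names(vectors), c("ipd_record_id", "opd_record_id"))
  }
  g <- matrix(NA_real_, nrow(vectors), length(fields),
              dimnames = list(NULL, fields))
  for (f in fields) {
    col <- vectors[[f]]
    if (is.character(col)) {
      g[, f] <- ifelse(col == "agree", 1,
                       ifelse(col == "disagree", 0, NA_real_))
    } else {
      if (any(col < 0 | col > 1, na.rm = TRUE)) {
        stop(sprintf("similarities for field '%s' fall outside [0, 1]", f),
             call. = FALSE)
      }
      g[, f] <- as.numeric(col)
    }
  }
  g
}

#' Fellegi-Sunter pair weights
#'
#' The sum over matching fields of base-2 log-likelihood ratios:
#' `log2(m/u)` on agreement and `log2((1-m)/(1-u))` on disagreement. Under
#' the `zero_contribution` missing policy a missing field adds zero weight;
#' under `disagreement` it adds the disagreement weight. In inexact mode the
#' similarity is either binarized at the profile threshold
#' (`threshold_binary`) or linearly interpolated between the two field
#' weights (`interpolate`).
#'
#' @param vectors comparison vectors from [build_comparison_vectors()].
#' @param params a [match_params()] object.
#' @param profile a [run_profile()]; defaults to exact FS with
#'   zero-contribution missing handling.
#' @return numeric vector of raw weights, one per pair.
#' @export
fs_weight <- function(vectors, params,
                      profile = run_profile("FS", "exact", "FS")) {
  stopifnot(inherits(params, "match_params"))
  g <- .gamma_matrix(vectors)
  fields <- colnames(g)
  if (!all(fields %in% names(params$m))) {
    stop("params do not cover all comparison fields", call. = FALSE)
  }
  wa <- log2(params$m[fields] / params$u[fields])
  wd <- log2((1 - params$m[fields]) / (1 - params$u[fields]))

  W <- numeric(nrow(g))
  for (j in seq_along(fields)) {
    s <- g[, j]
    if (profile$string_mode == "inexact" &&
        profile$inexact_conversion == "threshold_binary") {
      s <- as.numeric(s >= profile$similarity_threshold)
    }
    if (profile$string_mode == "exact" ||
        profile$inexact_conversion == "threshold_binary") {
      s <- round(s) # trichotomy already 0/1
    }
    contrib <- s * wa[j] + (1 - s) * wd[j]
    miss <- is.na(s)
    if (profile$missing_policy == "disagreement") {
      contrib[miss] <- wd[j]
    } else {
      contrib[miss] <- 0
    }
    W <- W + contrib
  }
  unname(W)
}

#' EpiLink field-weight parameters
#'
#' Per-field error rates `e` and average value frequencies `f`, yielding
#' field weights `log2((1 - e) / f)`. The defaults tie the EpiLink
#' vocabulary to the M/U one: `e = 1 - m` and `f = u`.
#'
#' @param e,f named numeric vectors in (0, 1) over the matching fields.
#' @return object of class `epilink_params` with the derived field weights.
#' @export
epilink_params <- function(e, f) {
  if (is.null(names(e)) || is.null(names(f)) ||
      !identical(sort(names(e)), sort(names(f)))) {
    stop("`e` and `f` must be named over the same fields", call. = FALSE)
  }
  f <- f[names(e)]
  if (any(e <= 0 | e >= 1) || any(f <= 0 | f >= 1)) {
    stop("e and f must lie strictly inside (0, 1)", call. = FALSE)
  }
  w <- log2((1 - e) / f)
  if (any(w <= 0)) {
    stop("field weights log2((1-e)/f) must be positive for informative fields",
         call. = FALSE)
  }
  structure(list(e = e, f = f, w = w), class = "epilink_params")
}

#' @rdname epilink_params
#' @param params a [match_params()] object to derive defaults from.
#' @export
epilink_from_match_params <- function(params) {
  epilink_params(e = 1 - params$m, f = params$u)
}

#' EpiLink pair weights
#'
#' Normalized similarity-weighted sum of field weights:
#' `W = sum(s_i * w_i) / sum(w_i)` over the non-missing fields, with
#' `w_i = log2((1 - e_i) / f_i)` and `s_i` the similarity (1/0 for exact
#' agree/disagree). Full agreement scores exactly 1, full disagreement 0.
#' Missing fields drop out of numerator and denominator; a pair with every
#' field missing gets `NA` and is counted in the `epilink_log` attribute.
#'
#' @param vectors comparison vectors.
#' @param params an [epilink_params()] object.
#' @return numeric vector of weights in `[0, 1]` (NA where undefined).
#' @export
epilink_weight <- function(vectors, params) {
  stopifnot(inherits(params, "epilink_params"))
  g <- .gamma_matrix(vectors)
  fields <- colnames(g)
  if (!all(fields %in% names(params$w))) {
    stop("params do not cover all comparison fields", call. = FALSE)
  }
  w <- params$w[fields]
  ww <- matrix(w, nrow(g), length(w), byrow = TRUE)
  ww[is.na(g)] <- NA_real_
  num <- rowSums(g * ww, na.rm = TRUE)
  den <- rowSums(ww, na.rm = TRUE)
  out <- ifelse(den > 0, num / den, NA_real_)
  attr(out, "epilink_log") <- list(all_missing = sum(den == 0))
  out
}

#' Deterministic pair weights
#'
#' The count of linking fields in exact agreement, an integer from 0 to the
#' number of fields; missing counts as non-agreement. In inexact mode a
#' field agrees when its similarity reaches `threshold`; the `fractional`
#' dialect sums the similarities instead, giving a many-valued weight in
#' `[0, n_fields]`.
#'
#' @param vectors comparison vectors.
#' @param threshold similarity threshold for inexact agreement.
#' @param fractional sum similarities instead of counting.
#' @return numeric vector of weights.
#' @export
deterministic_weight <- function(vectors, threshold = 0.95,
                                 fractional = FALSE) {
  g <- .gamma_matrix(vectors)
  if (fractional) {
    rowSums(g, na.rm = TRUE)
  } else {
    rowSums(g >= threshold, na.rm = TRUE)
  }
}
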