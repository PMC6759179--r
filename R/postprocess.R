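#' Min-max scaling of a weight column
#'
#' Linear rescaling so the lowest weight maps to 0 and the highest to 1:
#' `(W - min W) / (max W - min W)`. A constant column maps to all zeros and
#' is flagged via the `constant` attribute. `NA` weights (pairs truncated
#' from a positive-only run) stay `NA`.
#'
#' @param w numeric weight column (non-empty).
#' @return scaled numeric vector in `[0, 1]`.
#' @export
scale_weights <- function(w) {
  if (length(w) == 0L) stop("empty weight column", call. = FALSE)
  rng <- range(w, na.rm = TRUE)
  if (!is.finite(rng[1])) stop("no finite weights to scale", call. = FALSE)
  if (rng[1] == rng[2]) {
    out <- ifelse(is.na(w), NA_real_, 0)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (w - rng[1]) / (rng[2] - rng[1])
  attr(out, "constant") <- FALSE
  out
}

#' Dense ranks of a weight column
#'
#' Rank 1 is the highest weight; tied weights share a rank and ranks advance
#' by one per distinct value, so the number of distinct ranks equals the
#' number of distinct weights. `NA` weights get `NA` ranks.
#'
#' @param w numeric weight column (non-empty).
#' @return integer vector of dense ranks.
#' @export
rank_weights <- function(w) {
  if (length(w) == 0L) stop("empty weight column", call. = FALSE)
  lev <- sort(unique(w[!is.na(w)]), decreasing = TRUE)
  match(w, lev)
}

#' Average-scaled-weight ensemble
#'
#' Per pair, the arithmetic mean of the scaled weights across all runs (the
#' divisor is the number of runs). Pairs absent from a truncated
#' positive-only run contribute that run's minimum scaled value, 0; the
#' number of such imputations is logged in the `imputed_zero` attribute.
#'
#' @param scaled numeric matrix of scaled weights, one column per run, rows
#'   covering a common pair set.
#' @return numeric vector in `[0, 1]` with one entry per pair.
#' @export
ensemble_average <- function(scaled) {
  scaled <- .as_run_matrix(scaled)
  if (any(scaled < 0 | scaled > 1, na.rm = TRUE)) {
    stop("scaled weights must lie in [0, 1]", call. = FALSE)
  }
  n_imp <- sum(is.na(scaled))
  scaled[is.na(scaled)] <- 0
  out <- rowMeans(scaled)
  attr(out, "imputed_zero") <- n_imp
  out
}

#' Rank-1-or-2 voting ensemble
#'
#' Per pair, the number of runs that assigned the pair one of the `k`
#' highest weights (dense ranks `<= k`). Pairs missing from a truncated run
#' receive no vote from that run.
#'
#' @param ranks integer matrix of dense ranks, one column per run.
#' @param k rank cutoff (>= 1); the default counts rank-1-or-2 assignments.
#' @return integer vote counts in `[0, ncol(ranks)]`.
#' @export
ensemble_vote <- function(ranks, k = 2L) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  ranks <- .as_run_matrix(ranks)
  rowSums(ranks <= k, na.rm = TRUE)
}

# accept a matrix, data.frame or list of per-run columns; the columns must
# cover the same pair set
.as_run_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    len <- vapply(x, length, integer(1L))
    if (length(unique(len)) != 1L) {
      stop("run columns cover mismatched pair sets", call. = FALSE)
    }
    x <- do.call(cbind, x)
  }
  as.matrix(x)
}
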