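#' Gold-standard labels from MRN agreement
#'
#' A pair is gold-positive exactly when both records carry a non-missing
#' medical record number and the two agree; a missing MRN on either side
#' counts as a non-agreement. This is an *alloyed* gold standard: the MRN
#' assignment itself carries a small error rate, so gold labels can disagree
#' with the latent person identity on synthetically corrupted pairs.
#'
#' @param pairs output of [block_pairs()].
#' @param ipd,opd record data.frames with an `mrn` column.
#' @return integer vector of 0/1 labels, one per pair.
#' @export
gold_labels <- function(pairs, ipd, opd) {
  a <- ipd$mrn[pairs$ipd_row]
  b <- opd$mrn[pairs$opd_row]
  as.integer(!is.na(a) & !is.na(b) & a == b)
}

#' Latent-truth labels from the generator sidecar
#'
#' Available for synthetic data only: a pair is true-positive when both
#' records descend from the same latent person.
#'
#' @inheritParams gold_labels
#' @param ipd,opd record data.frames with a `true_person_id` column.
#' @return integer vector of 0/1 labels.
#' @export
truth_labels <- function(pairs, ipd, opd) {
  a <- ipd$true_person_id[pairs$ipd_row]
  b <- opd$true_person_id[pairs$opd_row]
  as.integer(!is.na(a) & !is.na(b) & a == b)
}

#' Confusion counts and metrics at a rank threshold
#'
#' Declares a pair a match when its dense rank is at most `max_rank` (ranks
#' 1 and 2 are the primary operating points) and crosses the declaration
#' with the labels. Metrics with a zero denominator are returned as `NA`.
#' Pairs with `NA` rank (truncated from the run's output) are never
#' declared.
#'
#' @param ranks dense ranks from [rank_weights()].
#' @param labels 0/1 labels.
#' @param max_rank declaration threshold.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
confusion_at_rank <- function(ranks, labels, max_rank = 1L) {
  declared <- !is.na(ranks) & ranks <= max_rank
  labels <- as.integer(labels)
  tp <- sum(declared & labels == 1L)
  fp <- sum(declared & labels == 0L)
  fn <- sum(!declared & labels == 1L)
  tn <- sum(!declared & labels == 0L)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp),
       npv = safe(tn, tn + fn))
}

#' ROC curve and AUC from weights
#'
#' Sweeps a declaration threshold over the distinct weight values (one
#' operating point per distinct weight, ties grouped) and integrates the
#' curve by trapezoids — numerically identical to the Mann-Whitney statistic
#' with the 1/2 tie convention. `NA` weights (truncated pairs) are treated
#' as below every threshold: never declared.
#'
#' @param weights numeric weight column.
#' @param labels 0/1 labels containing both classes.
#' @return list with `auc` and `curve` (data.frame `threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(weights, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("labels must contain both classes to trace a ROC curve",
         call. = FALSE)
  }
  w <- ifelse(is.na(weights), -Inf, weights)
  o <- order(w, decreasing = TRUE)
  ws <- w[o]
  ls <- labels[o]
  # group ties: one operating point per distinct weight
  last <- cumsum(rle(ws)$lengths)
  tp <- cumsum(ls == 1L)[last]
  fp <- cumsum(ls == 0L)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, rle(ws)$values),
                          tpr = tpr, fpr = fpr))
}

#' Pairwise correlations among run weight columns
#'
#' Pearson correlations over the common pair set; symmetric with a unit
#' diagonal. Pairwise-complete observations are used so truncated runs with
#' `NA` weights remain comparable.
#'
#' @param weights matrix of weights, one column per run.
#' @return run-by-run correlation matrix.
#' @export
weight_correlations <- function(weights) {
  weights <- .as_run_matrix(weights)
  if (ncol(weights) < 2L) stop("need at least 2 runs", call. = FALSE)
  stats::cor(weights, use = "pairwise.complete.obs")
}

#' Principal components of the scaled weight matrix
#'
#' Eigendecomposition of the correlation matrix of the scaled weights;
#' returns the proportion of variance per component (non-increasing,
#' summing to 1). Zero-variance columns are dropped with a warning.
#'
#' @param scaled matrix of scaled weights, one column per run (`NA` entries
#'   are treated as 0, the minimum scaled value).
#' @return numeric vector of explained-variance ratios.
#' @export
weight_pca <- function(scaled) {
  scaled <- .as_run_matrix(scaled)
  scaled[is.na(scaled)] <- 0
  v <- apply(scaled, 2L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance run column(s)", sum(v == 0)),
            call. = FALSE)
    scaled <- scaled[, v > 0, drop = FALSE]
  }
  if (ncol(scaled) < 2L) stop("need at least 2 varying runs", call. = FALSE)
  ev <- eigen(stats::cor(scaled), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

#' Table-style summary of one weight column
#'
#' The per-run weight summary: number of distinct weights, minimum and
#' maximum, and the pair counts at the two highest and two lowest distinct
#' weights.
#'
#' @param w numeric weight column (non-empty; `NA`s are truncated pairs and
#'   excluded).
#' @return one-row data.frame with `n_weights`, `min_weight`, `max_weight`,
#'   `n_highest`, `n_second_highest`, `n_lowest`, `n_second_lowest`.
#' @export
summarize_run <- function(w) {
  ww <- w[!is.na(w)]
  if (length(ww) == 0L) stop("empty weight column", call. = FALSE)
  lev <- sort(unique(ww), decreasing = TRUE)
  k <- length(lev)
  cnt <- function(val) sum(ww == val)
  data.frame(n_weights = k,
             min_weight = lev[k],
             max_weight = lev[1],
             n_highest = cnt(lev[1]),
             n_second_highest = if (k >= 2L) cnt(lev[2]) else NA_integer_,
             n_lowest = cnt(lev[k]),
             n_second_lowest = if (k >= 2L) cnt(lev[k - 1L]) else NA_integer_)
}
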