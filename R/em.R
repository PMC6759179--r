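# Two-class conditional-independence mixture over binary agreement vectors,
# fitted by EM. Comparison vectors are binarized first (exact: agree = 1,
# disagree = 0; inexact: similarity >= profile threshold), with missing
# handled per the profile's policy: zero_contribution leaves the field out
# of the pair's likelihood, disagreement folds it into gamma = 0.

.binarize_vectors <- function(vectors, profile) {
  g <- .gamma_matrix(vectors)
  if (profile$string_mode == "inexact") {
    num <- g >= profile$similarity_threshold
    g <- ifelse(is.na(g), NA, as.numeric(num))
  } else {
    g <- round(g)
  }
  if (profile$missing_policy == "disagreement") {
    g[is.na(g)] <- 0
  }
  g
}

# aggregate identical patterns: EM iterates over unique patterns only
.pattern_table <- function(g) {
  key <- apply(g, 1L, paste, collapse = "|")
  tab <- table(key)
  pat <- do.call(rbind, lapply(strsplit(names(tab), "|", fixed = TRUE),
                               function(x) {
                                 x[x == "NA"] <- NA_character_
                                 as.numeric(x)
                               }))
  colnames(pat) <- colnames(g)
  list(patterns = pat, counts = as.numeric(tab), key = key,
       pattern_key = names(tab))
}

# class likelihoods per pattern; a missing (NA) field contributes 1
.class_lik <- function(pat, prob) {
  lik <- rep(1, nrow(pat))
  for (j in seq_len(ncol(pat))) {
    gj <- pat[, j]
    term <- prob[j]^gj * (1 - prob[j])^(1 - gj)
    term[is.na(gj)] <- 1
    lik <- lik * term
  }
  lik
}

#' Posterior match probability under fixed M/U parameters
#'
#' The E-step of the mixture model: for each pair, the posterior probability
#' that it is a match,
#' `p * prod m^g (1-m)^(1-g) / (same + (1-p) * prod u^g (1-u)^(1-g))`,
#' with missing fields contributing nothing to either product.
#'
#' @param vectors comparison vectors.
#' @param params a [match_params()] object.
#' @param profile a [run_profile()] governing binarization.
#' @return numeric vector of posterior probabilities, one per pair.
#' @export
em_posterior <- function(vectors, params,
                         profile = run_profile("EM", "exact", "EM")) {
  stopifnot(inherits(params, "match_params"))
  g <- .binarize_vectors(vectors, profile)
  fields <- colnames(g)
  a <- params$p * .class_lik(g, params$m[fields])
  b <- (1 - params$p) * .class_lik(g, params$u[fields])
  unname(a / (a + b))
}

#' EM estimation of M/U parameters
#'
#' Fits the two-class conditional-independence mixture to the binarized
#' agreement vectors: the E-step computes posterior match probabilities
#' under the current parameters, the M-step re-estimates the prevalence and
#' each field's m and u as posterior-weighted agreement frequencies, and the
#' loop stops when the largest parameter change falls below `tol` or after
#' `max_iter` iterations. Estimates are clamped to `[eps, 1 - eps]` (and
#' flagged) if they degenerate. The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param vectors comparison vectors (at least two distinct agreement
#'   patterns; otherwise the model is unidentifiable and the fit is flagged
#'   degenerate).
#' @param init initial [match_params()]; by default m = 0.9 for every field,
#'   u = 0.1, p = 0.01.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change.
#' @param max_iter iteration cap.
#' @param profile a [run_profile()] governing binarization.
#' @param eps clamping bound for degenerate estimates.
#' @return list with `params` (a [match_params()]), `converged`,
#'   `degenerate`, `clamped`, `n_iter`, and `loglik` (the per-iteration
#'   trace).
#' @export
em_estimate <- function(vectors, init = NULL, tol = 1e-6, max_iter = 500L,
                        profile = run_profile("EM", "exact", "EM"),
                        eps = 1e-6) {
  g <- .binarize_vectors(vectors, profile)
  fields <- colnames(g)
  nf <- length(fields)
  if (is.null(init)) {
    m0 <- stats::setNames(rep(0.9, nf), fields)
    u0 <- stats::setNames(rep(0.1, nf), fields)
    init <- match_params(m0, u0, 0.01)
  }
  pt <- .pattern_table(g)
  pat <- pt$patterns
  cnt <- pt$counts
  N <- sum(cnt)

  if (nrow(pat) < 2L) {
    warning("fewer than 2 distinct agreement patterns; EM is unidentifiable",
            call. = FALSE)
    return(list(params = init, converged = FALSE, degenerate = TRUE,
                clamped = FALSE, n_iter = 0L, loglik = numeric(0)))
  }

  m <- init$m[fields]
  u <- init$u[fields]
  p <- init$p
  clamped <- FALSE
  loglik <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    a <- p * .class_lik(pat, m)
    b <- (1 - p) * .class_lik(pat, u)
    post <- a / (a + b)
    loglik <- c(loglik, sum(cnt * log(a + b)))

    wm <- cnt * post
    wu <- cnt * (1 - post)
    p_new <- sum(wm) / N
    m_new <- m
    u_new <- u
    for (j in seq_len(nf)) {
      ok <- !is.na(pat[, j])
      m_new[j] <- sum(wm[ok] * pat[ok, j]) / sum(wm[ok])
      u_new[j] <- sum(wu[ok] * pat[ok, j]) / sum(wu[ok])
    }
    cl <- function(x) pmin(pmax(x, eps), 1 - eps)
    if (any(c(m_new, u_new, p_new) <= eps) ||
        any(c(m_new, u_new, p_new) >= 1 - eps)) {
      clamped <- TRUE
    }
    m_new <- cl(m_new)
    u_new <- cl(u_new)
    p_new <- cl(p_new)

    delta <- max(abs(c(m_new - m, u_new - u, p_new - p)))
    m <- m_new
    u <- u_new
    p <- p_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  params <- structure(list(m = m, u = u, p = p), class = "match_params")
  list(params = params, converged = converged, degenerate = FALSE,
       clamped = clamped, n_iter = it, loglik = loglik)
}
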