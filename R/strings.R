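#' Jaro string similarity
#'
#' Computes the Jaro similarity between pairs of strings: the average of the
#' proportion of common characters in each string and the proportion of common
#' characters that are not transposed. Characters are "common" when they are
#' equal and within half the longer string's length (minus one) of each other;
#' transpositions are counted as half the number of common characters that
#' appear in a different order.
#'
#' The comparison is case sensitive: names are compared as given, without any
#' standardization.
#'
#' @param s1,s2 character vectors, recycled to a common length.
#' @return numeric vector of similarities in `[0, 1]`; `NA` where either input
#'   is `NA`; 0 by convention when either string is empty.
#' @examples
#' jaro("MARTHA", "MARHTA")  # 0.9444...
#' @export
jaro <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.character(s1), n)
  s2 <- rep_len(as.character(s2), n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (is.na(s1[k]) || is.na(s2[k])) {
      out[k] <- NA_real_
    } else {
      out[k] <- .jaro1(utf8ToInt(s1[k]), utf8ToInt(s2[k]))
    }
  }
  out
}

# one pair, on integer codepoint vectors
.jaro1 <- function(x, y) {
  la <- length(x)
  lb <- length(y)
  if (la == 0L || lb == 0L) return(0)
  if (la == lb && all(x == y)) return(1)
  win <- max(0L, max(la, lb) %/% 2L - 1L)
  used <- logical(lb)
  mx <- integer(0L) # common characters in s1 order
  for (i in seq_len(la)) {
    lo <- max(1L, i - win)
    hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!used[j] && y[j] == x[i]) {
        used[j] <- TRUE
        mx <- c(mx, x[i])
        break
      }
    }
  }
  m <- length(mx)
  if (m == 0L) return(0)
  t <- sum(mx != y[used]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

#' Jaro-Winkler string similarity
#'
#' Jaro similarity with a bonus for a common prefix:
#' `jw = jaro + l * prefix_scale * (1 - jaro)` where `l` is the length of the
#' common prefix, capped at `max_prefix`. The prefix bonus is applied
#' unconditionally by default; `boost_threshold` restricts it to pairs whose
#' Jaro similarity reaches the threshold (a dialect found in some
#' implementations).
#'
#' @inheritParams jaro
#' @param prefix_scale scaling factor for the prefix bonus; must lie in
#'   `[0, 0.25]` so the result cannot exceed 1.
#' @param max_prefix maximum prefix length receiving the bonus.
#' @param boost_threshold minimum Jaro similarity required before the prefix
#'   bonus applies; 0 (the default) applies it always.
#' @return numeric vector of similarities in `[0, 1]`, always `>=` the plain
#'   Jaro similarity.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")  # 0.9611...
#' @export
jaro_winkler <- function(s1, s2, prefix_scale = 0.1, max_prefix = 4L,
                         boost_threshold = 0) {
  if (!is.numeric(prefix_scale) || length(prefix_scale) != 1L ||
      is.na(prefix_scale) || prefix_scale < 0 || prefix_scale > 0.25) {
    stop("`prefix_scale` must be a single value in [0, 0.25]", call. = FALSE)
  }
  j <- jaro(s1, s2)
  n <- length(j)
  s1 <- rep_len(as.character(s1), n)
  s2 <- rep_len(as.character(s2), n)
  out <- j
  for (k in seq_len(n)) {
    if (is.na(j[k]) || j[k] < boost_threshold) next
    l <- .common_prefix(s1[k], s2[k], max_prefix)
    out[k] <- j[k] + l * prefix_scale * (1 - j[k])
  }
  out
}

.common_prefix <- function(a, b, cap) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  n <- min(length(x), length(y), cap)
  l <- 0L
  while (l < n && x[l + 1L] == y[l + 1L]) l <- l + 1L
  l
}
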