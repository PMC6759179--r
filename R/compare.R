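#' Blocked candidate-pair generation
#'
#' Returns exactly the cross-source pairs agreeing on a non-missing blocking
#' value (date of birth or year of birth). Pairs where either side's
#' blocking value is missing are excluded, and the count of excluded records
#' is logged. The pair count equals the sum over block values of
#' `n_IPD(v) * n_OPD(v)`.
#'
#' @param ipd,opd record data.frames with the block variable present.
#' @param block_var `"dob"` or `"yob"`.
#' @return data.frame with columns `ipd_record_id`, `opd_record_id`,
#'   `ipd_row`, `opd_row` (row indices into the inputs), and the block value;
#'   attribute `block_log` reports records excluded for missing block values.
#' @export
block_pairs <- function(ipd, opd, block_var = c("dob", "yob")) {
  block_var <- match.arg(block_var)
  if (!block_var %in% names(ipd) || !block_var %in% names(opd)) {
    stop(sprintf("block variable '%s' missing from an input", block_var),
         call. = FALSE)
  }
  ka <- as.character(ipd[[block_var]])
  kb <- as.character(opd[[block_var]])
  a_ok <- which(!is.na(ka))
  b_ok <- which(!is.na(kb))

  a <- split(a_ok, ka[a_ok])
  b <- split(b_ok, kb[b_ok])
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) {
    out <- data.frame(ipd_record_id = character(0),
                      opd_record_id = character(0),
                      ipd_row = integer(0), opd_row = integer(0),
                      block_value = character(0), stringsAsFactors = FALSE)
  } else {
    parts <- lapply(common, function(v) {
      ai <- a[[v]]
      bi <- b[[v]]
      cbind(rep(ai, each = length(bi)), rep(bi, times = length(ai)))
    })
    m <- do.call(rbind, parts)
    out <- data.frame(ipd_record_id = ipd$record_id[m[, 1L]],
                      opd_record_id = opd$record_id[m[, 2L]],
                      ipd_row = m[, 1L], opd_row = m[, 2L],
                      block_value = ka[m[, 1L]],
                      stringsAsFactors = FALSE)
    out <- out[order(out$ipd_row, out$opd_row), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "block_log") <- list(
    ipd_missing_block = sum(is.na(ka)),
    opd_missing_block = sum(is.na(kb)),
    n_pairs = nrow(out))
  out
}

#' Exact field comparison
#'
#' Character-by-character equality, sensitive to capitalization and every
#' other character. Missing on either side propagates to a `missing`
#' outcome.
#'
#' @param a,b character vectors (recycled).
#' @return character vector with values `"agree"`, `"disagree"`, `"missing"`.
#' @export
compare_exact <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- ifelse(is.na(a) | is.na(b), "missing",
                ifelse(a == b, "agree", "disagree"))
  out
}

#' Build per-pair comparison vectors
#'
#' One row per blocked pair. In exact mode each matching field holds the
#' trichotomous outcome `agree`/`disagree`/`missing`. In inexact mode the
#' name fields hold Jaro-Winkler similarities in `[0, 1]` (`NA` when either
#' side is missing) while gender — a one-character field for which string
#' similarity is meaningless — keeps the exact trichotomy.
#'
#' @param pairs output of [block_pairs()].
#' @param ipd,opd the record data.frames the pairs index into.
#' @param fields matching fields; default first name, last name, gender.
#' @param mode `"exact"` or `"inexact"`.
#' @param prefix_scale,max_prefix Jaro-Winkler parameters (inexact mode).
#' @return data.frame with `ipd_record_id`, `opd_record_id` and one column
#'   per field; attribute `mode` records the comparison mode.
#' @export
build_comparison_vectors <- function(pairs, ipd, opd,
                                     fields = c("first_name", "last_name",
                                                "gender"),
                                     mode = c("exact", "inexact"),
                                     prefix_scale = 0.1, max_prefix = 4L) {
  mode <- match.arg(mode)
  out <- data.frame(ipd_record_id = pairs$ipd_record_id,
                    opd_record_id = pairs$opd_record_id,
                    stringsAsFactors = FALSE)
  for (f in fields) {
    a <- as.character(ipd[[f]][pairs$ipd_row])
    b <- as.character(opd[[f]][pairs$opd_row])
    if (mode == "exact" || f == "gender") {
      out[[f]] <- compare_exact(a, b)
    } else {
      out[[f]] <- .jw_pairs(a, b, prefix_scale, max_prefix)
    }
  }
  attr(out, "mode") <- mode
  attr(out, "fields") <- fields
  out
}

# Jaro-Winkler over possibly repeated string pairs: compute once per unique
# pair. Empty strings score 0 by convention; missing propagates NA.
.jw_pairs <- function(a, b, prefix_scale = 0.1, max_prefix = 4L) {
  key <- paste(a, b, sep = "\r")
  key[is.na(a) | is.na(b)] <- NA_character_
  uk <- unique(key[!is.na(key)])
  if (length(uk) == 0L) return(rep(NA_real_, length(a)))
  parts <- strsplit(uk, "\r", fixed = TRUE)
  ua <- vapply(parts, `[`, character(1L), 1L)
  ub <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "",
               character(1L))
  us <- jaro_winkler(ua, ub, prefix_scale = prefix_scale,
                     max_prefix = max_prefix)
  us[match(key, uk)]
}
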