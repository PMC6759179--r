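std_params <- function(u = c(first_name = 1e-4, last_name = 5e-5,
                             gender = 0.5),
                       m = 0.95, p = 0.01) {
  match_params(setNames(rep(m, 3), names(u)), u, p)
}

test_that("default M/U parameters follow the reciprocal-count convention", {
  ds <- data.frame(first_name = c("A", "B", "C", "A", NA),
                   last_name = sprintf("L%03d", 1:5),
                   gender = c("F", "M", "F", "M", "F"),
                   stringsAsFactors = FALSE)
  mp <- default_match_params(ds)
  expect_equal(unname(mp$m), rep(0.95, 3))
  expect_equal(mp$u[["gender"]], 0.5)      # two distinct values
  expect_equal(mp$u[["first_name"]], 1 / 3) # NA not counted
  expect_equal(mp$u[["last_name"]], 1 / 5)
  ds$gender <- "F"
  expect_error(default_match_params(ds), "single distinct value")
})

test_that("match_params validates its probability constraints", {
  expect_error(match_params(c(a = 0.95), c(a = 0.97)), "u must be < m")
  expect_error(match_params(c(a = 1.2), c(a = 0.1)), "inside")
  expect_error(match_params(c(a = 0.9), c(a = 0.1), p = 0), "p")
})

test_that("single-field FS weights match their closed forms", {
  mp <- match_params(c(gender = 0.95), c(gender = 0.5))
  v <- function(o) {
    df <- data.frame(gender = o, stringsAsFactors = FALSE)
    attr(df, "fields") <- "gender"
    df
  }
  expect_equal(fs_weight(v("agree"), mp), log2(0.95 / 0.5),
               tolerance = 1e-12)   # ~0.926 bits
  expect_equal(fs_weight(v("disagree"), mp), log2(0.05 / 0.5),
               tolerance = 1e-12)   # ~ -3.322 bits
  expect_equal(fs_weight(v("missing"), mp), 0) # zero-contribution default
})

test_that("a missing field outranks a full disagreement under zero-contribution", {
  mp <- std_params()
  w_missing_gender <- fs_weight(
    make_exact_vectors(c("disagree", "disagree", "missing")), mp)
  w_all_disagree <- fs_weight(
    make_exact_vectors(c("disagree", "disagree", "disagree")), mp)
  expect_gt(w_missing_gender, w_all_disagree)
  # under the disagreement policy the two collapse
  prof <- run_profile("x", "exact", "FS", "disagreement")
  expect_equal(
    fs_weight(make_exact_vectors(c("disagree", "disagree", "missing")),
              mp, prof),
    fs_weight(make_exact_vectors(c("disagree", "disagree", "disagree")),
              mp, prof))
})

test_that("FS weights equal brute-force summation on all 27 patterns", {
  mp <- std_params()
  pats <- expand.grid(first_name = c("agree", "disagree", "missing"),
                      last_name = c("agree", "disagree", "missing"),
                      gender = c("agree", "disagree", "missing"),
                      stringsAsFactors = FALSE)
  attr(pats, "fields") <- names(pats)
  for (policy in c("zero_contribution", "disagreement")) {
    prof <- run_profile("x", "exact", "FS", policy)
    got <- fs_weight(pats, mp, prof)
    want <- vapply(seq_len(nrow(pats)),
                   function(i) fs_oracle(pats[i, ], mp$m, mp$u, policy),
                   numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("flipping disagree to agree strictly increases the FS weight", {
  mp <- std_params()
  pats <- all_complete_patterns()
  w <- fs_weight(pats, mp)
  for (i in seq_len(nrow(pats))) {
    for (f in names(pats)) {
      if (pats[i, f] == "disagree") {
        flipped <- pats[i, ]
        flipped[[f]] <- "agree"
        expect_gt(fs_weight(flipped, mp), w[i])
      }
    }
  }
})

test_that("complete patterns yield 8 distinct FS weights, plus one with gender missing", {
  mp <- std_params()
  w8 <- fs_weight(all_complete_patterns(), mp)
  expect_equal(length(unique(w8)), 8)
  with_missing <- rbind(all_complete_patterns(),
                        c("disagree", "disagree", "missing"))
  attr(with_missing, "fields") <- names(with_missing)
  w9 <- fs_weight(with_missing, mp)
  expect_equal(length(unique(w9)), 9)
})

test_that("FS ranks agreement patterns in the field-priority order", {
  # u_last < u_first < u_gender: surname agreement carries the most weight
  mp <- std_params()
  pat <- list(c("agree", "agree", "agree"),     # First, Last, Gender
              c("agree", "agree", "disagree"),  # First, Last
              c("disagree", "agree", "agree"),  # Last, Gender
              c("agree", "disagree", "agree"),  # First, Gender
              c("disagree", "agree", "disagree"), # Last
              c("agree", "disagree", "disagree"), # First
              c("disagree", "disagree", "agree"), # Gender
              c("disagree", "disagree", "disagree")) # None
  w <- fs_weight(do.call(make_exact_vectors, pat), mp)
  expect_equal(order(w, decreasing = TRUE), 1:8)
})

test_that("similarity conversion dialects behave as declared", {
  mp <- std_params()
  vi <- data.frame(first_name = c(0.97, 0.90), last_name = c(1, 1),
                   gender = c("agree", "agree"), stringsAsFactors = FALSE)
  attr(vi, "fields") <- names(vi)
  thr <- run_profile("t", "inexact", "FS", inexact_conversion =
                       "threshold_binary", similarity_threshold = 0.95)
  w_thr <- fs_weight(vi, mp, thr)
  # 0.97 binarizes to agreement, 0.90 to disagreement
  expect_equal(w_thr[1],
               fs_weight(make_exact_vectors(c("agree", "agree", "agree")),
                         mp))
  expect_equal(w_thr[2],
               fs_weight(make_exact_vectors(c("disagree", "agree", "agree")),
                         mp))
  itp <- run_profile("i", "inexact", "FS", inexact_conversion = "interpolate")
  w_itp <- fs_weight(vi, mp, itp)
  wa <- log2(mp$m[["first_name"]] / mp$u[["first_name"]])
  wd <- log2((1 - mp$m[["first_name"]]) / (1 - mp$u[["first_name"]]))
  base <- fs_weight(make_exact_vectors(c("agree", "agree", "agree")), mp) - wa
  expect_equal(w_itp[1], base + 0.97 * wa + 0.03 * wd, tolerance = 1e-12)
  # similarities outside [0, 1] are rejected
  bad <- vi
  bad$first_name <- c(1.2, 0.5)
  expect_error(fs_weight(bad, mp, itp), "outside")
})

test_that("EpiLink weights hit the documented extremes and plug-in value", {
  ep <- epilink_params(e = c(a = 0.05, b = 0.05, c = 0.05),
                       f = c(a = 0.25, b = 0.0625, c = 0.5))
  v <- function(...) {
    df <- as.data.frame(rbind(c(...)), stringsAsFactors = FALSE)
    names(df) <- c("a", "b", "c")
    attr(df, "fields") <- names(df)
    df
  }
  expect_equal(as.numeric(epilink_weight(v("agree", "agree", "agree"), ep)), 1)
  expect_equal(as.numeric(
    epilink_weight(v("disagree", "disagree", "disagree"), ep)), 0)
  # s = (1, 0, 1) with weights (2, 4, 1) -> 3/7
  ep2 <- epilink_params(e = c(a = 0.05, b = 0.05, c = 0.05),
                        f = c(a = 0.95 / 4, b = 0.95 / 16, c = 0.95 / 2))
  expect_equal(unname(ep2$w), c(2, 4, 1))
  expect_equal(as.numeric(epilink_weight(v("agree", "disagree", "agree"),
                                         ep2)),
               3 / 7, tolerance = 1e-12)
  # missing fields drop from numerator and denominator
  expect_equal(as.numeric(epilink_weight(v("agree", "missing", "disagree"),
                                         ep2)),
               2 / 3, tolerance = 1e-12)
  all_na <- epilink_weight(v("missing", "missing", "missing"), ep2)
  expect_true(is.na(as.numeric(all_na)))
  expect_equal(attr(all_na, "epilink_log")$all_missing, 1)
})

test_that("EpiLink weights stay inside [0, 1] on random inputs", {
  set.seed(5)
  ep <- epilink_from_match_params(std_params())
  pats <- expand.grid(first_name = c("agree", "disagree", "missing"),
                      last_name = c("agree", "disagree", "missing"),
                      gender = c("agree", "disagree", "missing"),
                      stringsAsFactors = FALSE)
  attr(pats, "fields") <- names(pats)
  w <- as.numeric(epilink_weight(pats, ep))
  expect_true(all(w[!is.na(w)] >= 0 & w[!is.na(w)] <= 1))
})

test_that("deterministic weights count exact agreements from 0 to 3", {
  pats <- all_complete_patterns()
  w <- deterministic_weight(pats)
  expect_equal(max(w), 3)
  expect_equal(min(w), 0)
  expect_equal(length(unique(w)), 4)
  expect_equal(deterministic_weight(
    make_exact_vectors(c("agree", "disagree", "missing"))), 1)
  # inexact: threshold count and fractional sum
  vi <- data.frame(first_name = 0.97, last_name = 0.5, gender = "agree",
                   stringsAsFactors = FALSE)
  attr(vi, "fields") <- names(vi)
  expect_equal(deterministic_weight(vi, threshold = 0.95), 2)
  expect_equal(deterministic_weight(vi, fractional = TRUE), 2.47)
})

test_that("probabilistic families split the 8 complete patterns apart", {
  # FS, EM-style (FS with estimated params), and EpiLink give 8 distinct
  # values over the complete patterns; deterministic collapses them to 4
  mp <- std_params()
  pats <- all_complete_patterns()
  expect_equal(length(unique(fs_weight(pats, mp))), 8)
  expect_equal(length(unique(as.numeric(
    epilink_weight(pats, epilink_from_match_params(mp))))), 8)
  expect_equal(length(unique(deterministic_weight(pats))), 4)
})

test_that("the default run matrix matches its declared structure", {
  rm <- default_run_matrix()
  expect_length(rm, 17)
  nms <- vapply(rm, `[[`, character(1), "name")
  expect_false(anyDuplicated(nms) > 0)
  modes <- vapply(rm, `[[`, character(1), "string_mode")
  expect_equal(sum(modes == "exact"), 9)
  expect_equal(sum(modes == "inexact"), 8)
  methods <- vapply(rm, `[[`, character(1), "method")
  expect_true(all(modes[methods == "EPI"] == "exact"))
  expect_equal(sum(vapply(rm, `[[`, logical(1), "positive_only_output")), 2)
})

test_that("profile constraints are enforced", {
  expect_error(run_profile("x", "inexact", "EPI"), "exact")
  expect_error(run_profile("x", similarity_threshold = 1.5), "threshold")
})
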