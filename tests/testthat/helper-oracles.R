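# Independent oracles used to cross-check the package implementations.
# Each is written directly from the textbook definition, on a different code
# path from the functions it checks.

# Jaro similarity from the definition, character-vector flags version
jaro_oracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(x)
  lb <- length(y)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  fx <- rep(FALSE, la)
  fy <- rep(FALSE, lb)
  for (i in seq_len(la)) {
    if (max(1, i - win) > min(lb, i + win)) next
    for (j in seq(max(1, i - win), min(lb, i + win))) {
      if (!fy[j] && x[i] == y[j]) {
        fx[i] <- TRUE
        fy[j] <- TRUE
        break
      }
    }
  }
  m <- sum(fx)
  if (m == 0) return(0)
  t <- sum(x[fx] != y[fy]) / 2
  mean(c(m / la, m / lb, (m - t) / m))
}

jw_oracle <- function(a, b, p = 0.1, maxl = 4) {
  j <- jaro_oracle(a, b)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  l <- 0
  while (l < min(length(x), length(y), maxl) && x[l + 1] == y[l + 1]) {
    l <- l + 1
  }
  j + l * p * (1 - j)
}

# optimal string alignment (restricted Damerau-Levenshtein) distance
osa_dist <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(x)
  lb <- length(y)
  d <- matrix(0, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cost <- as.integer(x[i] != y[j])
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1, d[i, j] + cost)
      if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1)
      }
    }
  }
  d[la + 1, lb + 1]
}

# AUC as the Mann-Whitney statistic: brute force over all label-1 x label-0
# pairs with the 1/2 tie convention; NA weights rank below everything
auc_mw_oracle <- function(w, labels) {
  w[is.na(w)] <- -Inf
  w1 <- w[labels == 1]
  w0 <- w[labels == 0]
  tot <- 0
  for (a in w1) tot <- tot + sum(a > w0) + 0.5 * sum(a == w0)
  tot / (length(w1) * length(w0))
}

# Fellegi-Sunter weight by explicit per-field lookup and summation
fs_oracle <- function(outcomes, m, u, missing_policy = "zero_contribution") {
  tot <- 0
  for (f in names(outcomes)) {
    o <- outcomes[[f]]
    wa <- log2(m[f] / u[f])
    wd <- log2((1 - m[f]) / (1 - u[f]))
    tot <- tot + switch(o,
      agree = wa,
      disagree = wd,
      missing = if (missing_policy == "disagreement") wd else 0)
  }
  unname(tot)
}

# build a comparison-vector data.frame from a matrix/list of trichotomous
# outcomes on the three standard fields
make_exact_vectors <- function(...) {
  pat <- list(...)
  df <- as.data.frame(do.call(rbind, pat), stringsAsFactors = FALSE)
  names(df) <- c("first_name", "last_name", "gender")
  attr(df, "mode") <- "exact"
  attr(df, "fields") <- names(df)
  df
}

# all 2^3 complete agreement patterns on the three standard fields
all_complete_patterns <- function() {
  g <- expand.grid(first_name = c("agree", "disagree"),
                   last_name = c("agree", "disagree"),
                   gender = c("agree", "disagree"),
                   stringsAsFactors = FALSE)
  attr(g, "mode") <- "exact"
  attr(g, "fields") <- names(g)
  g
}

# sample comparison vectors from a known two-class mixture (for EM recovery)
simulate_vectors <- function(n, p, m, u) {
  match <- runif(n) < p
  g <- sapply(seq_along(m), function(j) {
    pr <- ifelse(match, m[j], u[j])
    as.integer(runif(n) < pr)
  })
  df <- as.data.frame(ifelse(g == 1L, "agree", "disagree"),
                      stringsAsFactors = FALSE)
  names(df) <- names(m)
  attr(df, "mode") <- "exact"
  attr(df, "fields") <- names(df)
  list(vectors = df, match = match)
}

random_name <- function(len_range = 3:10) {
  paste(sample(LETTERS, sample(len_range, 1), replace = TRUE), collapse = "")
}
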