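#' Configuration for the synthetic identifier generator
#'
#' Builds and validates the parameter set controlling the paired
#' inpatient/outpatient synthetic datasets. Defaults emulate the structure of
#' a real two-institution EHR pairing at desk scale: an inpatient dataset with
#' one row per admission (so repeatedly admitted persons appear several times)
#' and an outpatient dataset with exactly one row per person; name typos;
#' newborn placeholder first names ("Male"/"Female") with a maternal surname
#' on the inpatient side; inconsistently represented compound surnames;
#' occasional missing gender; and a medical-record-number (MRN) gold standard
#' that itself carries a small error rate split across different-MRN, missing
#' MRN, and misassigned-MRN channels.
#'
#' @param n_persons number of latent persons in the population.
#' @param overlap_fraction proportion of persons present in both sources; the
#'   remainder is split evenly between inpatient-only and outpatient-only.
#' @param admission_rate mean admissions per inpatient person (>= 1); each
#'   person contributes `1 + Poisson(admission_rate - 1)` inpatient rows.
#' @param typo_rate_per_field probability that a name field on an inpatient
#'   row receives one random character edit.
#' @param newborn_fraction proportion of persons aged < 1 whose inpatient rows
#'   use the placeholder first name "Male"/"Female" and a maternal surname.
#' @param compound_surname_rate probability that an inpatient row renders the
#'   surname as an inconsistent compound variant.
#' @param missing_gender_rate probability that a row's gender is missing.
#' @param mrn_error_rate probability that an overlapping person's outpatient
#'   MRN is corrupted (the gold-standard error rate).
#' @param mrn_error_split length-3 probability vector naming the corruption
#'   channels `different`, `missing`, `misassigned`.
#' @param opd_missing_mrn_fraction probability that an outpatient-only
#'   person's inpatient MRN is missing (they may never have been admitted).
#' @param name_zipf_exponent exponent of the Zipf law ranking both name
#'   pools; larger values concentrate mass on the top-ranked names.
#' @param first_name_pool,last_name_pool sizes of the ranked name pools; the
#'   defaults make surnames more diverse than first names.
#' @param age_band_weights named numeric vector of sampling weights over the
#'   age bands `<1, 1-9, ..., 80-89, 90+`; the default has an infant mode so
#'   the newborn channel is populated.
#' @param reference_date date at which ages are computed.
#' @param age_cap upper limit applied to recorded ages.
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_persons = 20000L,
                             overlap_fraction = 0.3,
                             admission_rate = 1.5,
                             typo_rate_per_field = 0.02,
                             newborn_fraction = 0.1,
                             compound_surname_rate = 0.02,
                             missing_gender_rate = 0.002,
                             mrn_error_rate = 0.0075,
                             mrn_error_split = c(different = 0.77,
                                                 missing = 0.22,
                                                 misassigned = 0.01),
                             opd_missing_mrn_fraction = 0.9,
                             name_zipf_exponent = 1.1,
                             first_name_pool = 2000L,
                             last_name_pool = 20000L,
                             age_band_weights = c("0" = 0.118, "1" = 0.045,
                                                  "10" = 0.050, "20" = 0.086,
                                                  "30" = 0.099, "40" = 0.087,
                                                  "50" = 0.129, "60" = 0.142,
                                                  "70" = 0.121, "80" = 0.096,
                                                  "90" = 0.027),
                             reference_date = as.Date("2015-12-31"),
                             age_cap = 90L,
                             seed = 1L) {
  cfg <- list(n_persons = n_persons, overlap_fraction = overlap_fraction,
              admission_rate = admission_rate,
              typo_rate_per_field = typo_rate_per_field,
              newborn_fraction = newborn_fraction,
              compound_surname_rate = compound_surname_rate,
              missing_gender_rate = missing_gender_rate,
              mrn_error_rate = mrn_error_rate,
              mrn_error_split = mrn_error_split,
              opd_missing_mrn_fraction = opd_missing_mrn_fraction,
              name_zipf_exponent = name_zipf_exponent,
              first_name_pool = as.integer(first_name_pool),
              last_name_pool = as.integer(last_name_pool),
              age_band_weights = age_band_weights,
              reference_date = as.Date(reference_date),
              age_cap = as.integer(age_cap),
              seed = as.integer(seed))
  .validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

.validate_generator_config <- function(cfg) {
  chk_rate <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", name),
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1L ||
      is.na(cfg$n_persons) || cfg$n_persons < 1) {
    stop("`n_persons` must be a positive integer", call. = FALSE)
  }
  for (nm in c("overlap_fraction", "typo_rate_per_field", "newborn_fraction",
               "compound_surname_rate", "missing_gender_rate",
               "mrn_error_rate", "opd_missing_mrn_fraction")) {
    chk_rate(nm)
  }
  if (!is.numeric(cfg$admission_rate) || cfg$admission_rate < 1) {
    stop("`admission_rate` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$name_zipf_exponent) || cfg$name_zipf_exponent <= 0) {
    stop("`name_zipf_exponent` must be a positive real", call. = FALSE)
  }
  s <- cfg$mrn_error_split
  if (length(s) != 3L || any(s < 0) || abs(sum(s) - 1) > 1e-8) {
    stop("`mrn_error_split` must be 3 non-negative shares summing to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

# deterministic synthetic name pool: pronounceable two/three-syllable tokens,
# upper case, unique within the pool
.make_name_pool <- function(n, prefix_caps = TRUE) {
  onsets <- c("B", "BR", "C", "CH", "D", "F", "G", "GR", "H", "J", "K", "L",
              "M", "N", "P", "R", "S", "SH", "ST", "T", "TH", "V", "W", "Z")
  vowels <- c("A", "E", "I", "O", "U", "AI", "EE", "IA", "OU")
  codas <- c("", "N", "R", "S", "L", "M", "T", "CK", "RD", "NS")
  pool <- character(0L)
  k <- 2L
  while (length(pool) < n) {
    syl <- function() paste0(sample(onsets, 1L), sample(vowels, 1L),
                             sample(codas, 1L))
    cand <- vapply(seq_len(2L * (n - length(pool)) + 16L),
                   function(i) paste0(replicate(k, syl()), collapse = ""),
                   character(1L))
    pool <- unique(c(pool, cand))
    k <- if (k >= 4L) 2L else k + 1L
  }
  pool[seq_len(n)]
}

.zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

#' Generate the latent person population
#'
#' Draws `n_persons` latent persons with true identifier values: names from
#' Zipf-ranked pools (surnames more diverse than first names), gender, a date
#' of birth implied by an age-band mixture with an infant mode, race, ZIP
#' code, a unique true MRN, and source membership (inpatient, outpatient or
#' both) controlled by `overlap_fraction`.
#'
#' @param config a [generator_config()].
#' @return data.frame of latent persons with columns `true_person_id`,
#'   `first_name`, `last_name`, `gender`, `dob`, `yob`, `age`, `race`, `zip`,
#'   `mrn`, `in_ipd`, `in_opd`, `newborn_alias`, `maternal_surname`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_persons)

  first_pool <- .make_name_pool(config$first_name_pool)
  last_pool <- .make_name_pool(config$last_name_pool)
  first_name <- sample(first_pool, n, replace = TRUE,
                       prob = .zipf_probs(config$first_name_pool,
                                          config$name_zipf_exponent))
  last_name <- sample(last_pool, n, replace = TRUE,
                      prob = .zipf_probs(config$last_name_pool,
                                         config$name_zipf_exponent))

  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.53, 0.47))

  bands <- as.integer(names(config$age_band_weights))
  band <- sample(bands, n, replace = TRUE, prob = config$age_band_weights)
  band_width <- ifelse(band == 0L, 1L, ifelse(band == 1L, 9L, 10L))
  # dob uniform within the band's date window, age recomputed from dob
  days_back <- round(band * 365.25 +
                       stats::runif(n, 0, band_width * 365.25 - 1))
  dob <- config$reference_date - days_back
  age <- pmin(.age_at(dob, config$reference_date), config$age_cap)
  yob <- as.integer(format(dob, "%Y"))

  race <- sample(c("Asian", "black", "white", "other", NA_character_), n,
                 replace = TRUE, prob = c(0.09, 0.13, 0.55, 0.20, 0.03))
  zip_pool <- sprintf("%05d", sample.int(99999L, 120L))
  zip <- sample(zip_pool, n, replace = TRUE)
  zip[stats::runif(n) < 0.01] <- NA_character_

  mrn <- sprintf("M%07d", sample.int(9999999L, n))

  # source membership: overlap first, remainder split between the sources
  n_both <- round(n * config$overlap_fraction)
  n_ipd_only <- floor((n - n_both) / 2)
  memb <- sample(rep(c("both", "ipd", "opd"),
                     c(n_both, n_ipd_only, n - n_both - n_ipd_only)))
  in_ipd <- memb %in% c("both", "ipd")
  in_opd <- memb %in% c("both", "opd")

  # newborn channel decided per person among infants
  newborn_alias <- age < 1 & stats::runif(n) < config$newborn_fraction
  maternal_surname <- rep(NA_character_, n)
  if (any(newborn_alias)) {
    ms <- sample(last_pool, sum(newborn_alias), replace = TRUE,
                 prob = .zipf_probs(config$last_name_pool,
                                    config$name_zipf_exponent))
    # the maternal surname must differ from the child's registered one
    own <- last_name[newborn_alias]
    clash <- ms == own
    while (any(clash)) {
      ms[clash] <- sample(last_pool, sum(clash), replace = TRUE)
      clash <- ms == own
    }
    maternal_surname[newborn_alias] <- ms
  }

  data.frame(true_person_id = sprintf("P%06d", seq_len(n)),
             first_name = first_name, last_name = last_name,
             gender = gender, dob = dob, yob = yob, age = age,
             race = race, zip = zip, mrn = mrn,
             in_ipd = in_ipd, in_opd = in_opd,
             newborn_alias = newborn_alias,
             maternal_surname = maternal_surname,
             stringsAsFactors = FALSE)
}

.age_at <- function(dob, ref) {
  as.integer(floor(as.numeric(ref - dob) / 365.25))
}

#' Apply one character-level corruption to a string
#'
#' Performs exactly one edit of the named channel: substitute a character
#' (always with a different one), insert a character, delete a character, or
#' transpose two adjacent (differing) characters. Position and replacement
#' character are drawn from R's random stream unless given.
#'
#' @param value a single non-`NA` string; must be non-empty for
#'   `substitute`/`delete`/`transpose` and of length >= 2 for `transpose`.
#' @param channel one of `"substitute"`, `"insert"`, `"delete"`,
#'   `"transpose"`.
#' @param alphabet character vector of single characters to draw from.
#' @param pos optional 1-based position of the edit (for `insert`, 0 means
#'   prepend).
#' @param char optional replacement/insertion character.
#' @return the corrupted string, differing from `value` by exactly one edit
#'   of the named channel.
#' @export
corrupt_field <- function(value,
                          channel = c("substitute", "insert", "delete",
                                      "transpose"),
                          alphabet = LETTERS, pos = NULL, char = NULL) {
  channel <- match.arg(channel)
  if (length(value) != 1L || is.na(value)) {
    stop("`value` must be a single non-missing string", call. = FALSE)
  }
  ch <- strsplit(value, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n == 0L && channel != "insert") {
    stop(sprintf("cannot apply channel '%s' to an empty string", channel),
         call. = FALSE)
  }
  switch(channel,
    substitute = {
      i <- if (is.null(pos)) sample.int(n, 1L) else as.integer(pos)
      repl <- if (is.null(char)) sample(setdiff(alphabet, ch[i]), 1L) else char
      if (identical(repl, ch[i])) {
        stop("substitution must change the character", call. = FALSE)
      }
      ch[i] <- repl
      paste(ch, collapse = "")
    },
    insert = {
      i <- if (is.null(pos)) sample.int(n + 1L, 1L) - 1L else as.integer(pos)
      repl <- if (is.null(char)) sample(alphabet, 1L) else char
      paste(c(ch[seq_len(i)], repl, if (i < n) ch[(i + 1L):n]),
            collapse = "")
    },
    delete = {
      i <- if (is.null(pos)) sample.int(n, 1L) else as.integer(pos)
      paste(ch[-i], collapse = "")
    },
    transpose = {
      if (n < 2L) {
        stop("cannot transpose a string of length < 2", call. = FALSE)
      }
      ok <- which(ch[-n] != ch[-1L])
      if (length(ok) == 0L) {
        stop("no adjacent differing characters to transpose", call. = FALSE)
      }
      i <- if (is.null(pos)) ok[sample.int(length(ok), 1L)] else as.integer(pos)
      ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
      paste(ch, collapse = "")
    })
}

# one random typo on each element of x (vectorized helper)
.apply_typos <- function(x, alphabet = LETTERS) {
  vapply(x, function(v) {
    n <- nchar(v)
    channels <- c("substitute", "insert", "delete", "transpose")
    if (n < 2L) channels <- c("substitute", "insert", "delete")
    if (n < 1L) channels <- "insert"
    repeat {
      chan <- sample(channels, 1L)
      out <- tryCatch(corrupt_field(v, chan, alphabet),
                      error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
  }, character(1L), USE.NAMES = FALSE)
}

.compound_variant <- function(x, pool) {
  vapply(x, function(v) {
    if (grepl("-", v, fixed = TRUE)) {
      strsplit(v, "-", fixed = TRUE)[[1]][1]
    } else {
      paste0(v, "-", sample(pool, 1L))
    }
  }, character(1L), USE.NAMES = FALSE)
}

#' Derive the inpatient dataset (IPD)
#'
#' Each person marked as inpatient contributes one row per admission
#' (`1 + Poisson(admission_rate - 1)` rows). Rows then pass independently
#' through the error channels: newborn placeholder naming (first name
#' "Male"/"Female" with a maternal surname), compound-surname variants, name
#' typos, and missing gender. The inpatient MRN is always present and equals
#' the person's true MRN; the hidden `true_person_id` is retained for oracle
#' evaluation only.
#'
#' @param persons output of [generate_population()].
#' @param config the same [generator_config()].
#' @return data.frame of inpatient records with columns `record_id`,
#'   `source`, `first_name`, `last_name`, `gender`, `dob`, `yob`, `age`,
#'   `race`, `zip`, `mrn`, `true_person_id`.
#' @export
derive_inpatient <- function(persons, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  sel <- persons[persons$in_ipd, , drop = FALSE]
  n_adm <- 1L + stats::rpois(nrow(sel), config$admission_rate - 1)
  idx <- rep(seq_len(nrow(sel)), n_adm)
  rec <- sel[idx, , drop = FALSE]
  m <- nrow(rec)

  first <- rec$first_name
  last <- rec$last_name

  # newborn placeholder naming (per person; applied to all their IPD rows)
  nb <- rec$newborn_alias
  if (any(nb)) {
    g <- rec$gender[nb]
    g[is.na(g)] <- sample(c("F", "M"), sum(is.na(g)), replace = TRUE)
    first[nb] <- ifelse(g == "F", "Female", "Male")
    last[nb] <- rec$maternal_surname[nb]
  }

  comp <- !nb & stats::runif(m) < config$compound_surname_rate
  if (any(comp)) {
    pool <- .make_name_pool(64L)
    last[comp] <- .compound_variant(last[comp], pool)
  }

  typo_f <- stats::runif(m) < config$typo_rate_per_field
  if (any(typo_f)) first[typo_f] <- .apply_typos(first[typo_f])
  typo_l <- stats::runif(m) < config$typo_rate_per_field
  if (any(typo_l)) last[typo_l] <- .apply_typos(last[typo_l])

  gender <- rec$gender
  gender[stats::runif(m) < config$missing_gender_rate] <- NA_character_

  data.frame(record_id = sprintf("I%07d", seq_len(m)),
             source = "IPD",
             first_name = first, last_name = last, gender = gender,
             dob = rec$dob, yob = rec$yob, age = rec$age, race = rec$race,
             zip = rec$zip, mrn = rec$mrn,
             true_person_id = rec$true_person_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive the outpatient dataset (OPD)
#'
#' Exactly one row per person marked as outpatient, carrying the person's
#' true names (newborn aliases are an inpatient phenomenon). The inpatient
#' MRN column is corrupted two ways: outpatient-only persons lack an
#' inpatient MRN with probability `opd_missing_mrn_fraction`, and overlapping
#' persons hit the gold-standard error channels with probability
#' `mrn_error_rate` (a different MRN, a missing MRN, or another inpatient
#' person's MRN, per `mrn_error_split`).
#'
#' @inheritParams derive_inpatient
#' @return data.frame of outpatient records, one row per person, same columns
#'   as [derive_inpatient()].
#' @export
derive_outpatient <- function(persons, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  rec <- persons[persons$in_opd, , drop = FALSE]
  m <- nrow(rec)
  mrn <- rec$mrn

  # background missingness: persons never admitted have no inpatient MRN
  only_opd <- !rec$in_ipd
  drop_bg <- only_opd & stats::runif(m) < config$opd_missing_mrn_fraction
  mrn[drop_bg] <- NA_character_

  # gold-standard corruption among persons present in both sources
  both <- rec$in_ipd
  hit <- both & stats::runif(m) < config$mrn_error_rate
  if (any(hit)) {
    chan <- sample(names(config$mrn_error_split), sum(hit), replace = TRUE,
                   prob = config$mrn_error_split)
    w <- which(hit)
    mrn[w[chan == "different"]] <-
      sprintf("X%07d", sample.int(9999999L, sum(chan == "different")))
    mrn[w[chan == "missing"]] <- NA_character_
    mis <- w[chan == "misassigned"]
    if (length(mis)) {
      donors <- persons$mrn[persons$in_ipd]
      mrn[mis] <- sample(donors, length(mis), replace = TRUE)
    }
  }

  gender <- rec$gender
  gender[stats::runif(m) < config$missing_gender_rate] <- NA_character_

  data.frame(record_id = sprintf("O%07d", seq_len(m)),
             source = "OPD",
             first_name = rec$first_name, last_name = rec$last_name,
             gender = gender, dob = rec$dob, yob = rec$yob, age = rec$age,
             race = rec$race, zip = rec$zip, mrn = mrn,
             true_person_id = rec$true_person_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a full synthetic scenario
#'
#' Convenience wrapper: population, inpatient and outpatient datasets, and
#' the record-to-truth sidecar, all from one config.
#'
#' @param config a [generator_config()].
#' @return list with elements `persons`, `ipd`, `opd`, `truth` (data.frame
#'   `record_id`, `source`, `true_person_id`).
#' @export
generate_scenario <- function(config = generator_config()) {
  persons <- generate_population(config)
  ipd <- derive_inpatient(persons, config)
  opd <- derive_outpatient(persons, config)
  truth <- rbind(ipd[, c("record_id", "source", "true_person_id")],
                 opd[, c("record_id", "source", "true_person_id")])
  list(persons = persons, ipd = ipd, opd = opd, truth = truth)
}

#' Write a generated dataset to CSV
#'
#' UTF-8, header row, missing values encoded as empty fields. The hidden
#' `true_person_id` column is written to a sidecar file, not to the linkage
#' input.
#'
#' @param records a dataset from [derive_inpatient()]/[derive_outpatient()].
#' @param path output CSV path.
#' @param sidecar_path optional path for the `record_id` to `true_person_id`
#'   map.
#' @return `path`, invisibly.
#' @export
write_linkage_csv <- function(records, path, sidecar_path = NULL) {
  pub <- records[, setdiff(names(records), "true_person_id"), drop = FALSE]
  utils::write.csv(pub, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  if (!is.null(sidecar_path)) {
    utils::write.csv(records[, c("record_id", "true_person_id")],
                     sidecar_path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a linkage dataset written by [write_linkage_csv()]
#'
#' @param path CSV path.
#' @return data.frame with `dob` parsed as `Date` and empty fields as `NA`.
#' @export
read_linkage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  if ("dob" %in% names(df)) df$dob <- as.Date(df$dob)
  for (nm in intersect(c("yob", "age"), names(df))) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  df
}
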