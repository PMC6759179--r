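#' Field harmonization schema
#'
#' Recode tables and plausibility rules applied before linkage: gender and
#' race recodes (recode tables are functions of the raw value — duplicate
#' keys are rejected), missing-value sentinels, and a ZIP plausibility rule
#' (5 digits). Names are deliberately left untouched: no case folding, no
#' suffix stripping, no nickname lookup.
#'
#' @param gender_map named character vector mapping raw gender codes to
#'   `"F"`/`"M"`.
#' @param race_map named character vector collapsing raw race values to
#'   `Asian`/`black`/`white`/`other`.
#' @param missing_sentinels raw values treated as missing in every field.
#' @param zip_pattern regular expression a plausible ZIP must match.
#' @return object of class `schema_map`.
#' @export
schema_map <- function(gender_map = c("F" = "F", "M" = "M",
                                      "FEMALE" = "F", "MALE" = "M",
                                      "1" = "M", "2" = "F"),
                       race_map = c("Asian" = "Asian", "black" = "black",
                                    "white" = "white", "other" = "other",
                                    "ASIAN" = "Asian", "BLACK" = "black",
                                    "WHITE" = "white", "OTHER" = "other"),
                       missing_sentinels = c("", "NA", "UNK", "UNKNOWN"),
                       zip_pattern = "^[0-9]{5}$") {
  if (anyDuplicated(names(gender_map)) || anyDuplicated(names(race_map))) {
    stop("recode tables must not contain duplicate keys", call. = FALSE)
  }
  structure(list(gender_map = gender_map, race_map = race_map,
                 missing_sentinels = missing_sentinels,
                 zip_pattern = zip_pattern),
            class = "schema_map")
}

#' Harmonize field coding across sources
#'
#' Applies the schema's recodes and plausibility rules: gender and race are
#' recoded (unknown codes become missing, with a logged count), implausible
#' ZIP codes (anything but 5 digits, e.g. containing letters) are set
#' missing, and year of birth is re-extracted from the date of birth where
#' present. Names pass through unchanged.
#'
#' @param records a PersonRecord data.frame.
#' @param schema a [schema_map()].
#' @return the harmonized data.frame, with a `harmonize_log` attribute
#'   holding counts of recoded-to-missing values.
#' @export
harmonize <- function(records, schema = schema_map()) {
  stopifnot(inherits(schema, "schema_map"))
  out <- records
  log <- list()

  blank_out <- function(x) {
    x[x %in% schema$missing_sentinels] <- NA_character_
    x
  }
  for (nm in intersect(c("first_name", "last_name", "gender", "race", "zip",
                         "mrn"), names(out))) {
    out[[nm]] <- blank_out(as.character(out[[nm]]))
  }

  if ("gender" %in% names(out)) {
    raw <- out$gender
    mapped <- unname(schema$gender_map[raw])
    unknown <- !is.na(raw) & is.na(mapped)
    log$gender_unknown <- sum(unknown)
    out$gender <- mapped
  }
  if ("race" %in% names(out)) {
    raw <- out$race
    mapped <- unname(schema$race_map[raw])
    unknown <- !is.na(raw) & is.na(mapped)
    log$race_unknown <- sum(unknown)
    out$race <- mapped
  }
  if ("zip" %in% names(out)) {
    bad <- !is.na(out$zip) & !grepl(schema$zip_pattern, out$zip)
    log$zip_implausible <- sum(bad)
    out$zip[bad] <- NA_character_
  }
  if (all(c("dob", "yob") %in% names(out))) {
    has_dob <- !is.na(out$dob)
    out$yob[has_dob] <- as.integer(format(as.Date(out$dob[has_dob]), "%Y"))
  }
  attr(out, "harmonize_log") <- log
  out
}

#' Deduplicate a record dataset on the exact key set
#'
#' Removes rows that match exactly on the key fields (by default MRN, last
#' name, first name, gender, YOB, race, and ZIP; two missing values count as
#' equal). A row whose only difference from another is a missing ZIP is
#' dropped when that other row carries a valid ZIP. Among exact duplicates
#' the row with the lowest `record_id` survives, and the output is ordered
#' by `record_id`.
#'
#' @param records a harmonized data.frame with a `record_id` column.
#' @param key character vector of key fields.
#' @return the deduplicated data.frame, with a `dedup_log` attribute holding
#'   rows in/out and per-rule drop counts.
#' @export
deduplicate <- function(records,
                        key = c("mrn", "last_name", "first_name", "gender",
                                "yob", "race", "zip")) {
  if (nrow(records) == 0L) return(records)
  stopifnot(all(key %in% names(records)), "record_id" %in% names(records))
  records <- records[order(records$record_id), , drop = FALSE]

  keystr <- function(cols) {
    vals <- lapply(records[cols], function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "\r<NA>"
      x
    })
    do.call(paste, c(vals, sep = "\r"))
  }

  n_in <- nrow(records)
  # missing-ZIP rule: drop a missing-ZIP row when a sibling matching on all
  # other key fields holds a valid ZIP
  other <- setdiff(key, "zip")
  k_other <- keystr(other)
  has_zip <- !is.na(records$zip)
  sib_with_zip <- k_other %in% unique(k_other[has_zip])
  drop_zip <- !has_zip & sib_with_zip
  n_zip_rule <- sum(drop_zip)
  records <- records[!drop_zip, , drop = FALSE]

  k_full <- keystr(key)
  dup <- duplicated(k_full)
  n_exact <- sum(dup)
  out <- records[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dedup_log") <- list(rows_in = n_in, rows_out = nrow(out),
                                 dropped_missing_zip = n_zip_rule,
                                 dropped_exact_duplicate = n_exact)
  out
}
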