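quiet_cfg <- function(...) {
  # all error channels off unless a test switches one on
  args <- list(n_persons = 500, overlap_fraction = 1,
               admission_rate = 1, typo_rate_per_field = 0,
               newborn_fraction = 0, compound_surname_rate = 0,
               missing_gender_rate = 0, mrn_error_rate = 0,
               opd_missing_mrn_fraction = 0, seed = 99)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

test_that("config validation names the offending field", {
  expect_error(generator_config(n_persons = 0), "n_persons")
  expect_error(generator_config(typo_rate_per_field = 1.2),
               "typo_rate_per_field")
  expect_error(generator_config(overlap_fraction = -0.1), "overlap_fraction")
  expect_error(generator_config(name_zipf_exponent = 0), "name_zipf_exponent")
  expect_error(generator_config(mrn_error_split = c(1, 1, 1)),
               "mrn_error_split")
})

test_that("identical config and seed give identical output", {
  cfg <- generator_config(n_persons = 800, seed = 5)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$persons, s2$persons)
  expect_identical(s1$ipd, s2$ipd)
  expect_identical(s1$opd, s2$opd)
  # and byte-identical CSV output
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_linkage_csv(s1$ipd, f1)
  write_linkage_csv(s2$ipd, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("name pools follow the configured diversity ordering", {
  pop <- generate_population(generator_config(n_persons = 10000, seed = 3))
  expect_gt(length(unique(pop$last_name)), length(unique(pop$first_name)))
  # a steep zipf law concentrates names
  steep <- generate_population(generator_config(n_persons = 10000,
                                                name_zipf_exponent = 3,
                                                seed = 3))
  expect_lt(length(unique(steep$first_name)),
            length(unique(pop$first_name)))
  expect_lte(length(unique(steep$first_name)), 10000)
})

test_that("population invariants hold: yob/age consistent with dob", {
  cfg <- generator_config(n_persons = 3000, seed = 21)
  pop <- generate_population(cfg)
  expect_equal(pop$yob, as.integer(format(pop$dob, "%Y")))
  age <- floor(as.numeric(cfg$reference_date - pop$dob) / 365.25)
  expect_true(all(pop$age == pmin(age, cfg$age_cap)))
  expect_false(anyDuplicated(pop$true_person_id) > 0)
})

test_that("no-noise limit: one clean row per person, matching MRNs", {
  cfg <- quiet_cfg()
  scen <- generate_scenario(cfg)
  expect_equal(nrow(scen$ipd), sum(generate_population(cfg)$in_ipd))
  expect_false(anyDuplicated(scen$ipd$true_person_id) > 0)
  pop <- generate_population(cfg)
  key <- match(scen$ipd$true_person_id, pop$true_person_id)
  expect_identical(scen$ipd$mrn, pop$mrn[key])
  expect_identical(scen$ipd$first_name, pop$first_name[key])
  # full overlap, no errors: every IPD person has one OPD row agreeing on all
  expect_setequal(scen$ipd$true_person_id, scen$opd$true_person_id)
  j <- match(scen$ipd$true_person_id, scen$opd$true_person_id)
  for (f in c("first_name", "last_name", "gender", "race", "mrn")) {
    expect_identical(scen$ipd[[f]], scen$opd[[f]][j])
  }
})

test_that("record_ids are unique and truth is conserved", {
  scen <- generate_scenario(generator_config(n_persons = 1000, seed = 8))
  expect_false(anyDuplicated(scen$ipd$record_id) > 0)
  expect_false(anyDuplicated(scen$opd$record_id) > 0)
  expect_true(all(scen$ipd$true_person_id %in% scen$persons$true_person_id))
  expect_true(all(scen$opd$true_person_id %in% scen$persons$true_person_id))
  expect_false(anyDuplicated(scen$opd$true_person_id) > 0) # one row per person
})

test_that("admission counts average out to the admission rate", {
  cfg <- generator_config(n_persons = 5000, overlap_fraction = 1,
                          admission_rate = 1.5, seed = 12)
  pop <- generate_population(cfg)
  ipd <- derive_inpatient(pop, cfg)
  per_person <- table(ipd$true_person_id)
  se <- sqrt(0.5 / length(per_person)) # Poisson(0.5) extra rows
  expect_lt(abs(mean(per_person) - 1.5), 3 * se)
})

test_that("forced typo channel leaves every surname one edit away", {
  cfg <- quiet_cfg(n_persons = 300)
  cfg$typo_rate_per_field <- 1
  pop <- generate_population(cfg)
  ipd <- derive_inpatient(pop, cfg)
  latent <- pop$last_name[match(ipd$true_person_id, pop$true_person_id)]
  d <- mapply(osa_dist, ipd$last_name, latent)
  expect_true(all(d == 1))
})

test_that("overlap controls the shared population", {
  disj <- generate_scenario(quiet_cfg(overlap_fraction = 0))
  expect_length(intersect(disj$ipd$true_person_id,
                          disj$opd$true_person_id), 0)
})

test_that("error-channel frequencies match their configured rates", {
  # binomial conformance at n >= 5000, 3 standard errors
  cfg <- quiet_cfg(n_persons = 5000)
  cfg$typo_rate_per_field <- 0.05
  cfg$missing_gender_rate <- 0.04
  pop <- generate_population(cfg)
  ipd <- derive_inpatient(pop, cfg)
  latent <- pop[match(ipd$true_person_id, pop$true_person_id), ]
  n <- nrow(ipd)
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(ipd$first_name != latent$first_name) - 0.05), tol(0.05))
  expect_lt(abs(mean(is.na(ipd$gender)) - 0.04), tol(0.04))
})

test_that("outpatient missing-MRN share matches the configured fraction", {
  cfg <- quiet_cfg(n_persons = 5000, overlap_fraction = 0)
  cfg$opd_missing_mrn_fraction <- 0.2
  scen <- generate_scenario(cfg)
  share <- mean(is.na(scen$opd$mrn))
  expect_lt(abs(share - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(scen$opd)))
})

test_that("gold-standard corruption hits true matches at the configured rate", {
  cfg <- quiet_cfg(n_persons = 5000)
  cfg$mrn_error_rate <- 0.01
  scen <- generate_scenario(cfg)
  j <- match(scen$ipd$true_person_id, scen$opd$true_person_id)
  mism <- is.na(scen$opd$mrn[j]) | scen$ipd$mrn != scen$opd$mrn[j]
  mism[is.na(mism)] <- TRUE
  expect_lt(abs(mean(mism) - 0.01), 3 * sqrt(0.01 * 0.99 / nrow(scen$ipd)))
})

test_that("an alloyed gold standard produces both discrepancy populations", {
  cfg <- quiet_cfg(n_persons = 3000)
  cfg$mrn_error_rate <- 0.5
  cfg$mrn_error_split <- c(different = 0.4, missing = 0.2, misassigned = 0.4)
  scen <- generate_scenario(cfg)
  j <- match(scen$ipd$true_person_id, scen$opd$true_person_id)
  same_person <- !is.na(j)
  mrn_opd <- scen$opd$mrn[j]
  # same person, unequal or missing MRN
  expect_gt(sum(same_person &
                  (is.na(mrn_opd) | scen$ipd$mrn != mrn_opd), na.rm = TRUE), 0)
  # different persons, equal MRN (misassignment)
  hit <- scen$opd$mrn %in% scen$ipd$mrn
  other <- scen$opd$true_person_id[hit] !=
    scen$ipd$true_person_id[match(scen$opd$mrn[hit], scen$ipd$mrn)]
  expect_gt(sum(other), 0)
})

test_that("newborns get placeholder names on the inpatient side only", {
  cfg <- quiet_cfg(n_persons = 4000)
  cfg$newborn_fraction <- 1
  pop <- generate_population(cfg)
  ipd <- derive_inpatient(pop, cfg)
  opd <- derive_outpatient(pop, cfg)
  nb <- ipd$true_person_id %in% pop$true_person_id[pop$newborn_alias]
  expect_gt(sum(nb), 0)
  expect_true(all(ipd$first_name[nb] %in% c("Male", "Female")))
  latent <- pop[match(ipd$true_person_id, pop$true_person_id), ]
  expect_true(all(ipd$last_name[nb] != latent$last_name[nb]))
  j <- match(pop$true_person_id[pop$newborn_alias], opd$true_person_id)
  expect_true(all(opd$first_name[j] ==
                    pop$first_name[pop$newborn_alias]))
})

test_that("corrupt_field applies exactly one edit of the named channel", {
  expect_equal(corrupt_field("ANNA", "substitute", pos = 1, char = "B"),
               "BNNA")
  expect_equal(corrupt_field("AB", "transpose"), "BA")
  expect_error(corrupt_field("", "delete"), "empty")
  expect_error(corrupt_field("A", "transpose"), "length")
  expect_error(corrupt_field("AAA", "transpose"), "differing")
  set.seed(31)
  for (i in 1:100) {
    v <- random_name(2:9)
    chan <- sample(c("substitute", "insert", "delete", "transpose"), 1)
    out <- corrupt_field(v, chan)
    if (chan == "transpose") {
      expect_equal(osa_dist(v, out), 1)
    } else {
      expect_equal(c(adist(v, out)), 1) # plain Levenshtein oracle
    }
    nd <- switch(chan, insert = 1L, delete = -1L, 0L)
    expect_equal(nchar(out), nchar(v) + nd)
  }
})
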