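test_that("default configuration encodes the study conditions", {
  cfg <- default_cohort_config()
  expect_equal(cfg$n_patients, 502L)
  expect_equal(unname(cfg$satisfaction),
               c(0.625, 0.805, 0.7565, 0.609))
  expect_equal(cfg$male_fraction, 225 / 502)
  expect_equal(unname(cfg$narcotic_share[c("2wk", "6mo")]), c(0.652, 0.326))
  # interpolated interior shares are monotone between the endpoints
  expect_true(all(diff(cfg$narcotic_share) < 0))
  # truncated-normal SDs put ~99% of mass inside each printed range
  for (cl in c("C", "D", "E")) {
    s <- cfg$class_mme[[cl]]
    mass <- pnorm(s$hi, s$mean, s$sd) - pnorm(s$lo, s$mean, s$sd)
    expect_gte(mass, 0.985)
  }
  expect_silent(config_to_json(cfg, tempfile(fileext = ".json")))
})

test_that("invalid configurations are rejected", {
  cfg <- default_cohort_config()
  cfg$satisfaction["2wk"] <- 1.2
  expect_error(generate_cohort(cfg, seed = 1), "probabilities")
  cfg <- default_cohort_config()
  cfg$narcotic_split <- c(C = 0.5, D = 0.5, E = 0.5)
  expect_error(generate_cohort(cfg, seed = 1), "narcotic_split")
})

test_that("generation is seed-deterministic down to the CSV bytes", {
  cfg <- default_cohort_config()
  cfg$n_patients <- 40L
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg, seed = 11), f1)
  write_cohort(generate_cohort(cfg, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different cohort
  f3 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg, seed = 12), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generation leaves the caller's RNG stream untouched", {
  set.seed(55)
  before <- rnorm(1)
  set.seed(55)
  invisible(generate_cohort(default_cohort_config(), seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("back-filled prescriptions reproduce the sampled class exactly", {
  cohort <- generate_cohort(seed = 4)
  aug <- augment_cohort(cohort)
  expect_equal(as.character(aug$med_class), cohort$sampled_class)
  # class-C visits carry occasional short-acting narcotics in (0, 30]
  c_mme <- aug$daily_mme[cohort$sampled_class == "C"]
  expect_true(all(c_mme > 0 & c_mme <= 30))
  # A/B visits carry no opioid dose
  expect_true(all(aug$daily_mme[cohort$sampled_class %in% c("A", "B")] == 0))
})

test_that("configured marginals are recovered within 3 binomial SEs", {
  cfg <- default_cohort_config()
  cohort <- generate_cohort(cfg, seed = 6)
  n <- cfg$n_patients
  for (per in cfg$periods) {
    sub <- cohort[cohort$period == per, ]
    expect_equal(nrow(sub), n)
    p_sat <- cfg$satisfaction[[per]]
    se_sat <- sqrt(p_sat * (1 - p_sat) / n)
    expect_lt(abs(mean(sub$ipa <= 1) - p_sat), 3 * se_sat)
    p_narc <- cfg$narcotic_share[[per]]
    se_narc <- sqrt(p_narc * (1 - p_narc) / n)
    expect_lt(abs(mean(sub$sampled_class %in% c("C", "D", "E")) - p_narc),
              3 * se_narc)
  }
  p_male <- cfg$male_fraction
  expect_lt(abs(mean(cohort$gender[!duplicated(cohort$patient_id)] == "male") -
                  p_male),
            3 * sqrt(p_male * (1 - p_male) / n))
  expect_true(all(cohort$age >= 18 & cohort$age <= 87))
})

test_that("cross-sectional and attrition modes shrink the visit table", {
  cfg <- default_cohort_config()
  cfg$n_patients <- 60L
  cfg$cross_sectional <- TRUE
  cs <- generate_cohort(cfg, seed = 8)
  expect_equal(nrow(cs), 60)
  expect_true(all(table(cs$patient_id) == 1))

  cfg2 <- default_cohort_config()
  cfg2$n_patients <- 60L
  cfg2$attrition <- 0.5
  att <- generate_cohort(cfg2, seed = 8)
  expect_lt(nrow(att), 240)
  # the first (2wk) visit is always kept
  expect_equal(sum(att$period == "2wk"), 60)
})

test_that("config JSON round-trips through the reader", {
  cfg <- default_cohort_config()
  path <- tempfile(fileext = ".json")
  config_to_json(cfg, path)
  cfg2 <- config_from_json(path)
  expect_equal(cfg2$n_patients, cfg$n_patients)
  expect_equal(unname(unlist(cfg2$satisfaction)), unname(cfg$satisfaction))
  expect_equal(cfg2$class_mme$C$sd, cfg$class_mme$C$sd)
  # the round-tripped config generates the same cohort under the same seed
  a <- generate_cohort(cfg, seed = 21)
  b <- generate_cohort(cfg2, seed = 21)
  expect_equal(a$sampled_class, b$sampled_class)
  expect_equal(a$ipa, b$ipa)
})
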