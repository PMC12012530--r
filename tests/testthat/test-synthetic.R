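test_that("same seed and config give a byte-identical cohort", {
  cfg <- sim_config(n_per_group = c(control = 40, preterm = 15, chd = 20),
                    seed = 33)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(
    generate_cohort(cfg),
    generate_cohort(sim_config(n_per_group = cfg$n_per_group, seed = 34))
  ))
})

test_that("generated cohorts satisfy all cohort invariants", {
  co <- generate_cohort(sim_config(seed = 5))
  expect_true(all(co$total_sa > co$exposed_sa))
  expect_true(all(co$exposed_sa > 0) && all(co$ct > 0) &&
                all(co$supratentorial_volume > 0))
  expect_true(all(co$ga_weeks[co$group == "control"] >= 37))
  expect_true(all(co$ga_weeks[co$group == "preterm"] < 33))
  expect_true(all(co$pma_weeks >= 37 & co$pma_weeks <= 44 + 6 / 7))
  expect_false(any(duplicated(co$subject_id)))
  # re-validation excludes nothing
  revalidated <- as_cohort(as.data.frame(co))
  expect_equal(nrow(revalidated), nrow(co))
  expect_equal(nrow(validation_report(revalidated)), 0)
})

test_that("the noiseless limit returns the configured exponent exactly", {
  cfg <- sim_config(n_per_group = c(control = 80), seed = 2,
                    folding_alpha = c(control = 1.3),
                    folding_offset_sd = 0, volume_noise_sd = 0)
  co <- generate_cohort(cfg)
  fit <- fit_scaling(co, "folding", covariates = character(),
                     force_method = "ols")
  expect_equal(fit$alpha, 1.3, tolerance = 1e-9)
})

test_that("fitted alpha stays within 3 SE of the generating exponent", {
  cfg <- sim_config(n_per_group = c(control = 500), seed = 7,
                    folding_alpha = c(control = 1.30))
  fit <- fit_scaling(generate_cohort(cfg), "folding", force_method = "ols")
  expect_lt(abs(fit$alpha - 1.30), 3 * fit$alpha_se)
})

test_that("group term shifts propagate to the generated morphometry", {
  cfg <- sim_config(n_per_group = c(control = 400, preterm = 400), seed = 9,
                    covariate_effects = c(pma = 0, sex_male = 0,
                                          birthweight_z = 0, multiple_birth = 0),
                    term_shifts = list(
                      control = c(offset = 0, isometric = 0, shape = 0),
                      preterm = c(offset = -0.012, isometric = 0.035,
                                  shape = -0.141)
                    ))
  co <- add_morph_terms(generate_cohort(cfg))
  d <- function(col) mean(co[[col]][co$group == "preterm"]) -
    mean(co[[col]][co$group == "control"])
  # mean contrasts approach the configured shifts (MC error ~ sd/sqrt(400))
  expect_lt(abs(d("offset_k") - (-0.012)), 0.002)
  expect_lt(abs(d("isometric_i") - 0.035), 0.05)
  expect_lt(abs(d("shape_s") - (-0.141)), 0.05)
})

test_that("self-similar families obey the geometric identities exactly", {
  fam <- generate_self_similar_family(n = 10, scale_range = c(0.7, 1.4),
                                      seed = 3)
  expect_equal(fit_scaling(fam, "total_sa_vs_volume",
                           covariates = character())$alpha, 2 / 3)
  expect_equal(fit_scaling(fam, "ct_vs_volume",
                           covariates = character())$alpha, 1 / 3)
  expect_equal(fit_scaling(fam, "folding",
                           covariates = character())$alpha, 1.25)

  terms <- compute_terms(fam$total_sa, fam$exposed_sa, fam$ct)
  expect_equal(diff(range(terms$offset_k)), 0)
  expect_equal(diff(range(terms$shape_s)), 0)
  lambda <- fam$ct / fam$ct[1]
  expect_equal(terms$isometric_i - terms$isometric_i[1], 6 * log10(lambda))

  expect_error(generate_self_similar_family(n = 2), ">= 3")
  expect_error(generate_self_similar_family(scale_range = c(-1, 1)), "positive")
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(folding_offset_sd = -1), "SD")
  expect_error(sim_config(n_per_group = c(control = -5)), "counts")
  expect_error(sim_config(pma_ranges = list(control = c(30, 44),
                                            preterm = c(37, 44),
                                            chd = c(37, 42))),
               "eligibility")
})

test_that("CI of the fitted folding coefficient covers the generating value at ~95%", {
  # replicate-seed coverage of the OLS CI under the generator's own noise
  n_rep <- 120
  covered <- vapply(seq_len(n_rep), function(s) {
    co <- generate_cohort(sim_config(n_per_group = c(control = 150),
                                     seed = 1000 + s,
                                     folding_alpha = c(control = 1.26)))
    ci <- fit_scaling(co, "folding", force_method = "ols")$alpha_ci
    ci[1] <= 1.26 && 1.26 <= ci[2]
  }, logical(1))
  # binomial SE at p = .95, n = 120 is 2%; allow 3 SE
  expect_gt(mean(covered), 0.95 - 0.06)
})
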