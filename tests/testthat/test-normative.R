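test_that("control deviance z-scores have mean 0 and SD 1 by construction", {
  co <- small_sim(seed = 51, n_control = 150)
  ctrl <- co[co$group == "control", ]
  for (m in c("shape_s", "folding_scaling")) {
    nm <- fit_normative(ctrl, m, seed = 1)
    z <- deviance_z(nm, ctrl)$z
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
})

test_that("deviance z follows its definition for a constructed subject", {
  co <- small_sim(seed = 52)
  ctrl <- co[co$group == "control", ]
  nm <- fit_normative(ctrl, "offset_k", method = "ols")
  # take a control subject and displace its offset by exactly one control SD
  s1 <- ctrl[1, ]
  z0 <- deviance_z(nm, s1)$z
  terms <- compute_terms(s1$total_sa, s1$exposed_sa, s1$ct)
  # raise offset_k by control_residual_sd via total_sa (K has weight 1 on a)
  s2 <- s1
  s2$total_sa <- 10^(log10(s1$total_sa) + nm$control_residual_sd)
  # exposed/ct unchanged -> K shifts by exactly one residual SD
  expect_equal(deviance_z(nm, s2)$z, z0 + 1, tolerance = 1e-8)
})

test_that("non-control records are rejected when fitting the normative model", {
  co <- small_sim(seed = 53)
  expect_error(fit_normative(co, "shape_s"), "control records only")
})

test_that("normative fits are deterministic given the seed", {
  ctrl <- small_sim(seed = 54)[1:100, ]
  n1 <- fit_normative(ctrl, "shape_s", seed = 9)
  n2 <- fit_normative(ctrl, "shape_s", seed = 9)
  expect_identical(n1$coefficients, n2$coefficients)
})

test_that("an injected shape shift appears in the mean clinical z-score", {
  delta <- 0.141
  co <- generate_cohort(sim_config(
    n_per_group = c(control = 345, preterm = 73), seed = 55
  ))
  nm <- fit_normative(co[co$group == "control", ], "shape_s", seed = 1)
  z <- deviance_z(nm, co)
  zp <- z$z[z$group == "preterm"]
  expected <- -delta / nm$control_residual_sd
  # mean preterm z ~ -delta/sigma_ctrl within Monte-Carlo error
  expect_equal(mean(zp), expected, tolerance = 3 / sqrt(length(zp)))
  expect_lt(mean(zp), 0)
})

test_that("control residual SD tracks the generating folding noise", {
  co <- generate_cohort(sim_config(n_per_group = c(control = 345), seed = 56,
                                   folding_offset_sd = 0.01))
  nm <- fit_normative(co, "folding_scaling", seed = 1)
  expect_lt(abs(nm$control_residual_sd - 0.01), 0.001)  # within 10%
})

test_that("deviance z is equivariant under a constant metric shift", {
  co <- small_sim(seed = 57)
  ctrl <- co[co$group == "control", ]
  nm <- fit_normative(ctrl, "isometric_i", method = "ols")
  z1 <- deviance_z(nm, ctrl)$z
  # scale all areas and thickness by lambda: isometric term shifts by a
  # constant, predictions shift identically after refitting
  ctrl2 <- ctrl
  lam <- 10^0.1
  ctrl2$total_sa <- ctrl2$total_sa * lam^2
  ctrl2$exposed_sa <- ctrl2$exposed_sa * lam^2
  ctrl2$ct <- ctrl2$ct * lam
  nm2 <- fit_normative(ctrl2, "isometric_i", method = "ols")
  expect_equal(deviance_z(nm2, ctrl2)$z, z1, tolerance = 1e-8)
})

test_that("group-by-deviance interaction recovers the generated outcome slope", {
  co <- generate_cohort(sim_config(
    n_per_group = c(control = 345, preterm = 73), seed = 58
  ))
  zt <- deviance_table(co, metrics = "shape_s", method = "ols")
  res <- test_outcome_interaction(co, zt$z_shape_s, "cognitive",
                                  c("control", "preterm"),
                                  n_perm = 199, seed = 2)
  expect_lt(abs(res$b_estimate - (-4.78)), 3 * res$b_se)
  expect_equal(nrow(res$simple_slopes), 2)
  expect_equal(res$simple_slopes$n[res$simple_slopes$group == "preterm"], 57)
})

test_that("a z independent of the outcome gives a null interaction", {
  co <- generate_cohort(sim_config(
    n_per_group = c(control = 150, preterm = 60), seed = 59,
    outcome_model = list(intercept = 100, residual_sd = 15,
                         shape_z_slope = c(control = 0, preterm = 0),
                         imd_effect = 0, parent_english_effect = 0,
                         n_followup = c(control = NA, preterm = NA))
  ))
  z_noise <- cortiscale:::with_seed(60, rnorm(nrow(co)))
  res <- test_outcome_interaction(co, z_noise, "cognitive",
                                  c("control", "preterm"),
                                  n_perm = 199, seed = 3)
  expect_gt(res$p_perm, 0.01)
})

test_that("bootstrap delta R2 matches its variance-decomposition oracle", {
  # outcome = beta * z + noise, z independent of the covariate:
  # delta R2 = beta^2 var(z) / var(outcome)
  set.seed(61)
  n <- 4000
  beta <- 6
  z <- rnorm(n)
  imd <- sample.int(32844, n, replace = TRUE)
  y <- 100 + beta * z + rnorm(n, 0, 12)
  df <- make_cohort_df(n)
  df$subject_id <- sprintf("x%05d", 1:n)
  df$imd_rank <- imd
  df$cognitive_score <- y
  co <- as_cohort(df)
  est <- bootstrap_delta_r2(co, z, "cognitive", n_boot = 200, seed = 4)
  oracle <- beta^2 * var(z) / var(y)
  expect_lt(abs(est$delta_r2 - oracle), 0.02)
  expect_true(est$ci[1] <= est$delta_r2 && est$delta_r2 <= est$ci[2])
})

test_that("delta R2 is invariant to affine rescaling of z and null for residualised z", {
  co <- generate_cohort(sim_config(
    n_per_group = c(control = 200, preterm = 60), seed = 62
  ))
  zt <- deviance_table(co, metrics = "shape_s", method = "ols")
  pre <- co$group == "preterm"
  b1 <- bootstrap_delta_r2(co, zt$z_shape_s, "cognitive", group = "preterm",
                           n_boot = 150, seed = 5)
  b2 <- bootstrap_delta_r2(co, 3 * zt$z_shape_s - 7, "cognitive",
                           group = "preterm", n_boot = 150, seed = 5)
  expect_equal(b1$delta_r2, b2$delta_r2, tolerance = 1e-10)

  # orthogonalise z against the outcome within the analysis subsample
  d <- co[pre & !is.na(co$cognitive_score), ]
  zp <- zt$z_shape_s[pre][!is.na(co$cognitive_score[pre])]
  z_orth <- resid(lm(zp ~ d$cognitive_score))
  co_sub <- co[pre, ][!is.na(co$cognitive_score[pre]), ]
  b3 <- bootstrap_delta_r2(co_sub, z_orth, "cognitive", n_boot = 150, seed = 6)
  expect_lt(b3$delta_r2, 0.04)
  expect_error(bootstrap_delta_r2(co, zt$z_shape_s, "cognitive", n_boot = 50),
               "at least 100")
})

test_that("the six-metric outcome family is Holm-corrected jointly", {
  co <- small_sim(seed = 63, n_control = 120, n_preterm = 50)
  zt <- deviance_table(co, method = "ols")
  fam <- outcome_family(co, zt, "cognitive", c("control", "preterm"),
                        n_perm = 99, seed = 7)
  df <- as.data.frame(fam)
  expect_equal(nrow(df), 6)
  expect_equal(df$p_fwe, unname(holm_correct(df$p_perm)))
})
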