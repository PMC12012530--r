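test_that("with no covariates Freedman-Lane equals simple response permutation", {
  set.seed(20)
  n <- 40
  x <- cbind(`(Intercept)` = 1, slope = rnorm(n))
  y <- 0.3 * x[, 2] + rnorm(n)
  n_perm <- 300
  res <- permutation_lm(y, x, "slope", n_perm = n_perm, seed = 5)

  # naive oracle: permute y itself with the same RNG stream
  t_of <- function(yy) {
    f <- summary(lm(yy ~ x[, 2]))
    f$coefficients[2, "t value"]
  }
  t_obs <- t_of(y)
  t_star <- cortiscale:::with_seed(5, {
    E <- matrix(0, n, n_perm)
    e <- y - mean(y)
    for (j in seq_len(n_perm)) E[, j] <- e[sample.int(n)]
    apply(mean(y) + E, 2, t_of)
  })
  p_naive <- (1 + sum(abs(t_star) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  expect_equal(res$p_perm, p_naive)
  expect_equal(res$t_stat, t_obs, tolerance = 1e-10)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration at tiny n", {
  set.seed(21)
  n <- 6
  x <- cbind(1, c(-2.1, -1, -0.4, 0.7, 1.2, 2.4))
  y <- 0.8 * x[, 2] + rnorm(n, 0, 0.8)
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) !any(duplicated(p))), ]
  t_of <- function(yy) {
    b <- solve(crossprod(x), crossprod(x, yy))
    r <- yy - x %*% b
    s2 <- sum(r^2) / (n - 2)
    b[2] / sqrt(s2 * solve(crossprod(x))[2, 2])
  }
  t_obs <- t_of(y)
  t_all <- apply(perms, 1, function(p) t_of(y[p]))
  p_exact <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
  res <- permutation_lm(y, x, 2, n_perm = 2000, seed = 9)
  # MC p within 3 binomial SEs of the exhaustive p
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$p_perm - p_exact), 3 * se + 1 / 2000)
  expect_gte(res$p_perm, 1 / 2001)
})

test_that("B and t come from the parametric fit; permutation affects only p", {
  co <- small_sim(seed = 22)
  res <- test_term_difference(co, "shape_s", c("control", "preterm"),
                              n_perm = 99, seed = 1)
  co2 <- add_morph_terms(co)
  d <- co2[co2$group %in% c("control", "preterm"), ]
  d$gi_ <- as.numeric(d$group == "preterm")
  d$male <- as.numeric(d$sex == "male")
  d$pma2 <- (d$pma_weeks - mean(d$pma_weeks))^2
  f <- summary(lm(shape_s ~ gi_ + male + pma_weeks + pma2 + birthweight_z +
                    multiple_birth, data = d))$coefficients
  expect_equal(res$b_estimate, f["gi_", "Estimate"], tolerance = 1e-10)
  expect_equal(res$t_stat, f["gi_", "t value"], tolerance = 1e-10)
  res2 <- test_term_difference(co, "shape_s", c("control", "preterm"),
                               n_perm = 199, seed = 2)
  expect_equal(res2$b_estimate, res$b_estimate)
})

test_that("the scaling interaction recovers a generated exponent difference", {
  co <- generate_cohort(sim_config(
    n_per_group = c(control = 345, preterm = 73), seed = 23,
    folding_alpha = c(control = 1.26, preterm = 1.41)
  ))
  res <- test_scaling_difference(co, "folding", c("control", "preterm"),
                                 n_perm = 499, seed = 3)
  expect_lt(abs(res$b_estimate - 0.15), 3 * res$b_se)
  expect_lt(res$p_perm, 0.05)
})

test_that("a generated term shift is detected with the right sign", {
  co <- small_sim(seed = 24, n_control = 200, n_preterm = 70)
  res <- test_term_difference(co, "shape_s", c("control", "preterm"),
                              n_perm = 499, seed = 4)
  expect_lt(res$b_estimate, 0)  # generator default shape shift is -0.141
  expect_lt(res$p_perm, 0.05)
})

test_that("holm_correct reproduces the step-down rule and its edge cases", {
  # single p unchanged
  expect_equal(holm_correct(0.03), 0.03)
  # never below raw p, monotone in ranks
  p <- c(0.02, 0.8, 0.004, 0.04, 0.3)
  adj <- holm_correct(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(names(holm_correct(c(a = 0.1, b = 0.2), labels = c("a", "b"))),
               c("a", "b"))
})

test_that("families attach Holm-adjusted p to each member", {
  co <- small_sim(seed = 25)
  fam <- group_contrast_family(co, c("control", "preterm"), n_perm = 99,
                               seed = 5)
  df <- as.data.frame(fam)
  expect_equal(nrow(df), 6)
  expect_true(all(df$p_fwe >= df$p_perm))
  expect_equal(df$p_fwe, unname(holm_correct(df$p_perm)))
})

test_that("categorical predictors with >2 levels give pairwise families", {
  co <- generate_cohort(sim_config(
    n_per_group = c(control = 30, chd = 90), seed = 26
  ))
  chd <- co[co$group == "chd", ]
  fam <- test_covariate_effect(chd, "chd_subtype", "isometric_i",
                               covariates = c("sex", "pma", "pma2",
                                              "multiple_birth"),
                               n_perm = 99, seed = 6)
  expect_s3_class(fam, "hypothesis_family")
  expect_equal(length(fam$results), 3)  # 3 pairwise contrasts
  expect_error(
    test_covariate_effect(chd, "group", "isometric_i", n_perm = 99),
    "constant"
  )
})

test_that("a continuous covariate effect is testable on terms and scalings", {
  co <- small_sim(seed = 27, n_control = 150)
  ctrl <- co[co$group == "control", ]
  r1 <- test_covariate_effect(ctrl, "bwz", "isometric_i",
                              covariates = c("sex", "pma", "pma2",
                                             "multiple_birth"),
                              n_perm = 199, seed = 7)
  expect_s3_class(r1, "permutation_result")
  expect_gt(r1$b_estimate, 0)  # generator: bwz raises size
  r2 <- test_covariate_effect(ctrl, "bwz", "folding",
                              covariates = c("sex", "pma", "pma2",
                                             "multiple_birth"),
                              n_perm = 199, seed = 8)
  expect_s3_class(r2, "permutation_result")
  expect_true(r2$p_perm > 0 && r2$p_perm <= 1)
})
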