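test_that("split-chain Rhat separates stationary from divergent chains", {
  set.seed(1)
  mk <- function(chains) {
    arr <- array(chains, dim = c(nrow(chains), ncol(chains), 1))
    posterior_draws(arr, data.frame(name = "theta", kind = "mu",
                                    stage = "s", covariate = "c",
                                    unit = NA))
  }
  same <- mk(matrix(rnorm(3000), 1000, 3))
  r1 <- gelman_rubin(same)
  expect_gte(min(r1$rhat$rhat), 0.99)  # >= 1 up to estimator noise
  expect_lt(max(r1$rhat$rhat), 1.05)
  expect_true(r1$all_converged)

  apart <- mk(cbind(rnorm(1000, 0), rnorm(1000, 10)))
  r2 <- gelman_rubin(apart)
  # closed form: B/m ~ 2 * (10/2)^2 = 50 vs W ~ 1 -> Rhat ~ sqrt(26) ... > 2
  expect_gt(r2$rhat$rhat, 2)
  expect_false(r2$all_converged)

  # the threshold is inclusive: Rhat exactly at the cutoff converges
  r3 <- gelman_rubin(apart, threshold = r2$rhat$rhat)
  expect_true(r3$all_converged)

  expect_error(gelman_rubin(mk(matrix(rnorm(100), 100, 1))), "2 chains")
})

test_that("Rhat agrees with the coda implementation on shared draws", {
  set.seed(2)
  chains <- cbind(rnorm(500, 0.15), rnorm(500, -0.15), rnorm(500))
  arr <- array(chains, dim = c(500, 3, 1))
  x <- posterior_draws(arr, data.frame(name = "p", kind = "mu", stage = "s",
                                       covariate = "c", unit = NA))
  ours <- gelman_rubin(x)$rhat$rhat
  # coda uses unsplit chains; compare against coda run on our half-chains
  halves <- cbind(chains[1:250, ], chains[251:500, ])
  cl <- coda::mcmc.list(lapply(seq_len(6), function(j) coda::mcmc(halves[, j])))
  ref <- unname(coda::gelman.diag(cl, autoburnin = FALSE)$psrf[1, 1])
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("prior-sampling mode reproduces the specified prior moments", {
  d <- generate_dataset(sim_config(preset = "recovery",
                                   n_individuals_per_stage = c(3L, 3L),
                                   sets_per_individual = 2L,
                                   nest_n_sets = 10L, seed = 3))$data
  fit <- dcfit(d, model = "nest", prior_only = TRUE,
               control = mcmc_control(n_iter = 6000), seed = 1)
  m <- as.matrix(fit$draws)
  # N(0, precision 0.01) -> SD 10
  expect_true(all(abs(apply(m, 2, sd) / 10 - 1) < 0.1))
  expect_true(all(abs(colMeans(m)) < 10 * 3 / sqrt(nrow(m))))

  hfit <- dcfit(d, model = "postfledging", prior_only = TRUE,
                control = mcmc_control(n_iter = 6000), seed = 1)
  hm <- as.matrix(hfit$draws)
  reg <- hfit$draws$registry
  musd <- apply(hm[, reg$kind == "mu", drop = FALSE], 2, sd)
  expect_true(all(abs(musd / 10 - 1) < 0.1))
  # precision ~ Gamma(1, 1e-4): P(tau < 1e4) = 1 - exp(-1) ~ 0.632
  tau <- 1 / hm[, reg$kind == "sigma", drop = TRUE][, 1]^2
  expect_lt(abs(mean(tau < 1e4) - (1 - exp(-1))), 0.03)
})

test_that("fits are seed-deterministic and chain-order invariant", {
  sim <- generate_dataset(quick_sim_config(seed = 4))
  f1 <- suppressWarnings(dcfit(sim$data, "postfledging",
                               control = quick_control(1200), seed = 8))
  f2 <- suppressWarnings(dcfit(sim$data, "postfledging",
                               control = quick_control(1200), seed = 8))
  expect_identical(f1$draws$draws, f2$draws$draws)

  # permuting chains changes no pooled summary
  perm <- f1$draws
  perm$draws <- perm$draws[, c(2, 3, 1), , drop = FALSE]
  s1 <- summarize_coefficients(f1$draws, which = "mu")
  s2 <- summarize_coefficients(perm, which = "mu")
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$f, s2$f)
})

test_that("pooled-model posterior recovers a known shared coefficient vector", {
  beta <- c(0.5, -0.4, 0.3, 0, 0.2, 0.3, -0.2, 0.1, -0.1, 0, 0, 0.1, 0)
  cfg <- sim_config(preset = "recovery", nest_n_sets = 200L,
                    nest_beta = beta, n_individuals_per_stage = c(1L, 1L),
                    sets_per_individual = 1L, seed = 5)
  d <- generate_dataset(cfg)$data
  fit <- suppressWarnings(dcfit(d, model = "nest",
                                control = mcmc_control(n_iter = 6000),
                                seed = 2))
  sm <- summarize_coefficients(fit, which = "population")
  covered <- sm$cri_lo <= beta & beta <= sm$cri_hi
  expect_gte(sum(covered), 12)  # at least 12 of 13 inside the 95% CRI
})

test_that("individuals with few observations shrink toward the population", {
  # one stage; most birds inform mu, two probe birds share the same true
  # offset but differ in data volume (1 vs 20 sets)
  set.seed(6)
  cfg <- quick_sim_config(seed = 6)
  spec <- model_spec()
  mu <- as.numeric(cfg$population_means)
  offset <- rep(0.8, 13)
  # choices must be drawn on the same scale the model fits: z-score the
  # covariate pool first, then choose
  pool <- simulate_covariates(cfg, 15 * 8 + 21)
  mns <- vapply(pool, mean, 0); sds <- vapply(pool, sd, 0)
  zpool <- as.data.frame(mapply(function(x, m, s) (x - m) / s, pool, mns, sds))
  birds <- c(rep(sprintf("m%02d", 1:15), each = 8), rep("probe1", 1),
             rep("probe20", 20))
  betas <- rbind(t(replicate(15, rnorm(13, mu, 0.3))),
                 mu + offset, mu + offset)
  rownames(betas) <- c(sprintf("m%02d", 1:15), "probe1", "probe20")
  tab <- do.call(rbind, lapply(seq_along(birds), function(i) {
    loc <- zpool[(3 * i - 2):(3 * i), ]
    used <- simulate_choice(loc, betas[birds[i], ], spec)
    data.frame(set_id = sprintf("x%04d", i), species = "flycatcher",
               individual_id = birds[i], brood_id = birds[i],
               stage = "early_dependent", day_postfledge = 3L,
               role = replace(rep("available", 3), used, "used"),
               pool[(3 * i - 2):(3 * i), ])
  }))
  d <- choice_data(tab)
  fit <- suppressWarnings(dcfit(d, "postfledging",
                                control = quick_control(2500), seed = 3))
  reg <- fit$draws$registry
  m <- as.matrix(fit$draws)
  mu_hat <- colMeans(m[, reg$kind == "mu", drop = FALSE])
  b1 <- colMeans(m[, reg$unit %in% "early_dependent.probe1", drop = FALSE])
  b20 <- colMeans(m[, reg$unit %in% "early_dependent.probe20", drop = FALSE])
  # the single-set bird sits closer to mu than the 20-set bird does
  expect_lt(mean(abs(b1 - mu_hat)), mean(abs(b20 - mu_hat)))
})

test_that("postfledging fit validates stage coverage and grouping", {
  d <- generate_dataset(sim_config(preset = "recovery",
                                   n_individuals_per_stage = c(3L, 3L),
                                   sets_per_individual = 2L, seed = 7))$data
  expect_error(dcfit(d, "postfledging", grouping = c(late_dependent = 1L),
                     control = quick_control()), "cover")
  g <- c(early_dependent = 1L, late_dependent = 3L)
  expect_error(dcfit(d, "postfledging", grouping = g,
                     control = quick_control()), "zero choice sets")
})

test_that("mcmc_control and prior_spec validate their arguments", {
  expect_error(mcmc_control(n_chains = 1), "n_chains")
  expect_error(mcmc_control(n_iter = 100, n_burnin = 100))
  expect_error(prior_spec(fixed_prec = 0))
})
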