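# build a posterior_draws object from a plain draws matrix (1 chain)
draws_of <- function(m, kind = "beta", stage = "nest") {
  if (is.vector(m)) m <- matrix(m, ncol = 1)
  reg <- data.frame(name = colnames(m) %||% paste0("p", seq_len(ncol(m))),
                    kind = kind, stage = stage,
                    covariate = colnames(m) %||% paste0("p", seq_len(ncol(m))),
                    unit = NA_character_)
  posterior_draws(array(m, dim = c(nrow(m), 1, ncol(m))), reg)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("coefficient summaries: mean, CRI and f behave as defined", {
  cons <- draws_of(rep(2, 1000))
  s <- summarize_coefficients(cons, "all")
  expect_equal(s$mean, 2)
  expect_equal(c(s$cri_lo, s$cri_hi), c(2, 2))
  expect_equal(s$f, 1)

  sym <- draws_of(rep(c(-1, 1), 500))
  expect_equal(summarize_coefficients(sym, "all")$f, 0.5)

  set.seed(1)
  shifted <- draws_of(rnorm(10000) + 1)
  expect_equal(summarize_coefficients(shifted, "all")$f, pnorm(1),
               tolerance = 0.01)

  expect_error(summarize_coefficients(cons, "nope"), "empty")
  # f and CRI ordering invariants
  expect_true(all(s$cri_lo <= s$cri_hi))
  expect_true(s$f >= 0.5 && s$f <= 1)
})

test_that("f is invariant to chain permutation and robust to thinning", {
  set.seed(2)
  arr <- array(rnorm(3000, 0.4), dim = c(500, 3, 2))
  reg <- data.frame(name = c("a", "b"), kind = "mu", stage = "s",
                    covariate = c("a", "b"), unit = NA)
  x <- posterior_draws(arr, reg)
  xp <- posterior_draws(arr[, c(3, 1, 2), , drop = FALSE], reg)
  expect_equal(summarize_coefficients(x, "all")$f,
               summarize_coefficients(xp, "all")$f)
  xt <- posterior_draws(arr[seq(1, 500, by = 5), , , drop = FALSE], reg)
  expect_equal(summarize_coefficients(xt, "all")$f,
               summarize_coefficients(x, "all")$f, tolerance = 0.05)
})

test_that("selection ratios exponentiate summaries and honour eligibility", {
  s <- data.frame(parameter = "u", kind = "mu", stage = "late",
                  covariate = "understory_density",
                  mean = 0, cri_lo = -0.2, cri_hi = 0.3, f = 0.8)
  r <- selection_ratio(s, interaction_f = 0.5)
  expect_equal(r$ratio, 1)
  expect_true(r$eligible)

  s$mean <- 1.16; s$cri_lo <- 0.5; s$cri_hi <- 1.8
  r <- selection_ratio(s, interaction_f = 0.98)
  expect_equal(r$ratio, exp(1.16), tolerance = 1e-12)
  expect_equal(round(r$ratio, 2), 3.19)
  expect_false(r$eligible)     # strong interaction blocks interpretation
  expect_true(selection_ratio(s, interaction_f = 0.89)$eligible)
  expect_false(selection_ratio(s, interaction_f = 0.90)$eligible)

  # order preservation under exponentiation
  expect_true(r$ratio_lo <= r$ratio & r$ratio <= r$ratio_hi)
})

test_that("Estrella's R2 hits its limits and is monotone in the likelihood", {
  n <- 100
  expect_equal(estrella_r2(n * log(1 / 3), n), 0)
  expect_equal(estrella_r2(0, n), 1)
  expect_error(estrella_r2(1, n), "<= 0")

  # independently coded evaluation at n = 100, J = 3, ll = -80
  L0 <- 100 * log(1 / 3)
  byhand <- 1 - exp(log(-80 / L0) * (-(2 / 100) * L0))
  expect_equal(estrella_r2(-80, 100, 3), byhand, tolerance = 1e-12)

  lls <- seq(n * log(1 / 3) + 1e-9, -1e-9, length.out = 50)
  r2 <- vapply(lls, estrella_r2, 0, n_sets = n)
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 <= 1))
})

# a hand-built "dcfit" with known draws lets curve geometry be tested
# without MCMC noise
fake_fit <- function(bdraws, data) {
  spec <- model_spec()
  reg <- data.frame(name = spec$labels, kind = "beta", stage = "nest",
                    covariate = spec$labels, unit = NA_character_)
  structure(list(model = "nest",
                 draws = posterior_draws(
                   array(bdraws, dim = c(nrow(bdraws), 1, 13)), reg),
                 spec = spec, data = data,
                 scaling = list(scheme = "zscore",
                                means = setNames(rep(0, 7), all_covariates()),
                                sds = setNames(rep(1, 7), all_covariates()))),
            class = "dcfit")
}

test_that("use curves are anchored, flat at zero effect, monotone otherwise", {
  d <- standardize_covariates(choice_data(make_choice_table(30, seed = 3)))
  z <- as.data.frame(d)

  bz <- matrix(0, 200, 13)
  flat <- use_curve(fake_fit(bz, z), "understory_density")
  expect_equal(flat$mean, rep(1, nrow(flat)), tolerance = 1e-12)
  expect_equal(flat$cri_lo, flat$cri_hi)

  b <- matrix(0, 200, 13); b[, 2] <- 0.8   # positive understory effect only
  up <- use_curve(fake_fit(b, z), "understory_density")
  expect_true(all(diff(up$mean) > 0))
  # anchored at the dataset mean: r = 1 with a zero-width band
  mid <- which.min(abs(up$x - mean(z$understory_density)))
  expect_lt(abs(up$mean[mid] - 1), 0.05)

  # wider posterior -> wider band, pointwise on average
  set.seed(4)
  b1 <- matrix(0, 400, 13); b1[, 2] <- rnorm(400, 0.5, 0.2)
  b2 <- b1; b2[, 2] <- rnorm(400, 0.5, 0.6)
  c1 <- use_curve(fake_fit(b1, z), "understory_density")
  c2 <- use_curve(fake_fit(b2, z), "understory_density")
  expect_gt(mean(c2$cri_hi - c2$cri_lo), mean(c1$cri_hi - c1$cri_lo))
})

test_that("a supported edge interaction forces a near/far scenario", {
  d <- standardize_covariates(choice_data(make_choice_table(30, seed = 5)))
  z <- as.data.frame(d)
  b <- matrix(0, 200, 13)
  b[, 2] <- 0.5
  b[, 9] <- 0.6    # understory x edge interaction, always positive -> f = 1
  ff <- fake_fit(b, z)
  expect_error(use_curve(ff, "understory_density"), "near")
  near <- use_curve(ff, "understory_density", scenario = "near")
  far <- use_curve(ff, "understory_density", scenario = "far")
  expect_lt(attr(near, "edge_distance"), attr(far, "edge_distance"))
  # with a positive interaction the far-from-edge curve is steeper
  expect_gt(tail(far$mean, 1), tail(near$mean, 1))
})

test_that("coefficient table reports ratios only where eligible", {
  d <- standardize_covariates(choice_data(make_choice_table(25, seed = 6)))
  z <- as.data.frame(d)
  set.seed(7)
  b <- matrix(rnorm(200 * 13, 0, 0.1), 200, 13)
  b[, 9] <- abs(b[, 9]) + 0.2   # strong understory x edge interaction
  fit <- fake_fit(b, z)
  fit$n_sets <- 25; fit$loglik_null <- 25 * log(1 / 3)
  tab <- coefficient_table(fit)
  expect_equal(nrow(tab), 13)
  u <- tab[tab$covariate == "understory_density", ]
  expect_false(u$eligible)
  expect_true(is.na(tab$selection_ratio[grepl(":", tab$covariate)][1]))
  litter <- tab[tab$covariate == "litter_depth", ]
  expect_equal(litter$selection_ratio, exp(litter$mean), tolerance = 1e-12)
  # CSV round trip
  p <- tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE)
  back <- read.csv(p)
  expect_equal(back$mean, tab$mean, tolerance = 1e-9)
  file.remove(p)
})
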