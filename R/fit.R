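#' Prior specification
#'
#' Vague priors in the parameterization conventional for Gibbs-style
#' samplers: normal priors are given by mean and *precision* (so the
#' default `N(0, 0.01)` has variance 100), applied to the nest
#' coefficients and to every population-mean hyperparameter; each
#' precision hyperparameter `tau = 1/sigma^2` of the individual-level
#' coefficient distributions carries a diffuse `Gamma(1, 0.0001)` prior
#' (equivalently, an inverse-gamma prior on the variance).
#'
#' @param fixed_mean,fixed_prec normal prior mean and precision for
#'   fixed effects / population means.
#' @param sd_shape,sd_rate gamma shape and rate for the precision
#'   hyperparameters.
#' @return Object of class `"prior_spec"`.
#' @export
prior_spec <- function(fixed_mean = 0, fixed_prec = 0.01,
                       sd_shape = 1, sd_rate = 1e-4) {
  stopifnot(fixed_prec > 0, sd_shape > 0, sd_rate > 0)
  structure(list(fixed_mean = fixed_mean, fixed_prec = fixed_prec,
                 sd_shape = sd_shape, sd_rate = sd_rate),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param n_chains number of chains (>= 2 so convergence can be
#'   diagnosed; default 3).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded from each chain
#'   (default half of `n_iter`); proposal-scale adaptation runs only
#'   during burn-in, so retained draws come from a fixed kernel.
#' @param thin keep every `thin`-th post-burn-in draw (default sized so
#'   each chain retains at most ~2000 draws).
#' @param adapt_interval burn-in iterations between proposal-scale
#'   adjustments (acceptance-rate target window 0.23-0.44).
#' @param init_scale initial random-walk proposal SD.
#' @param init_sd SD of the overdispersed chain starting values.
#' @return Object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 3L, n_iter = 20000L,
                         n_burnin = floor(n_iter / 2),
                         thin = max(1L, floor((n_iter - n_burnin) / 2000)),
                         adapt_interval = 50L, init_scale = 0.1,
                         init_sd = 0.5) {
  stopifnot(n_chains >= 2L, n_iter > n_burnin, n_burnin >= 0L, thin >= 1L,
            (n_iter - n_burnin) >= thin)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 adapt_interval = as.integer(adapt_interval),
                 init_scale = init_scale, init_sd = init_sd),
            class = "mcmc_control")
}

#' Fit a Bayesian discrete-choice resource-selection model
#'
#' The single fitting entry point.  `model = "nest"` fits the pooled
#' conditional-logit model: one coefficient vector shared by all nest
#' choice sets, with `N(0, 0.01)`-precision priors.  `model =
#' "postfledging"` fits the hierarchical model: every individual-stage
#' combination gets its own coefficient vector drawn from stage-specific
#' normal population distributions (`beta_isk ~ N(mu_sk, sigma_sk)`),
#' with normal priors on the `mu` and diffuse gamma priors on the
#' precisions `1/sigma^2`.  Individuals observed in several stages
#' contribute one vector per stage; individuals with few choice sets
#' shrink toward the population distribution.
#'
#' Sampling is adaptive random-walk Metropolis within Gibbs (conjugate
#' Gibbs draws for `mu` and the precisions), 3 chains by default, with
#' overdispersed starting values and split-chain Rhat computed on all
#' monitored parameters.  Non-convergence is a reported state, not an
#' error: the fit is returned with `convergence$all_converged = FALSE`
#' and a warning.
#'
#' @param data a [choice_data] table.  Rows of the other period (nest
#'   vs. juvenile) are dropped automatically, but standardization is
#'   computed from the full table passed in (pooled over all locations),
#'   so pass the species dataset you want the z-scores anchored to.
#' @param model `"nest"` or `"postfledging"`.
#' @param spec a [model_spec()] (default: the full 13-coefficient model).
#' @param priors a [prior_spec()].
#' @param control an [mcmc_control()].
#' @param grouping named stage-to-model-stage map for the hierarchical
#'   model (default: the table's `stage_grouping` attribute; see
#'   [stage_grouping()]).
#' @param standardize `"zscore"` (default) or `"none"`; ignored when the
#'   table already carries a scaling record.
#' @param seed integer; chain `c` uses `seed + c - 1`.
#' @param prior_only if TRUE, draw from the prior instead of the
#'   posterior (the likelihood is switched off); used to validate the
#'   prior implementation.
#' @return Object of class `"dcfit"` with components `draws`
#'   ([posterior_draws]), `convergence` ([gelman_rubin()] report),
#'   `loglik_hat` (data log-likelihood at posterior means, with
#'   individual-level means for the hierarchical model), `estrella_r2`,
#'   `n_sets`, plus the data, scaling record, spec, priors, control and
#'   stage metadata.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `simulate`, `residuals`, `logLik`, `plot`.
#' @examples
#' \donttest{
#' sim <- generate_dataset(sim_config(preset = "recovery", seed = 7))
#' fit <- dcfit(sim$data, model = "postfledging",
#'              control = mcmc_control(n_iter = 2000), seed = 7)
#' coef(fit)
#' }
#' @export
dcfit <- function(data, model = c("nest", "postfledging"),
                  spec = model_spec(), priors = prior_spec(),
                  control = mcmc_control(),
                  grouping = attr(data, "stage_grouping"),
                  standardize = c("zscore", "none"),
                  seed = 1L, prior_only = FALSE) {
  model <- match.arg(model)
  standardize <- match.arg(standardize)
  stopifnot(inherits(data, "choice_data"))
  if (is.null(scaling_record(data)))
    data <- standardize_covariates(data, scheme = standardize)
  scaling <- scaling_record(data)

  sub <- if (model == "nest") data$stage == "nest" else data$stage != "nest"
  if (!any(sub)) stop("no ", model, " choice sets in the data")
  d <- as.data.frame(data)[sub, , drop = FALSE]
  da <- design_all(d, spec)
  n <- length(da$used)
  P <- length(spec$labels)

  if (model == "postfledging") {
    if (is.null(grouping)) stop("stage grouping required")
    stages_present <- unique(da$data$stage)
    if (!all(stages_present %in% names(grouping)))
      stop("stage grouping must cover: ",
           paste(setdiff(stages_present, names(grouping)), collapse = ", "))
    gidx <- unname(grouping[da$data$stage[seq(1, 3 * n, by = 3L)]])
    used_groups <- sort(unname(unique(grouping[stages_present])))
    if (!identical(used_groups, seq_along(used_groups)))
      stop("configuration error: model stage(s) with zero choice sets: ",
           paste(setdiff(seq_len(max(grouping)), used_groups),
                 collapse = ", "))
    S <- length(used_groups)
    stage_names <- vapply(seq_len(S), function(s) {
      paste(names(grouping)[grouping == s & names(grouping) %in%
                              stages_present], collapse = "+")
    }, "")
    ind <- da$data$individual_id[seq(1, 3 * n, by = 3L)]
    unit_key <- paste(stage_names[gidx], ind, sep = ".")
    units <- unique(data.frame(key = unit_key, stage = gidx,
                               individual = ind,
                               stringsAsFactors = FALSE))
    unit_of_set <- match(unit_key, units$key)
    U <- nrow(units)
  }

  # sampling
  draw_list <- vector("list", control$n_chains)
  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  for (ch in seq_len(control$n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    if (model == "nest") {
      if (prior_only) {
        draw_list[[ch]] <- matrix(
          rnorm(n_keep * P, priors$fixed_mean, 1 / sqrt(priors$fixed_prec)),
          n_keep, P)
      } else {
        res <- .sampler_pooled(da$X, da$used - 1L, control$n_iter,
                               control$n_burnin, control$thin,
                               priors$fixed_mean, priors$fixed_prec,
                               rnorm(P, 0, control$init_sd),
                               control$init_scale, control$adapt_interval)
        draw_list[[ch]] <- res$beta
      }
    } else {
      if (prior_only) {
        mu <- matrix(rnorm(n_keep * S * P, priors$fixed_mean,
                           1 / sqrt(priors$fixed_prec)), n_keep, S * P)
        sg <- matrix(1 / sqrt(rgamma(n_keep * S * P, priors$sd_shape,
                                     rate = priors$sd_rate)), n_keep, S * P)
        bu <- matrix(NA_real_, n_keep, U * P)
        for (u in seq_len(U)) {
          s <- units$stage[[u]]
          cols <- (s - 1L) * P + seq_len(P)
          bu[, (u - 1L) * P + seq_len(P)] <-
            rnorm(n_keep * P, mu[, cols], sg[, cols])
        }
        draw_list[[ch]] <- cbind(mu, sg, bu)
      } else {
        init_mu <- rnorm(S * P, 0, control$init_sd)
        # unit coefficients start spread around their stage's init_mu so
        # the first precision draw sees realistic between-unit variance
        idx <- rep((units$stage - 1L) * P, each = P) + seq_len(P)
        init_beta <- init_mu[idx] + rnorm(U * P, 0, control$init_sd)
        res <- .sampler_hier(da$X, da$used - 1L, unit_of_set - 1L,
                             units$stage - 1L, U, S,
                             control$n_iter, control$n_burnin, control$thin,
                             priors$fixed_mean, priors$fixed_prec,
                             priors$sd_shape, priors$sd_rate,
                             init_mu, init_beta,
                             control$init_scale, control$adapt_interval)
        draw_list[[ch]] <- cbind(res$mu, res$sigma, res$beta)
      }
    }
  }

  # registry and container
  if (model == "nest") {
    registry <- data.frame(name = spec$labels, kind = "beta",
                           stage = "nest", covariate = spec$labels,
                           unit = NA_character_, stringsAsFactors = FALSE)
  } else {
    lab <- function(kind, who) paste0(kind, "[", who, ",", spec$labels, "]")
    registry <- rbind(
      do.call(rbind, lapply(seq_len(S), function(s)
        data.frame(name = lab("mu", stage_names[s]), kind = "mu",
                   stage = stage_names[s], covariate = spec$labels,
                   unit = NA_character_, stringsAsFactors = FALSE))),
      do.call(rbind, lapply(seq_len(S), function(s)
        data.frame(name = lab("sigma", stage_names[s]), kind = "sigma",
                   stage = stage_names[s], covariate = spec$labels,
                   unit = NA_character_, stringsAsFactors = FALSE))),
      do.call(rbind, lapply(seq_len(U), function(u)
        data.frame(name = lab("beta", units$key[u]), kind = "beta_i",
                   stage = stage_names[units$stage[u]],
                   covariate = spec$labels, unit = units$key[u],
                   stringsAsFactors = FALSE))))
  }
  arr <- array(unlist(draw_list), dim = c(n_keep, nrow(registry),
                                          control$n_chains))
  arr <- aperm(arr, c(1, 3, 2))
  draws <- posterior_draws(arr, registry)

  conv <- gelman_rubin(draws)
  if (!prior_only && !conv$all_converged)
    warning("MCMC has not converged (max Rhat = ",
            round(max(conv$rhat$rhat), 3),
            "); consider more iterations", call. = FALSE)

  # fit statistics at posterior means
  pm <- colMeans(as.matrix(draws))
  if (model == "nest") {
    ll_hat <- data_loglik(d, setNames(pm, NULL)[registry$kind == "beta"],
                          spec)
  } else {
    bm <- matrix(pm[registry$kind == "beta_i"], U, P, byrow = TRUE)
    B <- bm[unit_of_set, , drop = FALSE]
    rownames(B) <- as.character(da$set_id)
    ll_hat <- data_loglik(d, B, spec)
  }

  out <- list(model = model, draws = draws, convergence = conv,
              data = d, scaling = scaling, spec = spec, priors = priors,
              control = control, seed = as.integer(seed),
              prior_only = prior_only,
              n_sets = n, loglik_null = n * log(1 / 3),
              loglik_hat = ll_hat,
              estrella_r2 = estrella_r2(min(ll_hat, 0), n, 3L))
  if (model == "postfledging") {
    out$grouping <- grouping
    out$stage_names <- stage_names
    out$units <- units
    out$unit_of_set <- unit_of_set
  }
  class(out) <- "dcfit"
  out
}

#' Fit the pooled nest-site selection model
#'
#' Thin wrapper over [dcfit()] with `model = "nest"`: a single shared
#' coefficient vector for all nest choice sets.
#'
#' @inheritParams dcfit
#' @param ... passed on to [dcfit()].
#' @return A `"dcfit"` object.
#' @export
fit_nest <- function(data, priors = prior_spec(),
                     control = mcmc_control(), ...) {
  dcfit(data, model = "nest", priors = priors, control = control, ...)
}

#' Fit the hierarchical postfledging selection model
#'
#' Thin wrapper over [dcfit()] with `model = "postfledging"`:
#' stage-structured population distributions over individual-level
#' coefficient vectors.  Pass `grouping = stage_grouping(pool_late_independent
#' = TRUE)` to pool the late-dependent and independent stages.
#'
#' @inheritParams dcfit
#' @param ... passed on to [dcfit()].
#' @return A `"dcfit"` object.
#' @export
fit_postfledging <- function(data, grouping = attr(data, "stage_grouping"),
                             priors = prior_spec(),
                             control = mcmc_control(), ...) {
  dcfit(data, model = "postfledging", grouping = grouping,
        priors = priors, control = control, ...)
}
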