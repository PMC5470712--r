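#' Configuration for the synthetic choice-set generator
#'
#' Bundles everything the generator needs: the roster (stages,
#' individuals per stage, sets per individual), the ground-truth
#' population-level coefficient distributions, the covariate marginals
#' with their within-set correlation, and the seed.  Three presets are
#' provided:
#'
#' * `"fieldlike"` (default): three juvenile stages with a roster shaped
#'   like a season of telemetry on a forest songbird (39/30/24
#'   individuals, 2-8 sets each, so 100-250 sets per stage), plus 170
#'   nest sets with a shared coefficient vector.
#' * `"recovery"`: 2 stages x 40 individuals x 12 sets each (960 sets),
#'   no nest sets; the workhorse for parameter-recovery studies.
#' * `"null"`: as `"recovery"` but all population means 0 and population
#'   SDs 0.05 -- selection indistinguishable from random.
#'
#' Ground-truth coefficients are on the pooled z-score scale of the
#' emitted dataset (see [generate_dataset()]).  Covariate marginals
#' default to the natural ranges of the field protocol -- litter depth
#' 0-10 cm, understory density 0-1, stem densities 0-2000/ha, canopy
#' 0-100 %, edge distance 10-400 m -- and are presets, not estimates.
#'
#' @param preset `"fieldlike"`, `"recovery"` or `"null"`.
#' @param stages character vector of juvenile stage labels.
#' @param n_individuals_per_stage integer vector, one per stage.
#' @param sets_per_individual integer, or a length-2 range from which a
#'   per-individual count is drawn uniformly; either a single value/range
#'   for all stages or a list with one entry per stage.
#' @param population_means,population_sds numeric matrices, stages x 13
#'   (rows may be named by stage); SDs must be positive.
#' @param nest_n_sets number of nest choice sets (0 to omit the nest
#'   component).
#' @param nest_beta shared nest coefficient vector (length 13).
#' @param covariate_model named list of marginals, one per covariate;
#'   each entry a list with `dist` (`"gamma"`, `"beta"` or `"unif"`) and
#'   its parameters plus `min`/`max` clipping bounds.
#' @param rho within-set correlation of the vegetation covariates on the
#'   latent Gaussian scale, in `[0, 1)`.
#' @param rho_edge within-set correlation of edge distance (high by
#'   default: the three locations of a set sit within ~50 m of each
#'   other, so their edge distances are similar but not identical).
#' @param siblings_per_brood tracked individuals per brood (>1 exercises
#'   [filter_one_per_brood()]).
#' @param independence_day day postfledge at which simulated juveniles
#'   are labelled independent.
#' @param species species label stamped on the dataset.
#' @param seed integer seed; every random quantity derives from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(preset = c("fieldlike", "recovery", "null"),
                       stages = NULL,
                       n_individuals_per_stage = NULL,
                       sets_per_individual = NULL,
                       population_means = NULL,
                       population_sds = NULL,
                       nest_n_sets = NULL,
                       nest_beta = NULL,
                       covariate_model = default_covariate_model(),
                       rho = 0.3,
                       rho_edge = 0.9,
                       siblings_per_brood = 1L,
                       independence_day = 20L,
                       species = "flycatcher",
                       seed = 1L) {
  preset <- match.arg(preset)
  P <- 13L
  if (preset == "fieldlike") {
    if (is.null(stages))
      stages <- c("early_dependent", "late_dependent", "independent")
    if (is.null(n_individuals_per_stage))
      n_individuals_per_stage <- c(39L, 30L, 24L)
    if (is.null(sets_per_individual))
      sets_per_individual <- list(c(2L, 5L), c(4L, 8L), c(3L, 7L))
    if (is.null(nest_n_sets)) nest_n_sets <- 170L
    if (is.null(population_means))
      population_means <- rbind(
        early_dependent = c(0.30, -0.20, 0.10, 0.00, 0.10, 0.35, -0.15,
                            0.10, -0.15, 0, 0, 0, 0.10),
        late_dependent  = c(0.05, 0.45, 0.25, 0.05, 0.00, 0.25, -0.05,
                            0.00, 0.30, 0, 0.05, 0, 0.00),
        independent     = c(-0.20, 0.60, 0.30, 0.10, -0.05, 0.15, 0.05,
                            -0.05, 0.20, 0.05, 0, 0, 0.00))
    if (is.null(population_sds))
      population_sds <- matrix(0.3, length(stages), P)
  } else {
    if (is.null(stages)) stages <- c("early_dependent", "late_dependent")
    if (is.null(n_individuals_per_stage))
      n_individuals_per_stage <- rep(40L, length(stages))
    if (is.null(sets_per_individual)) sets_per_individual <- 12L
    if (is.null(nest_n_sets)) nest_n_sets <- 0L
    if (is.null(population_means))
      population_means <- if (preset == "null")
        matrix(0, length(stages), P)
      else
        rbind(c(0.40, -0.30, 0.30, 0.00, 0.10, 0.30, -0.20,
                0.15, -0.10, 0, 0, 0.10, 0),
              c(-0.20, 0.50, 0.20, 0.10, 0.00, 0.25, 0.10,
                -0.10, 0.20, 0, 0.05, 0, 0.10))[seq_along(stages), ,
                                                drop = FALSE]
    if (is.null(population_sds))
      population_sds <- matrix(if (preset == "null") 0.05 else 0.3,
                               length(stages), P)
  }
  if (is.null(nest_beta))
    nest_beta <- c(0.30, -0.25, 0.00, 0.10, 0.15, 0.40, -0.10,
                   0.00, 0.12, 0, 0, 0, -0.08)
  population_means <- matrix(population_means, length(stages), P)
  population_sds <- matrix(population_sds, length(stages), P)
  rownames(population_means) <- rownames(population_sds) <- stages
  labels <- model_spec()$labels
  colnames(population_means) <- colnames(population_sds) <- labels
  names(nest_beta) <- labels
  stopifnot(all(population_sds > 0), rho >= 0, rho < 1,
            rho_edge >= 0, rho_edge < 1,
            length(n_individuals_per_stage) == length(stages))
  if (!is.list(sets_per_individual))
    sets_per_individual <- rep(list(sets_per_individual), length(stages))
  stopifnot(all(vapply(sets_per_individual, min, 0) >= 1))
  structure(list(preset = preset, stages = stages,
                 n_individuals_per_stage = n_individuals_per_stage,
                 sets_per_individual = sets_per_individual,
                 population_means = population_means,
                 population_sds = population_sds,
                 nest_n_sets = nest_n_sets, nest_beta = nest_beta,
                 covariate_model = covariate_model,
                 rho = rho, rho_edge = rho_edge,
                 siblings_per_brood = as.integer(siblings_per_brood),
                 independence_day = as.integer(independence_day),
                 species = species, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default covariate marginals (field-protocol ranges)
#' @return Named list of marginal definitions, one per covariate.
#' @export
default_covariate_model <- function() {
  list(
    litter_depth = list(dist = "gamma", shape = 4, scale = 0.75,
                        min = 0, max = 10),
    understory_density = list(dist = "beta", a = 2, b = 2,
                              min = 0, max = 1),
    sapling_density = list(dist = "gamma", shape = 1.5, scale = 400,
                           min = 0, max = 2000),
    pole_density = list(dist = "gamma", shape = 2, scale = 150,
                        min = 0, max = 2000),
    saw_density = list(dist = "gamma", shape = 2, scale = 75,
                       min = 0, max = 2000),
    canopy_cover = list(dist = "beta", a = 5, b = 1.2,
                        min = 0, max = 100),
    edge_distance = list(dist = "unif", min = 10, max = 400))
}

# Quantile transform of a latent-normal u in (0,1) under one marginal.
marginal_quantile <- function(m, u) {
  x <- switch(m$dist,
    gamma = qgamma(u, shape = m$shape, scale = m$scale),
    beta  = m$min + (m$max - m$min) * qbeta(u, m$a, m$b),
    unif  = m$min + (m$max - m$min) * u,
    stop("config error: unknown marginal distribution '", m$dist, "'"))
  pmin(pmax(x, m$min), m$max)
}

#' Simulate the covariates of one choice set
#'
#' Draws the three locations of a set from the configured marginals with
#' within-set correlation induced by a Gaussian copula: each covariate
#' shares a set-level latent normal (weight `sqrt(rho)`) plus a
#' location-level residual, then is mapped through the marginal's
#' quantile function.  This emulates the field design -- available
#' points lie ~50 m from the used point, so the three locations share
#' local habitat -- without simulating geometry.  Uses the ambient R RNG.
#'
#' @param cfg a [sim_config()].
#' @param n_sets number of sets to draw at once.
#' @return A `3*n_sets`-row data.frame with the seven covariate columns,
#'   values clipped into their valid ranges.
#' @export
simulate_covariates <- function(cfg, n_sets = 1L) {
  cv <- all_covariates()
  bad <- setdiff(cv, names(cfg$covariate_model))
  if (length(bad) > 0)
    stop("config error: no marginal for ", paste(bad, collapse = ", "))
  out <- matrix(NA_real_, 3L * n_sets, length(cv),
                dimnames = list(NULL, cv))
  for (v in cv) {
    rho <- if (v == "edge_distance") cfg$rho_edge else cfg$rho
    z_set <- rep(rnorm(n_sets), each = 3L)
    z <- sqrt(rho) * z_set + sqrt(1 - rho) * rnorm(3L * n_sets)
    out[, v] <- marginal_quantile(cfg$covariate_model[[v]], pnorm(z))
  }
  as.data.frame(out)
}

#' Simulate one individual's coefficient vector
#'
#' Component-wise independent normal draws around the stage's population
#' means, the random-coefficient structure assumed by the hierarchical
#' model.  Uses the ambient R RNG.
#'
#' @param mu,sigma numeric vectors of population means and SDs
#'   (`sigma > 0`).
#' @return Numeric coefficient vector with `mu`'s names.
#' @export
simulate_individual_coefficients <- function(mu, sigma) {
  stopifnot(length(mu) == length(sigma), all(sigma > 0))
  setNames(rnorm(length(mu), mu, sigma), names(mu))
}

#' Simulate the choice within one set
#'
#' Draws the used-location index with probability proportional to
#' `exp(utility)`, using exactly the design-matrix and probability code
#' ([build_design()], [choice_probabilities()]) used by inference, so the
#' generator's implied likelihood is the fitted likelihood by
#' construction.
#'
#' @param locations 3-row data.frame of one set's locations.
#' @param beta coefficient vector.
#' @param spec a [model_spec()].
#' @return Integer in 1:3, the chosen (used) position.
#' @export
simulate_choice <- function(locations, beta, spec = model_spec()) {
  p <- choice_probabilities(build_design(locations, spec), beta)
  sample.int(3L, 1L, prob = p)
}

#' Generate a synthetic choice-set dataset with known ground truth
#'
#' Builds a full dataset under the generative model the analysis
#' assumes: covariates drawn per set from the configured marginals,
#' individual-level coefficient vectors drawn from the stage-specific
#' normal population distributions, and the used location drawn
#' multinomial-logit from the utilities.  Utilities are computed on the
#' pooled z-score scale of the emitted dataset (the same standardization
#' [standardize_covariates()] applies at fit time), so ground-truth
#' coefficients are per-SD effects and the generator and the fitted
#' model share one likelihood exactly.  The emitted table carries the
#' covariates on their original field scales and passes all
#' [choice_data()] validation.
#'
#' Fully reproducible: the same `cfg` (including its seed) yields a
#' byte-identical table.  The caller's RNG state is left untouched.
#'
#' @param cfg a [sim_config()].
#' @return List with `data` (a [choice_data]) and `truth` (class
#'   `"sim_truth"`: population means/SDs, per individual-stage
#'   coefficient vectors, the nest coefficient vector, the pooled
#'   scaling record, and the seed).
#' @examples
#' out <- generate_dataset(sim_config(preset = "recovery", seed = 42))
#' nrow(out$data) / 3  # 960 choice sets
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(cfg$seed)

  S <- length(cfg$stages)
  pool_n <- max(cfg$n_individuals_per_stage, 0L)
  ids <- sprintf("bird%03d", seq_len(pool_n))
  broods <- sprintf("brood%03d",
                    ceiling(seq_len(pool_n) / cfg$siblings_per_brood))
  roster <- list()
  for (s in seq_len(S)) {
    n_s <- cfg$n_individuals_per_stage[[s]]
    rng <- cfg$sets_per_individual[[s]]
    k <- if (length(rng) == 1L) rep(rng, n_s)
         else sample(seq(rng[1], rng[2]), n_s, replace = TRUE)
    roster[[s]] <- data.frame(stage = cfg$stages[[s]],
                              individual_id = ids[seq_len(n_s)],
                              brood_id = broods[seq_len(n_s)],
                              n_sets = k)
  }
  roster <- do.call(rbind, roster)

  day_range <- function(stage) switch(stage,
    early_dependent = c(0L, 7L),
    late_dependent = c(8L, cfg$independence_day - 1L),
    independent = c(cfg$independence_day, cfg$independence_day + 25L))

  # covariates for every set (juvenile then nest), then pooled z-scoring
  n_juv <- sum(roster$n_sets)
  n_all <- n_juv + cfg$nest_n_sets
  covs <- simulate_covariates(cfg, n_sets = n_all)
  means <- vapply(covs, mean, 0)
  sds <- vapply(covs, sd, 0)
  zcovs <- as.data.frame(mapply(function(x, m, s) (x - m) / s,
                                covs, means, sds))
  spec <- model_spec()

  # individual-stage ground-truth coefficients
  units <- unique(roster[, c("stage", "individual_id")])
  beta_units <- t(vapply(seq_len(nrow(units)), function(i) {
    s <- units$stage[[i]]
    simulate_individual_coefficients(cfg$population_means[s, ],
                                     cfg$population_sds[s, ])
  }, numeric(13L)))
  rownames(beta_units) <- paste(units$stage, units$individual_id, sep = ".")

  rows <- vector("list", n_all)
  set_i <- 0L
  for (r in seq_len(nrow(roster))) {
    stage <- roster$stage[[r]]
    dr <- day_range(stage)
    b <- beta_units[paste(stage, roster$individual_id[[r]], sep = "."), ]
    for (k in seq_len(roster$n_sets[[r]])) {
      set_i <- set_i + 1L
      loc <- zcovs[(3L * set_i - 2L):(3L * set_i), , drop = FALSE]
      used <- simulate_choice(loc, b, spec)
      rows[[set_i]] <- data.frame(
        set_id = sprintf("set%05d", set_i), species = cfg$species,
        individual_id = roster$individual_id[[r]],
        brood_id = roster$brood_id[[r]], stage = stage,
        day_postfledge = sample(seq(dr[1], dr[2]), 1L),
        role = replace(rep("available", 3L), used, "used"))
    }
  }
  for (k in seq_len(cfg$nest_n_sets)) {
    set_i <- set_i + 1L
    loc <- zcovs[(3L * set_i - 2L):(3L * set_i), , drop = FALSE]
    used <- simulate_choice(loc, cfg$nest_beta, spec)
    nid <- sprintf("nest%03d", k)
    rows[[set_i]] <- data.frame(
      set_id = sprintf("set%05d", set_i), species = cfg$species,
      individual_id = nid, brood_id = nid, stage = "nest",
      day_postfledge = NA_integer_,
      role = replace(rep("available", 3L), used, "used"))
  }
  meta <- do.call(rbind, rows)  # each element is already 3 rows (role recycles the scalars)
  df <- cbind(meta, covs)
  rownames(df) <- NULL

  grouping <- stage_grouping()[intersect(names(stage_grouping()),
                                         cfg$stages)]
  grouping[] <- match(grouping, sort(unique(grouping)))  # contiguous 1..S
  d <- choice_data(df, species = cfg$species, stage_grouping = grouping)
  truth <- structure(list(
    population_means = cfg$population_means,
    population_sds = cfg$population_sds,
    individual_coefficients = beta_units,
    nest_beta = if (cfg$nest_n_sets > 0) cfg$nest_beta else NULL,
    scaling = list(scheme = "zscore", means = means, sds = sds),
    seed = cfg$seed), class = "sim_truth")
  list(data = d, truth = truth)
}
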