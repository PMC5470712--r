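# In-code fixtures shared across test files.

# A minimal valid location row on field scales.
loc_row <- function(set_id, role, stage = "nest", individual = "b1",
                    brood = individual, day = NA_integer_,
                    litter = 3, under = 0.5, sapl = 500, pole = 300,
                    saw = 150, canopy = 85, edge = 120,
                    species = "flycatcher") {
  data.frame(set_id = set_id, species = species, individual_id = individual,
             brood_id = brood, stage = stage, day_postfledge = day,
             role = role, litter_depth = litter, understory_density = under,
             sapling_density = sapl, pole_density = pole, saw_density = saw,
             canopy_cover = canopy, edge_distance = edge)
}

# n complete choice sets with covariates jittered around the defaults.
make_choice_table <- function(n_sets = 3, stage = "nest", seed = 1,
                              individual = "b1", species = "flycatcher") {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sets), function(i) {
    used_at <- sample.int(3, 1)
    do.call(rbind, lapply(1:3, function(j) {
      loc_row(sprintf("s%03d", i),
              role = if (j == used_at) "used" else "available",
              stage = stage, individual = individual,
              day = if (stage == "nest") NA_integer_ else 3L,
              litter = runif(1, 1, 6), under = runif(1, 0.2, 0.8),
              sapl = runif(1, 100, 900), pole = runif(1, 100, 500),
              saw = runif(1, 50, 250), canopy = runif(1, 60, 100),
              edge = runif(1, 20, 380), species = species)
    }))
  }))
}

# Small hierarchical simulation used by several inference tests.
quick_sim_config <- function(seed = 1, ...) {
  sim_config(preset = "recovery", stages = "early_dependent",
             n_individuals_per_stage = 15L, sets_per_individual = 8L,
             population_means = matrix(
               c(0.5, -0.4, 0.3, 0, 0.2, 0.3, -0.2, 0, 0, 0, 0, 0, 0), 1),
             population_sds = matrix(0.3, 1, 13), seed = seed, ...)
}

quick_control <- function(n_iter = 2000L, ...) {
  mcmc_control(n_iter = n_iter, ...)
}

# Naive conditional-logit log-likelihood, written independently of the
# package internals: explicit per-set probability normalisation.
naive_data_loglik <- function(d, beta, spec = model_spec()) {
  total <- 0
  for (sid in unique(d$set_id)) {
    rows <- d[d$set_id == sid, , drop = FALSE]
    M <- as.matrix(rows[, spec$mains, drop = FALSE])
    X <- M
    if (spec$edge_term) X <- cbind(X, rows$edge_distance)
    if (spec$interactions) X <- cbind(X, M * rows$edge_distance)
    V <- as.numeric(X %*% beta)
    p <- exp(V) / sum(exp(V))
    total <- total + log(p[rows$role == "used"])
  }
  total
}
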