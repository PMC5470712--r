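#' Posterior coefficient summaries
#'
#' For each selected parameter: the posterior mean, the central 95%
#' credible interval (2.5th/97.5th percentiles of the pooled post-burn
#' chains) and `f`, the proportion of the posterior sharing the sign of
#' the mean -- a directional-confidence summary approaching 1 as the
#' evidence for the effect's direction strengthens.  Draws exactly equal
#' to zero count as agreeing with the mean's sign.
#'
#' @param draws a [posterior_draws] object (or a `"dcfit"`, whose draws
#'   are used).
#' @param which `"population"` (nest `beta` plus `mu`/`sigma`), `"all"`,
#'   or a character vector of parameter names/kinds.
#' @return data.frame with columns `parameter`, `kind`, `stage`,
#'   `covariate`, `mean`, `cri_lo`, `cri_hi`, `f`.
#' @export
summarize_coefficients <- function(draws, which = "population") {
  if (inherits(draws, "dcfit")) draws <- draws$draws
  stopifnot(inherits(draws, "posterior_draws"))
  reg <- draws$registry
  keep <- if (identical(which, "all")) rep(TRUE, nrow(reg))
    else if (identical(which, "population"))
      reg$kind %in% c("beta", "mu", "sigma")
    else reg$name %in% which | reg$kind %in% which
  if (!any(keep)) stop("empty parameter selection")
  m <- as.matrix(draws)[, keep, drop = FALSE]
  mu <- colMeans(m)
  qs <- apply(m, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  f <- vapply(seq_len(ncol(m)), function(j) {
    s <- sign(mu[[j]])
    if (s == 0) s <- 1  # exact-zero mean: no direction; ties give f = 0.5
    mean(sign(m[, j]) == s | m[, j] == 0)
  }, 0)
  out <- data.frame(parameter = reg$name[keep], kind = reg$kind[keep],
                    stage = reg$stage[keep], covariate = reg$covariate[keep],
                    mean = unname(mu), cri_lo = qs[1, ], cri_hi = qs[2, ],
                    f = f, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Selection ratio from a coefficient summary
#'
#' The selection ratio `exp(beta)` is the multiplicative change in
#' relative selection probability per one-unit covariate change, all
#' else constant; its CRI is the exponentiated coefficient CRI.  A
#' ratio is flagged ineligible (not interpretable on its own) when the
#' covariate's interaction with edge distance is strongly supported
#' (interaction `f >= 0.90`), because selection then depends on more
#' than one coefficient; the ratio is still computed.
#'
#' @param summary one-or-more rows of [summarize_coefficients()] output
#'   for main-effect coefficients.
#' @param interaction_f the `f` value(s) of the corresponding
#'   interaction term(s); `NA` (no interaction in the model) counts as
#'   eligible.
#' @return data.frame with `covariate`, `stage`, `ratio`, `ratio_lo`,
#'   `ratio_hi`, `interaction_f`, `eligible`.
#' @examples
#' s <- data.frame(parameter = "understory_density", kind = "mu",
#'                 stage = "late", covariate = "understory_density",
#'                 mean = 1.16, cri_lo = 0.5, cri_hi = 1.8, f = 0.99)
#' selection_ratio(s, interaction_f = 0.5)$ratio  # exp(1.16) ~ 3.19
#' @export
selection_ratio <- function(summary, interaction_f = NA_real_) {
  stopifnot(is.data.frame(summary),
            all(c("mean", "cri_lo", "cri_hi") %in% names(summary)))
  interaction_f <- rep_len(interaction_f, nrow(summary))
  data.frame(covariate = summary$covariate, stage = summary$stage,
             ratio = exp(summary$mean), ratio_lo = exp(summary$cri_lo),
             ratio_hi = exp(summary$cri_hi),
             interaction_f = interaction_f,
             eligible = is.na(interaction_f) | interaction_f < 0.90,
             stringsAsFactors = FALSE)
}

#' Estrella's pseudo R-squared for discrete choice models
#'
#' With null log-likelihood `L0 = n log(1/J)` (every alternative equally
#' likely), `R2 = 1 - (L/L0)^(-(2/n) L0)`.  It equals 0 when the model
#' predicts at random (`L = L0`) and 1 at perfect prediction (`L = 0`);
#' values near 0.25 and 0.50 are conventionally read as modest and
#' strong predictive accuracy.
#'
#' @param loglik_hat model log-likelihood at the chosen point estimate
#'   (must be <= 0).
#' @param n_sets number of choice sets.
#' @param n_alternatives alternatives per set (3 in this design).
#' @return The pseudo R-squared (a scalar <= 1).
#' @examples
#' estrella_r2(100 * log(1/3), 100)  # 0
#' estrella_r2(0, 100)               # 1
#' @export
estrella_r2 <- function(loglik_hat, n_sets, n_alternatives = 3L) {
  if (loglik_hat > 0) stop("loglik_hat must be <= 0")
  stopifnot(n_sets >= 1, n_alternatives >= 2)
  L0 <- n_sets * log(1 / n_alternatives)
  1 - (loglik_hat / L0)^(-(2 / n_sets) * L0)
}

#' Fit statistics
#'
#' @param fit a `"dcfit"` object.
#' @return List with `loglik_hat` (data log-likelihood at posterior
#'   means; individual-level coefficient means for the hierarchical
#'   model), `loglik_null`, `n_sets` and `estrella_r2`.
#' @export
fit_stats <- function(fit) {
  stopifnot(inherits(fit, "dcfit"))
  list(loglik_hat = fit$loglik_hat, loglik_null = fit$loglik_null,
       n_sets = fit$n_sets, estrella_r2 = fit$estrella_r2)
}

#' Relative probability-of-use curve
#'
#' Posterior curve of relative selection probability over the observed
#' range of one covariate, holding all other covariates at their dataset
#' means.  For each posterior draw, `r(x) = exp(V(x) - V(x_bar))`, where
#' both utilities share the scenario's edge distance, so the curve is
#' anchored at 1 at the dataset-mean focal value (anchoring changes the
#' y-scale only, never the shape).  When the focal covariate's
#' interaction with edge distance is strongly supported (`f >= 0.90`),
#' selection depends on where the choice set sits relative to edge, and
#' a scenario must be chosen: `"near"` (10th percentile of observed edge
#' distances) or `"far"` (90th percentile).
#'
#' @param fit a `"dcfit"` object.
#' @param focal name of a main-effect covariate in the model.
#' @param scenario `"none"` (edge at its mean), `"near"` or `"far"`.
#' @param stage for postfledging fits, which model stage's population
#'   coefficients to use (defaults to the first).
#' @param n_grid number of grid points over the observed range.
#' @return Object of class `"use_curve"`: data.frame with `x` (focal
#'   value on the original field scale), `mean`, `cri_lo`, `cri_hi`;
#'   attributes record the focal covariate, scenario and the edge
#'   distance used (original scale).
#' @export
use_curve <- function(fit, focal, scenario = c("none", "near", "far"),
                      stage = NULL, n_grid = 50L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(fit, "dcfit"))
  spec <- fit$spec
  if (!focal %in% c(spec$mains, if (spec$edge_term) "edge_distance"))
    stop("focal covariate '", focal, "' is not a main effect in the model")
  reg <- fit$draws$registry
  m <- as.matrix(fit$draws)
  if (fit$model == "nest") {
    keep <- reg$kind == "beta"
  } else {
    if (is.null(stage)) stage <- fit$stage_names[[1]]
    if (!stage %in% fit$stage_names)
      stop("unknown model stage '", stage, "'")
    keep <- reg$kind == "mu" & reg$stage == stage
  }
  B <- m[, keep, drop = FALSE]          # draws x P, columns in label order
  colnames(B) <- reg$covariate[keep]

  int_lab <- paste0(focal, ":edge_distance")
  has_int <- spec$interactions && int_lab %in% spec$labels
  if (has_int) {
    bi <- B[, int_lab]
    s <- sign(mean(bi))
    # a direction-free (mean-zero) interaction cannot be "supported"
    f_int <- if (s == 0) 0.5 else mean(sign(bi) == s | bi == 0)
    if (f_int >= 0.90 && scenario == "none")
      stop("interaction of ", focal, " with edge distance is strongly ",
           "supported (f = ", round(f_int, 2),
           "); choose scenario 'near' or 'far'")
  }

  d <- fit$data                          # model scale
  xr <- range(d[[focal]])
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  edge_val <- switch(scenario,
    none = mean(d$edge_distance),
    near = unname(quantile(d$edge_distance, 0.10)),
    far  = unname(quantile(d$edge_distance, 0.90)))

  base <- vapply(all_covariates(), function(v) mean(d[[v]]), 0)
  mk_row <- function(xval) {
    r <- base
    r[[focal]] <- xval
    if (focal != "edge_distance") r[["edge_distance"]] <- edge_val
    as.data.frame(as.list(r))
  }
  ref <- build_design(mk_row(mean(d[[focal]])), spec)[1, , drop = TRUE]
  G <- do.call(rbind, lapply(grid, function(x)
    build_design(mk_row(x), spec)[1, ]))
  delta <- sweep(G, 2L, ref)             # n_grid x P
  curves <- exp(delta %*% t(B[, spec$labels, drop = FALSE]))  # grid x draws
  qs <- apply(curves, 1L, quantile, probs = c(0.025, 0.975), names = FALSE)

  rec <- fit$scaling
  to_orig <- function(v, x) if (is.null(rec) || rec$scheme == "none") x
    else x * rec$sds[[v]] + rec$means[[v]]
  out <- data.frame(x = to_orig(focal, grid),
                    mean = rowMeans(curves),
                    cri_lo = qs[1, ], cri_hi = qs[2, ])
  structure(out, focal = focal, scenario = scenario,
            stage = if (fit$model == "nest") "nest" else stage,
            edge_distance = to_orig("edge_distance", edge_val),
            class = c("use_curve", "data.frame"))
}

#' @export
plot.use_curve <- function(x, ...) {
  plot(x$x, x$mean, type = "l", ylim = range(x$cri_lo, x$cri_hi),
       xlab = attr(x, "focal"), ylab = "relative probability of use", ...)
  lines(x$x, x$cri_lo, lty = 2)
  lines(x$x, x$cri_hi, lty = 2)
  abline(h = 1, lty = 3)
  invisible(x)
}

#' Stage-by-covariate coefficient report
#'
#' One row per (stage, parameter): posterior mean, 95% CRI, `f`, and --
#' for main-effect coefficients whose edge interaction is not strongly
#' supported -- the selection ratio with its CRI.  The edge-distance
#' main effect is judged against the strongest of the six interactions.
#' Machine-readable (plain data.frame, export with [utils::write.csv]).
#'
#' @param fit a `"dcfit"` object.
#' @return data.frame report.
#' @export
coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "dcfit"))
  sm <- summarize_coefficients(fit$draws, which = "population")
  sm <- sm[sm$kind %in% c("beta", "mu"), , drop = FALSE]
  spec <- fit$spec
  out <- sm
  out$selection_ratio <- NA_real_
  out$ratio_lo <- NA_real_
  out$ratio_hi <- NA_real_
  out$eligible <- NA
  for (i in seq_len(nrow(out))) {
    cv <- out$covariate[[i]]
    if (grepl(":", cv, fixed = TRUE)) next   # interaction row: no ratio
    if (!spec$interactions) { fi <- NA_real_ }
    else if (cv == "edge_distance") {
      rows <- sm$stage == out$stage[[i]] & grepl(":", sm$covariate)
      fi <- if (any(rows)) max(sm$f[rows]) else NA_real_
    } else {
      row <- sm$stage == out$stage[[i]] &
        sm$covariate == paste0(cv, ":edge_distance")
      fi <- if (any(row)) sm$f[row] else NA_real_
    }
    r <- selection_ratio(out[i, , drop = FALSE], interaction_f = fi)
    out$selection_ratio[[i]] <- r$ratio
    out$ratio_lo[[i]] <- r$ratio_lo
    out$ratio_hi[[i]] <- r$ratio_hi
    out$eligible[[i]] <- r$eligible
  }
  out
}
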