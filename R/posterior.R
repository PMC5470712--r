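#' Posterior draws container
#'
#' Labelled `draws x chains x parameters` array of all monitored
#' quantities, with a registry distinguishing parameter kinds: the
#' pooled nest coefficients (`beta`), population means (`mu`),
#' population SDs (`sigma`) and individual-level coefficients
#' (`beta_i`).  Built by [dcfit()]; users rarely construct it directly.
#'
#' @param draws numeric array `n_draws x n_chains x n_params`, third
#'   dimension named.
#' @param registry data.frame with one row per parameter: `name`,
#'   `kind`, `stage`, `covariate`, `unit`.
#' @return Object of class `"posterior_draws"`.
#' @export
posterior_draws <- function(draws, registry) {
  stopifnot(length(dim(draws)) == 3L,
            dim(draws)[3] == nrow(registry),
            !anyNA(draws), all(is.finite(draws)))
  dimnames(draws)[[3]] <- registry$name
  sig <- registry$kind == "sigma"
  if (any(sig) && any(draws[, , sig, drop = FALSE] <= 0))
    stop("sigma draws must be positive")
  if (anyDuplicated(registry$name)) stop("parameter labels must be unique")
  structure(list(draws = draws, registry = registry),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("Posterior draws:", d[1], "draws x", d[2], "chains x", d[3],
      "parameters\n")
  cat("  kinds:", paste(names(table(x$registry$kind)),
                        table(x$registry$kind), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Pool chains into a draws matrix
#'
#' @param x a [posterior_draws] object.
#' @param ... unused.
#' @return Matrix `(n_draws * n_chains) x n_params`, chains stacked.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(x$draws)[[3]]
  m
}

# subset parameters by registry predicate; returns posterior_draws
subset_draws <- function(x, keep) {
  posterior_draws(x$draws[, , keep, drop = FALSE],
                  x$registry[keep, , drop = FALSE])
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor (Rhat) per monitored parameter,
#' using the split-chain variant: each chain is halved, and the
#' between/within variance ratio is computed over the `2C` half-chains.
#' Splitting also flags within-chain drift that the original diagnostic
#' misses, and is never less conservative.  A parameter converges when
#' `Rhat <= threshold`; the conventional threshold 1.1 is inclusive.
#'
#' @param x a [posterior_draws] object with at least 2 chains and 10
#'   retained draws per chain.
#' @param threshold convergence cutoff (default 1.1).
#' @return Object of class `"convergence_report"`: data.frame `rhat`
#'   with one row per parameter, logical `all_converged`, and the
#'   threshold.
#' @export
gelman_rubin <- function(x, threshold = 1.1) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- dim(x$draws)
  if (d[2] < 2L) stop("need at least 2 chains for Rhat")
  if (d[1] < 10L) stop("need at least 10 retained draws per chain")
  m <- floor(d[1] / 2L)
  rhat <- vapply(seq_len(d[3]), function(j) {
    halves <- cbind(x$draws[seq_len(m), , j, drop = TRUE],
                    x$draws[m + seq_len(m), , j, drop = TRUE])
    W <- mean(apply(halves, 2L, var))
    B <- m * var(colMeans(halves))
    if (W == 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  }, 0)
  tab <- data.frame(parameter = x$registry$name, rhat = rhat,
                    kind = x$registry$kind)
  structure(list(rhat = tab, all_converged = all(rhat <= threshold),
                 threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence (split-chain Rhat, threshold ", x$threshold, "):\n",
      sep = "")
  cat("  max Rhat =", round(max(x$rhat$rhat), 4),
      if (x$all_converged) " -- all parameters converged\n"
      else " -- NOT converged\n")
  bad <- x$rhat[x$rhat$rhat > x$threshold, , drop = FALSE]
  if (nrow(bad) > 0) {
    cat("  worst parameters:\n")
    print(head(bad[order(-bad$rhat), ], 5))
  }
  invisible(x)
}
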