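#' @export
print.dcfit <- function(x, ...) {
  cat("Bayesian discrete-choice resource-selection fit (",
      x$model, " model)\n", sep = "")
  cat("  choice sets:", x$n_sets,
      if (x$model == "postfledging")
        paste0("; individual-stage units: ", nrow(x$units),
               "; model stages: ", paste(x$stage_names, collapse = ", ")),
      "\n")
  cat("  chains:", x$control$n_chains, "x", x$control$n_iter,
      "iterations (burn-in", x$control$n_burnin, ", thin",
      x$control$thin, ")\n")
  cat("  max Rhat:", round(max(x$convergence$rhat$rhat), 3),
      if (x$convergence$all_converged) "(converged)" else "(NOT converged)",
      "\n")
  cat("  Estrella's R2:", round(x$estrella_r2, 3), "\n")
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' For the nest model, the shared coefficient vector; for the
#' postfledging model, a `stages x coefficients` matrix of population
#' means (`mu`).
#'
#' @param object a `"dcfit"` object.
#' @param ... unused.
#' @return Named vector or matrix of posterior means.
#' @export
coef.dcfit <- function(object, ...) {
  m <- as.matrix(object$draws)
  reg <- object$draws$registry
  if (object$model == "nest") {
    setNames(colMeans(m[, reg$kind == "beta", drop = FALSE]),
             object$spec$labels)
  } else {
    mu <- colMeans(m[, reg$kind == "mu", drop = FALSE])
    matrix(mu, length(object$stage_names), length(object$spec$labels),
           byrow = TRUE,
           dimnames = list(object$stage_names, object$spec$labels))
  }
}

#' @export
logLik.dcfit <- function(object, ...) {
  structure(object$loglik_hat,
            df = sum(object$draws$registry$kind %in% c("beta", "mu", "sigma")),
            nobs = object$n_sets, class = "logLik")
}

#' Choice probabilities for new choice sets
#'
#' Probabilities over the three alternatives of each set in `newdata`,
#' evaluated at the posterior-mean population coefficients (the stage's
#' `mu` for the postfledging model).  Covariates are mapped onto the
#' fit's standardized scale using its scaling record before the
#' utilities are formed.
#'
#' @param object a `"dcfit"` object.
#' @param newdata a [choice_data] table (or set-structured data.frame)
#'   on original covariate scales; defaults to the fitted data.
#' @param ... unused.
#' @return Matrix `n_sets x 3` of choice probabilities (rows sum to 1),
#'   rownames the set ids.
#' @export
predict.dcfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    d <- object$data  # already on the model scale
  } else {
    d <- as.data.frame(newdata)
    rec <- object$scaling
    if (!is.null(rec) && rec$scheme == "zscore")
      for (v in all_covariates())
        d[[v]] <- (d[[v]] - rec$means[[v]]) / rec$sds[[v]]
  }
  da <- design_all(d, object$spec)
  n <- length(da$used)
  cf <- coef(object)
  if (object$model == "nest") {
    V <- matrix(da$X %*% cf, ncol = 3L, byrow = TRUE)
  } else {
    stg <- da$data$stage[seq(1, 3 * n, by = 3L)]
    gidx <- unname(object$grouping[stg])
    B <- cf[gidx, , drop = FALSE]
    V <- matrix(rowSums(da$X * B[rep(seq_len(n), each = 3L), ,
                                 drop = FALSE]),
                ncol = 3L, byrow = TRUE)
  }
  m <- apply(V, 1L, max)
  E <- exp(V - m)
  p <- E / rowSums(E)
  rownames(p) <- as.character(da$set_id)
  colnames(p) <- paste0("alt", 1:3)
  p
}

#' Posterior-predictive simulation of choices
#'
#' For each simulation, a coefficient draw is taken from the posterior
#' (the set's own individual-level vector for the hierarchical model)
#' and a used location is redrawn for every fitted choice set.
#'
#' @param object a `"dcfit"` object.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Integer matrix `n_sets x nsim` of used positions in 1:3.
#' @export
simulate.dcfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  da <- design_all(object$data, object$spec)
  n <- length(da$used)
  m <- as.matrix(object$draws)
  reg <- object$draws$registry
  out <- matrix(NA_integer_, n, nsim,
                dimnames = list(as.character(da$set_id), NULL))
  P <- length(object$spec$labels)
  for (s in seq_len(nsim)) {
    j <- sample.int(nrow(m), 1L)
    if (object$model == "nest") {
      B <- matrix(m[j, reg$kind == "beta"], n, P, byrow = TRUE)
    } else {
      bu <- matrix(m[j, reg$kind == "beta_i"], ncol = P, byrow = TRUE)
      B <- bu[object$unit_of_set, , drop = FALSE]
    }
    V <- matrix(rowSums(da$X * B[rep(seq_len(n), each = 3L), ,
                                 drop = FALSE]),
                ncol = 3L, byrow = TRUE)
    mx <- apply(V, 1L, max)
    E <- exp(V - mx)
    p <- E / rowSums(E)
    out[, s] <- vapply(seq_len(n),
                       function(i) sample.int(3L, 1L, prob = p[i, ]), 0L)
  }
  out
}

#' Deviance residuals per choice set
#'
#' `sqrt(-2 log p_used)` evaluated at the posterior-mean coefficients:
#' 0 when the used location was certain under the model, large when the
#' model found the observed choice surprising.  Unsigned, since the
#' three alternatives are unordered.
#'
#' @param object a `"dcfit"` object.
#' @param ... unused.
#' @return Named numeric vector, one value per choice set.
#' @export
residuals.dcfit <- function(object, ...) {
  p <- predict(object)
  da <- design_all(object$data, object$spec)
  pu <- p[cbind(seq_len(nrow(p)), da$used)]
  setNames(sqrt(-2 * log(pu)), rownames(p))
}

#' Summarize a discrete-choice resource-selection fit
#'
#' Coefficient table (posterior mean, 95% CRI, directional confidence
#' `f`, and the selection ratio `exp(beta)` where eligible), fit
#' statistics (Estrella's R2 against the equal-probability null) and the
#' convergence report.
#'
#' @param object a `"dcfit"` object.
#' @param ... unused.
#' @return Object of class `"summary.dcfit"`.
#' @export
summary.dcfit <- function(object, ...) {
  structure(list(model = object$model,
                 table = coefficient_table(object),
                 stats = fit_stats(object),
                 convergence = object$convergence),
            class = "summary.dcfit")
}

#' @export
print.summary.dcfit <- function(x, digits = 3, ...) {
  cat("Coefficient summary (", x$model, " model):\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat("\nFit: n_sets =", x$stats$n_sets,
      " loglik_hat =", round(x$stats$loglik_hat, 2),
      " null =", round(x$stats$loglik_null, 2),
      " Estrella R2 =", round(x$stats$estrella_r2, 3), "\n")
  cat("Max Rhat =", round(max(x$convergence$rhat$rhat), 3),
      if (x$convergence$all_converged) "(converged)\n"
      else "(NOT converged)\n")
  invisible(x)
}

#' Caterpillar plot of population-level coefficients
#'
#' Posterior means and 95% CRIs of the nest coefficients or, for the
#' postfledging model, the stage-specific population means, drawn with
#' base graphics.
#'
#' @param x a `"dcfit"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dcfit <- function(x, ...) {
  sm <- summarize_coefficients(x$draws, which = "population")
  k <- nrow(sm)
  old <- par(mar = c(4, 11, 2, 1))
  on.exit(par(old))
  ylab <- if (x$model == "nest") sm$covariate
          else paste(sm$stage, sm$covariate, sep = ": ")
  plot(sm$mean, seq_len(k), xlim = range(sm$cri_lo, sm$cri_hi),
       yaxt = "n", xlab = "coefficient (posterior mean, 95% CRI)",
       ylab = "", pch = 16, ...)
  axis(2, at = seq_len(k), labels = ylab, las = 1, cex.axis = 0.7)
  segments(sm$cri_lo, seq_len(k), sm$cri_hi, seq_len(k))
  abline(v = 0, lty = 3)
  invisible(x)
}
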