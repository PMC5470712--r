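#' Choice probabilities within one choice set
#'
#' Multinomial-logit probabilities over the three alternatives of a
#' choice set: `p_j = exp(V_j) / sum_k exp(V_k)` with utilities
#' `V = D %*% beta`.  Computed with a max shift so that large utilities
#' never overflow.
#'
#' @param D 3 x P design matrix from [build_design()].
#' @param beta coefficient vector of length P.
#' @return Numeric vector of 3 probabilities summing to 1.
#' @examples
#' D <- diag(3)[, 1:2]
#' choice_probabilities(D, c(0, 0))  # uniform 1/3
#' @export
choice_probabilities <- function(D, beta) {
  V <- drop(as.matrix(D) %*% as.numeric(beta))
  if (any(!is.finite(V))) stop("non-finite utilities")
  e <- exp(V - max(V))
  unname(e / sum(e))
}

#' Log-likelihood of one choice set
#'
#' Log probability that the used alternative is chosen, computed through
#' the max-shifted log-sum-exp (raw utilities are never exponentiated).
#'
#' @inheritParams choice_probabilities
#' @param used_index position of the used location, 1, 2 or 3.
#' @return The log probability (a nonpositive number).
#' @examples
#' D <- matrix(0, 3, 2)
#' set_loglik(D, c(1, -1), 2)  # log(1/3)
#' @export
set_loglik <- function(D, beta, used_index) {
  stopifnot(length(used_index) == 1L, used_index %in% 1:3)
  V <- drop(as.matrix(D) %*% as.numeric(beta))
  if (any(!is.finite(V))) stop("non-finite utilities")
  m <- max(V)
  unname(V[used_index] - m - log(sum(exp(V - m))))
}

#' Log-likelihood of a choice-set dataset
#'
#' Sum of [set_loglik()] over the independent choice sets of a dataset.
#' Coefficients may be shared (a single vector) or assigned per set (a
#' matrix with one row per set, rownames giving `set_id`), which is how
#' the hierarchical model's individual-level coefficients enter.
#'
#' @param d a [choice_data] table (one row per location).
#' @param beta numeric vector of length P (shared coefficients), or a
#'   numeric matrix (`n_sets` x P) whose rownames are the set ids.
#' @param spec a [model_spec()].
#' @return Total log-likelihood (0 for an empty dataset).
#' @export
data_loglik <- function(d, beta, spec = model_spec()) {
  if (nrow(d) == 0L) return(0)
  da <- design_all(d, spec)
  n <- length(da$used)
  P <- length(spec$labels)
  if (is.matrix(beta)) {
    if (is.null(rownames(beta)))
      stop("per-set coefficient matrix needs set ids as rownames")
    idx <- match(as.character(da$set_id), rownames(beta))
    if (anyNA(idx))
      stop("no coefficient vector assigned to set(s): ",
           paste(head(da$set_id[is.na(idx)]), collapse = ", "))
    B <- beta[idx, , drop = FALSE]
    V <- matrix(rowSums(da$X * B[rep(seq_len(n), each = 3L), , drop = FALSE]),
                ncol = 3L, byrow = TRUE)
  } else {
    stopifnot(length(beta) == P)
    V <- matrix(da$X %*% as.numeric(beta), ncol = 3L, byrow = TRUE)
  }
  if (any(!is.finite(V))) stop("non-finite utilities")
  m <- apply(V, 1L, max)
  Vu <- V[cbind(seq_len(n), da$used)]
  sum(Vu - m - log(rowSums(exp(V - m))))
}
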