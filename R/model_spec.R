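#' Vegetation covariate names
#'
#' The six local vegetation covariates measured at every location, in the
#' canonical column order used throughout the package: litter depth (cm),
#' understory foliage density (proportion of a density board covered,
#' 0-1), sapling density (stems/ha, 3.0-12.5 cm DBH), pole timber density
#' (stems/ha, 12.5-27.5 cm DBH), saw timber density (stems/ha, > 27.5 cm
#' DBH) and canopy cover (percent, 0-100).
#'
#' @return Character vector of the six covariate column names.
#' @export
veg_covariates <- function() {
  c("litter_depth", "understory_density", "sapling_density",
    "pole_density", "saw_density", "canopy_cover")
}

#' All covariate columns (vegetation plus edge distance)
#' @return Character vector of the seven covariate column names.
#' @export
all_covariates <- function() c(veg_covariates(), "edge_distance")

#' Model specification for the choice-set utility
#'
#' Defines which columns enter the linear utility of a location.  The
#' default specification is the full model: the six vegetation main
#' effects, a distance-to-edge main effect, and each vegetation covariate
#' interacted with edge distance, giving P = 13 coefficients.  There is
#' no intercept: alternative-invariant terms cancel in the conditional
#' logit, and alternatives within a set are unlabelled and exchangeable.
#'
#' @param main_covariates character vector of vegetation main-effect
#'   columns (a subset of [veg_covariates()], order preserved).
#' @param edge_term logical; include the `edge_distance` main effect.
#' @param interactions logical; include `main x edge_distance`
#'   interaction columns, one per vegetation main effect.
#' @return An object of class `"model_spec"`: a list with elements
#'   `mains`, `edge_term`, `interactions` and `labels` (the fixed column
#'   ordering of the design matrix).
#' @examples
#' spec <- model_spec()
#' length(spec$labels)  # 13
#' @export
model_spec <- function(main_covariates = veg_covariates(),
                       edge_term = TRUE, interactions = TRUE) {
  stopifnot(length(main_covariates) >= 1)
  bad <- setdiff(main_covariates, veg_covariates())
  if (length(bad) > 0)
    stop("unknown vegetation covariate(s): ", paste(bad, collapse = ", "))
  if (interactions && !all(main_covariates %in% veg_covariates()))
    stop("interactions require vegetation main effects")
  labels <- main_covariates
  if (edge_term) labels <- c(labels, "edge_distance")
  if (interactions)
    labels <- c(labels, paste0(main_covariates, ":edge_distance"))
  structure(list(mains = main_covariates, edge_term = edge_term,
                 interactions = interactions, labels = labels),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Choice-set utility specification (", length(x$labels),
      " coefficients, no intercept)\n", sep = "")
  cat("  mains:       ", paste(x$mains, collapse = ", "), "\n")
  cat("  edge term:   ", x$edge_term, "\n")
  cat("  interactions:", x$interactions, "\n")
  invisible(x)
}

#' Build the design matrix for one choice set
#'
#' Expands the three locations of a choice set into a 3 x P matrix whose
#' row j is the covariate expansion of location j under `spec`.  Each
#' interaction column equals the corresponding vegetation column
#' multiplied elementwise by the edge-distance column, on whatever scale
#' (raw or standardized) the data currently carry -- interactions are
#' never re-centered separately.
#'
#' @param cs a 3-row data.frame holding one choice set (e.g. one group of
#'   a [choice_data] table), or any data.frame with the covariate columns.
#' @param spec a [model_spec()].
#' @return Numeric matrix with one row per location and columns labelled
#'   as `spec$labels`.
#' @examples
#' d <- generate_dataset(sim_config(preset = "recovery", seed = 1))$data
#' D <- build_design(d[1:3, ], model_spec())
#' dim(D)  # 3 x 13
#' @export
build_design <- function(cs, spec = model_spec()) {
  need <- unique(c(spec$mains,
                   if (spec$edge_term || spec$interactions) "edge_distance"))
  miss <- setdiff(need, names(cs))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  M <- as.matrix(cs[, spec$mains, drop = FALSE])
  if (!is.numeric(M)) stop("covariate columns must be numeric")
  out <- M
  if (spec$edge_term || spec$interactions)
    e <- as.numeric(cs[["edge_distance"]])
  if (spec$edge_term) out <- cbind(out, edge_distance = e)
  if (spec$interactions) out <- cbind(out, M * e)
  colnames(out) <- spec$labels
  if (any(!is.finite(out))) stop("non-finite covariate values in design")
  out
}

# Design matrix for a whole dataset: (3n x P) with rows in set order.
# Returns list(X, used (1-based position within set), set_id).
design_all <- function(d, spec = model_spec()) {
  d <- as.data.frame(d)
  ord <- order(match(d$set_id, unique(d$set_id)))
  d <- d[ord, , drop = FALSE]
  n <- nrow(d) / 3L
  if (n != floor(n)) stop("dataset rows are not a multiple of 3")
  X <- build_design(d, spec)
  role <- matrix(d$role == "used", ncol = 3L, byrow = TRUE)
  if (!all(rowSums(role) == 1L))
    stop("each choice set must have exactly one used location")
  used <- max.col(role, ties.method = "first")
  list(X = X, used = used, set_id = unique(d$set_id), data = d)
}
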