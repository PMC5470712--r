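#' Construct and validate a choice-set table
#'
#' A `choice_data` object is a data.frame with one row per sampled
#' location and three consecutive rows per choice set (one used plus two
#' available locations sampled at the same time for the same bird).
#' Required columns: `set_id`, `species`, `individual_id`, `brood_id`,
#' `stage` (`nest`, `early_dependent`, `late_dependent` or
#' `independent`), `day_postfledge` (NA for nest sets), `role`
#' (`used`/`available`) and the seven covariates of [all_covariates()].
#'
#' Validation enforces the field-protocol invariants: every set has
#' exactly 3 rows and exactly one used row; densities, litter depth and
#' edge distance are nonnegative; canopy cover lies in 0-100; juvenile
#' sets are never labelled `nest`; nest sets carry no `day_postfledge`.
#'
#' @param df data.frame with the columns above.
#' @param species species label for the whole table (defaults to the
#'   unique value of the `species` column).
#' @param stage_grouping named integer vector mapping each juvenile stage
#'   present to a model-stage index (see [stage_grouping()]); used by the
#'   hierarchical fit, where ovenbird-style pooling maps
#'   `late_dependent` and `independent` to the same index.
#' @return The validated table, classed `"choice_data"`, rows ordered by
#'   set, with attributes `species` and `stage_grouping`.
#' @export
choice_data <- function(df, species = NULL, stage_grouping = NULL) {
  req <- c("set_id", "species", "individual_id", "brood_id", "stage",
           "day_postfledge", "role", all_covariates())
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  if (is.null(species)) {
    species <- unique(df$species)
    if (length(species) != 1L)
      stop("table mixes species; pass one species at a time")
  }
  if (!all(df$species == species)) stop("all rows must share `species`")
  ord <- order(match(df$set_id, unique(df$set_id)))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  tab <- table(df$set_id)
  if (any(tab != 3L))
    stop("set(s) without exactly 3 rows: ",
         paste(head(names(tab)[tab != 3L]), collapse = ", "))
  if (!all(df$role %in% c("used", "available")))
    stop("`role` must be 'used' or 'available'")
  u <- tapply(df$role == "used", df$set_id, sum)
  if (any(u != 1L))
    stop("set(s) without exactly one used location: ",
         paste(head(names(u)[u != 1L]), collapse = ", "))
  ok_stage <- c("nest", "early_dependent", "late_dependent", "independent")
  if (!all(df$stage %in% ok_stage))
    stop("unknown stage label(s): ",
         paste(unique(setdiff(df$stage, ok_stage)), collapse = ", "))
  st <- tapply(df$stage, df$set_id, function(s) length(unique(s)))
  if (any(st != 1L)) stop("stage must be constant within a set")
  if (any(df$stage == "nest" & !is.na(df$day_postfledge)))
    stop("nest sets must not carry day_postfledge")

  cv <- as.matrix(df[, all_covariates()])
  if (any(!is.finite(cv))) stop("non-finite covariate values")
  nonneg <- c("litter_depth", "sapling_density", "pole_density",
              "saw_density", "edge_distance")
  if (any(cv[, nonneg] < 0)) stop("negative values in nonnegative covariates")
  if (any(df$canopy_cover < 0 | df$canopy_cover > 100))
    stop("canopy_cover outside [0, 100]")

  if (is.null(stage_grouping)) {
    juv <- setdiff(unique(df$stage), "nest")
    stage_grouping <- stage_grouping()[juv]
  } else {
    juv <- setdiff(unique(df$stage), "nest")
    if (!all(juv %in% names(stage_grouping)))
      stop("stage_grouping must cover every juvenile stage present")
  }
  structure(df, species = species, stage_grouping = stage_grouping,
            class = c("choice_data", "data.frame"))
}

#' Stage-to-model-stage mapping
#'
#' @param pool_late_independent logical; if TRUE, `late_dependent` and
#'   `independent` share one model stage (the pooling used when the
#'   independent period alone cannot support separate population-level
#'   coefficients).
#' @return Named integer vector over the three juvenile stages.
#' @examples
#' stage_grouping()                         # 3 model stages
#' stage_grouping(pool_late_independent = TRUE)  # 2 model stages
#' @export
stage_grouping <- function(pool_late_independent = FALSE) {
  if (pool_late_independent)
    c(early_dependent = 1L, late_dependent = 2L, independent = 2L)
  else
    c(early_dependent = 1L, late_dependent = 2L, independent = 3L)
}

#' @export
print.choice_data <- function(x, ...) {
  n <- nrow(x) / 3L
  cat("Choice-set data:", n, "sets,",
      length(unique(x$individual_id)), "individuals, species =",
      attr(x, "species"), "\n")
  st <- table(x$stage[x$role == "used"])
  cat("  sets per stage:",
      paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a choice-set table from delimited text
#'
#' Ingests a CSV (RFC-4180, header row, UTF-8) with one row per location
#' and groups rows into choice sets.  The used location is identified
#' from the role column, never from row position.  Sets with other than
#' 3 rows are excluded (their count is recorded in the `"excluded"`
#' attribute and reported via `message()`); a set with duplicate used
#' rows is a validation error.  Spreadsheet-deposited tables (e.g. an
#' XLSX supplement) should be exported to CSV first; the reader consumes
#' delimited text only so its contract is testable byte-for-byte.
#'
#' @param path path to the CSV file.
#' @param schema named character vector mapping canonical column names
#'   (see [choice_data()]) to the file's column names; canonical names
#'   absent from the schema are looked up verbatim.
#' @param understory_unit `"proportion"` (0-1, the density-board scale)
#'   or `"percent"`; percent values are divided by 100 on read.
#' @param species,stage_grouping passed to [choice_data()].
#' @return A validated [choice_data] object with attribute `excluded`
#'   (number of incomplete sets dropped).
#' @export
read_choice_table <- function(path, schema = NULL,
                              understory_unit = c("proportion", "percent"),
                              species = NULL, stage_grouping = NULL) {
  understory_unit <- match.arg(understory_unit)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("set_id", "species", "individual_id", "brood_id", "stage",
           "day_postfledge", "role", all_covariates())
  for (canon in req) {
    src <- if (!is.null(schema) && canon %in% names(schema))
      schema[[canon]] else canon
    if (!src %in% names(raw))
      stop("schema error: required column '", canon,
           "' (file column '", src, "') not found")
    names(raw)[names(raw) == src] <- canon
  }
  raw <- raw[, req]
  if (understory_unit == "percent")
    raw$understory_density <- raw$understory_density / 100
  tab <- table(raw$set_id)
  bad <- names(tab)[tab != 3L]
  if (length(bad) > 0) {
    message("excluding ", length(bad), " incomplete choice set(s)")
    raw <- raw[!(raw$set_id %in% bad), , drop = FALSE]
  }
  u <- tapply(raw$role == "used", raw$set_id, sum)
  if (any(u > 1L))
    stop("duplicate used rows in set(s): ",
         paste(head(names(u)[u > 1L]), collapse = ", "))
  d <- choice_data(raw, species = species, stage_grouping = stage_grouping)
  attr(d, "excluded") <- length(bad)
  d
}

#' Write a choice-set table to canonical CSV
#'
#' One row per location with `set_id`/`role` columns, readable back by
#' [read_choice_table()] losslessly.
#'
#' @param d a [choice_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(d, path) {
  write.csv(as.data.frame(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign a postfledging developmental stage
#'
#' Juvenile choice sets are categorized by developmental milestones:
#' `early_dependent` during the first week out of the nest (day <= 7,
#' fed by parents), `late_dependent` from day 8 while still receiving
#' parental care, and `independent` once parental care has ceased
#' (behaviourally determined, so passed as a flag).  Day 8 falls in the
#' late-dependent stage, keeping the partition contiguous.
#'
#' @param day_postfledge integer day(s) since fledging, >= 0.
#' @param independent logical flag(s); TRUE forces `independent`
#'   regardless of day.
#' @return Character vector of stage labels.
#' @examples
#' assign_stage(3, FALSE)   # early_dependent
#' assign_stage(15, FALSE)  # late_dependent
#' assign_stage(25, TRUE)   # independent
#' @export
assign_stage <- function(day_postfledge, independent = FALSE) {
  n <- max(length(day_postfledge), length(independent))
  day <- rep_len(as.numeric(day_postfledge), n)
  ind <- rep_len(as.logical(independent), n)
  if (any(is.na(day)) || any(day < 0))
    stop("day_postfledge must be a nonnegative number")
  out <- ifelse(ind, "independent",
                ifelse(day <= 7, "early_dependent", "late_dependent"))
  out
}

#' Keep one tracked individual per brood
#'
#' Where more than one sibling of a brood was radio-tracked, all choice
#' sets of a single individual (chosen by a seeded uniform draw) are
#' retained and the siblings' sets dropped, reducing variation due to
#' brood effects and correlations among siblings.  Deterministic given
#' `seed`; broods with one tracked individual pass through unchanged.
#' Nest sets are never touched.
#'
#' @param d a [choice_data] object.
#' @param seed integer seed for the per-brood draw.
#' @return Filtered [choice_data]; attribute `broods_collapsed` counts
#'   the broods that lost individuals.
#' @export
filter_one_per_brood <- function(d, seed) {
  stopifnot(inherits(d, "choice_data"))
  juv <- d$stage != "nest"
  key <- unique(data.frame(brood_id = d$brood_id[juv],
                           individual_id = d$individual_id[juv]))
  keep <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    unlist(lapply(split(key$individual_id, key$brood_id), function(ids) {
      ids <- sort(as.character(ids))
      ids[[sample.int(length(ids), 1L)]]
    }))
  })
  collapsed <- sum(table(key$brood_id) > 1L)
  drop <- juv & !(d$individual_id %in% keep)
  out <- choice_data(as.data.frame(d)[!drop, , drop = FALSE],
                     species = attr(d, "species"),
                     stage_grouping = attr(d, "stage_grouping"))
  attr(out, "broods_collapsed") <- collapsed
  out
}

#' Standardize covariates
#'
#' Centers and scales each covariate by its pooled mean and SD over all
#' locations of the dataset (used and available alike), so that fitted
#' coefficients are per-SD effects.  The scaling record is attached so
#' that probability-of-use curves and selection ratios can be mapped
#' back to original field scales.
#'
#' @param d a [choice_data] object.
#' @param scheme `"zscore"` or `"none"` (identity record).
#' @return The transformed [choice_data] with attribute `scaling`, a list
#'   with `scheme`, `means` and `sds` (retrievable via
#'   [scaling_record()], invertible via [unstandardize_covariates()]).
#' @export
standardize_covariates <- function(d, scheme = c("zscore", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(d, "choice_data"), nrow(d) > 0)
  cv <- all_covariates()
  if (scheme == "none") {
    rec <- list(scheme = "none",
                means = setNames(rep(0, length(cv)), cv),
                sds = setNames(rep(1, length(cv)), cv))
    attr(d, "scaling") <- rec
    return(d)
  }
  means <- vapply(cv, function(v) mean(d[[v]]), 0)
  sds <- vapply(cv, function(v) sd(d[[v]]), 0)
  zero <- cv[sds == 0 | !is.finite(sds)]
  if (length(zero) > 0)
    stop("zero-variance covariate(s): ", paste(zero, collapse = ", "))
  for (v in cv) d[[v]] <- (d[[v]] - means[[v]]) / sds[[v]]
  attr(d, "scaling") <- list(scheme = "zscore", means = means, sds = sds)
  d
}

#' @rdname standardize_covariates
#' @export
scaling_record <- function(d) attr(d, "scaling")

#' @rdname standardize_covariates
#' @export
unstandardize_covariates <- function(d) {
  rec <- attr(d, "scaling")
  if (is.null(rec) || rec$scheme == "none") {
    attr(d, "scaling") <- NULL
    return(d)
  }
  for (v in all_covariates())
    d[[v]] <- d[[v]] * rec$sds[[v]] + rec$means[[v]]
  attr(d, "scaling") <- NULL
  d
}
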