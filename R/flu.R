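#' Expression difference scores
#'
#' Subtracts baseline expression from the post-vaccination measurement for
#' matched subjects and probesets, then centres and scales each probeset's
#' difference scores to sum of squares one.  Probesets with constant
#' difference scores cannot be scaled; they either raise an error (the
#' default, naming the offending columns) or are dropped when
#' `drop_constant = TRUE`.
#'
#' @param baseline,day3 numeric matrices (subjects x probesets) with matching
#'   dimensions.
#' @param drop_constant drop probesets whose difference scores are constant
#'   instead of erroring.
#' @return a `scaled_block` of scaled difference scores (with an attribute
#'   `"dropped"` listing removed probeset columns when `drop_constant`).
#' @export
expression_difference_scores <- function(baseline, day3, drop_constant = FALSE) {
  baseline <- as.matrix(baseline); day3 <- as.matrix(day3)
  if (!all(dim(baseline) == dim(day3)))
    stop("baseline and day3 must have identical dimensions (matched subjects and probesets)")
  d <- day3 - baseline
  if (drop_constant) {
    centered <- sweep(d, 2L, colMeans(d), `-`)
    keep <- colSums(centered^2) > 0
    dropped <- which(!keep)
    d <- d[, keep, drop = FALSE]
    out <- center_scale(d)
    attr(out, "dropped") <- dropped
    return(out)
  }
  center_scale(d)
}

#' Vaccine-efficacy outcome from antibody titers
#'
#' For each subject, computes the log fold change of each hemagglutination-
#' inhibition (HAI) assay between day 28 and baseline, takes the maximum over
#' the assays (damping the influence of subjects with high pre-existing
#' titers), and centres the result across subjects.  Titers must be positive
#' for the log transform; natural logarithms are used.
#'
#' @param titers data frame with columns `subject`, `assay`, `baseline`,
#'   `day28` (one row per subject x assay).
#' @return named numeric vector of centred maximal log fold changes, one per
#'   subject (ordered by first appearance).
#' @export
hai_outcome <- function(titers) {
  req <- c("subject", "assay", "baseline", "day28")
  if (!all(req %in% names(titers)))
    stop("titers must have columns subject, assay, baseline, day28")
  if (any(titers$baseline <= 0 | titers$day28 <= 0))
    stop("non-positive titer values; log fold change undefined")
  titers$lfc <- log(titers$day28) - log(titers$baseline)
  subjects <- unique(titers$subject)
  mx <- vapply(subjects, function(s) {
    max(titers$lfc[titers$subject == s])
  }, numeric(1))
  out <- mx - mean(mx)
  names(out) <- as.character(subjects)
  out
}

#' Run a vaccine-study analysis recipe
#'
#' Executes the full pipeline on delimited text inputs: expression difference
#' scores from baseline and day-3 matrices, the maximal-HAI outcome from a
#' titer table, then stability-selected sparse principal covariates
#' regression.  All parameters come from a flat key-value config (see
#' [read_config()] and the template in
#' `system.file("extdata", "flu_recipe.cfg", package = "spcovr")`).
#'
#' @param config path to a config file, or a named list of settings.
#' @param output_dir directory for result files; overrides the config entry.
#' @return list with the predictor block, outcome, `stability_result` and
#'   output paths.
#' @export
run_flu_recipe <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  get <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) cfg[[key]] else default
  }
  baseline <- read_matrix(get("baseline_expression"))
  day3 <- read_matrix(get("day3_expression"))
  titers <- utils::read.csv(get("titers"))
  x <- expression_difference_scores(baseline$values, day3$values,
                                    drop_constant = isTRUE(get("drop_constant", TRUE)))
  y_vec <- hai_outcome(titers)
  if (length(y_vec) != x$n_obs)
    stop("number of subjects in titer table does not match expression data")
  # the outcome enters centred but unscaled
  y <- new_scaled_block(matrix(y_vec, ncol = 1L), scaling = "none")
  settings <- penalty_settings(
    alpha = get("alpha", 0.99),
    n_components = get("n_components", 2L),
    loading_constraint = get("loading_constraint", "unit_length")
  )
  stab <- stability_settings(
    n_resamples = get("n_resamples", 500L),
    resample_fraction = get("resample_fraction", 0.5),
    pi_threshold = get("pi_threshold", 0.90),
    expected_false = get("expected_false", 1),
    q_override = get("q_override"),
    grid_size = get("grid_size", 50L),
    seed = get("seed", 1L)
  )
  options <- fit_options(
    max_iter = get("max_iter", 500L), tol = get("tol", 1e-6),
    n_random_starts = get("n_random_starts", 1L), seed = get("seed", 1L)
  )
  result <- run_stability_selection(x, y, settings, stab, options,
                                    lambda2_frac = get("lambda2_frac", 0.05))
  out_dir <- if (!is.null(output_dir)) output_dir else get("output_dir", ".")
  paths <- write_stability_result(result, out_dir)
  manifest <- c(cfg[setdiff(names(cfg), "output_dir")],
                list(output_dir = out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(x = x, y = y, result = result,
       paths = c(paths, file.path(out_dir, "manifest.json")))
}
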