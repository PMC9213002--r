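#' Run configuration
#'
#' Tunable parameters of the alignment pipeline with the defaults used for
#' all reported results: a 13-minute temporal window for the ensemble model,
#' modification acceptance at a violation reduction of at least 3, 200
#' error-correction iterations after each modification and 1400 after the
#' final one, a 75% supermajority for confident votes, and one reiteration
#' round.
#'
#' @param ... named overrides of the defaults listed under Details.
#' @details Recognized fields:
#' \describe{
#'   \item{window_minutes}{temporal window of the ensemble model (min), 13.}
#'   \item{accept_threshold}{minimum drop in adjacency violations for a
#'     modification to be kept, 3.  \code{Inf} disables co-optimization.}
#'   \item{correction_iters_inner}{error-correction iterations after each
#'     candidate modification, 200.}
#'   \item{correction_iters_final}{additional iterations once a labeled
#'     dataset is fully co-optimized, 1400.}
#'   \item{supermajority}{vote fraction for a confident identity, 0.75.}
#'   \item{reiteration_rounds}{rounds of confident-match TPS re-alignment, 1.}
#'   \item{prealign_mode}{\code{"affine"} or \code{"tps"} landmark pre-fit.}
#'   \item{tps_lambda}{TPS regularization used when the pipeline fits a TPS
#'     from correspondences (pre-alignment in tps mode and the reiteration
#'     fit), 0.1: smooths at the scale of the positional noise expected in
#'     the control points rather than interpolating it.}
#'   \item{cpd_beta, cpd_lambda, cpd_outlier_weight, cpd_max_iters,
#'     cpd_tol}{coherent point drift parameters, 3 / 10 / 0.1 / 100 / 1e-6:
#'     a stiff field that absorbs body-scale deformation without fitting
#'     per-nucleus noise.}
#'   \item{squared_distance}{use squared instead of raw Euclidean LAP costs,
#'     FALSE (sensitivity switch).}
#'   \item{rng_seed}{seed consumed by every stochastic step, 1.}
#' }
#' @return A named list of class \code{run_config}.
#' @examples
#' cfg <- run_config(accept_threshold = 5)
#' cfg$accept_threshold
#' @export
run_config <- function(...) {
  cfg <- list(
    window_minutes = 13,
    accept_threshold = 3L,
    correction_iters_inner = 200L,
    correction_iters_final = 1400L,
    supermajority = 0.75,
    reiteration_rounds = 1L,
    prealign_mode = "affine",
    tps_lambda = 0.1,
    cpd_beta = 3.0,
    cpd_lambda = 10.0,
    cpd_outlier_weight = 0.1,
    cpd_max_iters = 100L,
    cpd_tol = 1e-6,
    squared_distance = FALSE,
    rng_seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  if (!(cfg$supermajority > 0.5 && cfg$supermajority <= 1))
    stop("supermajority must lie in (0.5, 1], got ", cfg$supermajority)
  if (is.finite(cfg$accept_threshold) && cfg$accept_threshold < 1)
    stop("accept_threshold must be >= 1")
  for (f in c("correction_iters_inner", "correction_iters_final",
              "reiteration_rounds", "cpd_max_iters"))
    if (cfg[[f]] < 0) stop(f, " must be >= 0, got ", cfg[[f]])
  if (cfg$window_minutes <= 0) stop("window_minutes must be positive")
  cfg$prealign_mode <- match.arg(cfg$prealign_mode, c("affine", "tps"))
  cfg
}

#' @rdname run_config
#' @param path YAML file of overrides; an empty file yields all defaults.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}
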