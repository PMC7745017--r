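#' Configuration of the synthetic scene-viewing corpus
#'
#' Bundles every generating parameter of the synthetic-data module. The
#' defaults emulate the study conditions of a two-group scene-viewing corpus:
#' 42 young and 34 older adults, 150 scenes of 800 x 600 px parcellated by an
#' 8 x 6 grid, about 6.9 annotated objects per scene, 10 missing trials,
#' about 21 fixations per 6-s trial with lognormal durations around 250 ms,
#' a logit-linear fixation-probability structure with subject/scene/object
#' random intercepts, and within-object landing positions drawn from a 2D
#' Gaussian with a slight undershoot of the object centre. Generating fixed
#' effects default to the object-analysis coefficients of the emulated study
#' (intercept -0.2278, age difference -0.208, central bias -0.1795, size
#' 1.028, salience 0.3823, with the corresponding age interactions).
#'
#' @param n_subjects_young,n_subjects_old subjects per age group.
#' @param n_scenes number of scene images.
#' @param image_width_px,image_height_px image dimensions in pixels; must be
#'   divisible by `grid_cols` / `grid_rows`.
#' @param grid_cols,grid_rows grid parcellation used by grid-based analyses.
#' @param objects_per_scene_mean mean of the (truncated, >= 2) Poisson object
#'   count per scene.
#' @param n_missing_trials number of (subject, scene) trials absent from the
#'   fixation report.
#' @param fixations_per_trial_mean mean number of fixations per trial,
#'   including the initial central fixation.
#' @param fixation_duration_log_mean,fixation_duration_log_sd parameters of
#'   the lognormal fixation-duration distribution (natural log of ms).
#' @param beta named numeric vector of generating coefficients on the logit
#'   scale for the young (reference) group; names among `"(Intercept)"`,
#'   `"central_bias"`, `"size"`, `"salience"` (predictors are z-standardized
#'   before entering the logit).
#' @param beta_age_delta named numeric vector of old-minus-young differences
#'   (an `"(Intercept)"` entry is the age main effect).
#' @param re_sd named numeric vector of random-intercept standard deviations
#'   for `"subject"`, `"scene"` and (object-level analyses) `"object"`.
#' @param pvl_mean_offset length-2 numeric, mean normalized landing offset
#'   (x, y) in launch-relative units; negative values are undershoots of the
#'   object centre. Components must lie in (-0.5, 0.5).
#' @param pvl_sd length-2 numeric, SDs of the normalized landing offsets.
#' @param p_object_target probability that a simulated saccade targets an
#'   annotated object (otherwise a background location).
#' @param p_refixation probability of an immediate within-object refixation.
#' @param n_memory_trials number of memory-test trials per subject (half of
#'   them signal trials).
#' @param memory_hit_rate,memory_fa_rate named numeric vectors (`young`,
#'   `old`) of generating hit and false-alarm probabilities. Defaults invert
#'   the emulated study's printed d' and criterion summaries.
#' @param seed integer seed; all generator substreams are derived from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects_young = 42L,
                       n_subjects_old = 34L,
                       n_scenes = 150L,
                       image_width_px = 800L,
                       image_height_px = 600L,
                       grid_cols = 8L,
                       grid_rows = 6L,
                       objects_per_scene_mean = 6.9,
                       n_missing_trials = 10L,
                       fixations_per_trial_mean = 21,
                       fixation_duration_log_mean = 5.45,
                       fixation_duration_log_sd = 0.35,
                       beta = c("(Intercept)" = -0.2278,
                                central_bias = -0.1795,
                                size = 1.028,
                                salience = 0.3823),
                       beta_age_delta = c("(Intercept)" = -0.208,
                                          central_bias = 0.033,
                                          size = 0.1567,
                                          salience = 0.0523),
                       re_sd = c(subject = 0.367, scene = 0.304,
                                 object = 1.018),
                       pvl_mean_offset = c(-0.0509, -0.0294),
                       pvl_sd = c(0.15, 0.15),
                       p_object_target = 0.6,
                       p_refixation = 0.3,
                       n_memory_trials = 30L,
                       memory_hit_rate = c(young = 0.6255, old = 0.4980),
                       memory_fa_rate = c(young = 0.1112, old = 0.0909),
                       seed = 1L) {
  cfg <- list(
    n_subjects_young = as.integer(n_subjects_young),
    n_subjects_old = as.integer(n_subjects_old),
    n_scenes = as.integer(n_scenes),
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    grid_cols = as.integer(grid_cols),
    grid_rows = as.integer(grid_rows),
    objects_per_scene_mean = objects_per_scene_mean,
    n_missing_trials = as.integer(n_missing_trials),
    fixations_per_trial_mean = fixations_per_trial_mean,
    fixation_duration_log_mean = fixation_duration_log_mean,
    fixation_duration_log_sd = fixation_duration_log_sd,
    beta = beta,
    beta_age_delta = beta_age_delta,
    re_sd = re_sd,
    pvl_mean_offset = pvl_mean_offset,
    pvl_sd = pvl_sd,
    p_object_target = p_object_target,
    p_refixation = p_refixation,
    n_memory_trials = as.integer(n_memory_trials),
    memory_hit_rate = memory_hit_rate,
    memory_fa_rate = memory_fa_rate,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_subjects_young", "n_subjects_old", "n_scenes",
              "image_width_px", "image_height_px", "grid_cols", "grid_rows")
  for (f in counts)
    if (cfg[[f]] <= 0L) stop("count field must be strictly positive: ", f)
  if (cfg$image_width_px %% cfg$grid_cols != 0L ||
      cfg$image_height_px %% cfg$grid_rows != 0L)
    stop("image dimensions must be divisible by the grid dimensions")
  if (cfg$n_missing_trials < 0L) stop("n_missing_trials must be >= 0")
  n_trials <- (cfg$n_subjects_young + cfg$n_subjects_old) * cfg$n_scenes
  if (cfg$n_missing_trials >= n_trials)
    stop("n_missing_trials must be smaller than the number of trials")
  if (any(cfg$re_sd < 0)) stop("re_sd values must be >= 0")
  if (any(abs(cfg$pvl_mean_offset) >= 0.5))
    stop("pvl_mean_offset components must lie in (-0.5, 0.5)")
  if (any(cfg$pvl_sd < 0)) stop("pvl_sd must be >= 0")
  if (cfg$objects_per_scene_mean <= 0)
    stop("objects_per_scene_mean must be strictly positive")
  if (cfg$fixations_per_trial_mean < 1)
    stop("fixations_per_trial_mean must be >= 1")
  if (cfg$fixation_duration_log_sd < 0)
    stop("fixation_duration_log_sd must be >= 0")
  rate_ok <- function(r) all(r >= 0 & r <= 1)
  if (!rate_ok(cfg$memory_hit_rate) || !rate_ok(cfg$memory_fa_rate))
    stop("memory hit/false-alarm rates must lie in [0, 1]")
  if (!all(c("young", "old") %in% names(cfg$memory_hit_rate)) ||
      !all(c("young", "old") %in% names(cfg$memory_fa_rate)))
    stop("memory rates must be named vectors with entries 'young' and 'old'")
  if (cfg$p_object_target < 0 || cfg$p_object_target > 1 ||
      cfg$p_refixation < 0 || cfg$p_refixation > 1)
    stop("target/refixation probabilities must lie in [0, 1]")
  invisible(cfg)
}

#' Desk-scale configuration preset
#'
#' The study-scale defaults of [sim_config()] are expensive for iterative
#' model fitting; this preset keeps the generating parameters but shrinks the
#' corpus to 20 + 20 subjects and 60 scenes (with proportionally fewer
#' missing trials), the scale used by the model-fitting workflows.
#'
#' @param ... overrides passed on to [sim_config()].
#' @export
desk_config <- function(...) {
  args <- list(n_subjects_young = 20L, n_subjects_old = 20L, n_scenes = 60L,
               n_missing_trials = 2L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d young + %d old subjects, %d scenes (%d x %d px, %d x %d grid)\n",
    x$n_subjects_young, x$n_subjects_old, x$n_scenes,
    x$image_width_px, x$image_height_px, x$grid_cols, x$grid_rows))
  cat(sprintf("  ~%.1f objects/scene, ~%.0f fixations/trial, %d missing trials, seed %d\n",
              x$objects_per_scene_mean, x$fixations_per_trial_mean,
              x$n_missing_trials, x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # preserve names of named vectors through YAML round-trip
  for (f in c("beta", "beta_age_delta", "re_sd",
              "memory_hit_rate", "memory_fa_rate"))
    x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("beta", "beta_age_delta", "re_sd",
              "memory_hit_rate", "memory_fa_rate"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  do.call(sim_config, x)
}

# Derived substream seed so partial regeneration is stable: each (kind, id)
# pair gets its own reproducible stream below 2^31.
substream_seed <- function(seed, kind, id = 0L) {
  h <- sum(utf8ToInt(kind) * seq_along(utf8ToInt(kind)))
  as.integer((as.numeric(seed) * 48271 + h * 69621 + as.numeric(id) * 16807) %%
               2147483647)
}
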