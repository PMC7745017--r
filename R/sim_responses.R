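#' Simulate binary fixation indicators from the generating logit model
#'
#' The indicator-level generator mirrors the fitted model exactly: for every
#' subject x scene x region the fixation indicator is a Bernoulli draw with
#' logit equal to the generating fixed effects (intercept, age difference,
#' z-standardized region predictors, and their age interactions) plus
#' random intercepts for subject, scene and -- when the regions are objects
#' and `re_sd` carries an `object` entry -- object, drawn once per unit from
#' centred normals. It exists for estimator validation: data simulated this
#' way follow the fitted model's assumptions exactly, unlike the
#' scanpath-level generator.
#'
#' @param config a [sim_config()]; `beta` names (other than the intercept)
#'   must match predictor columns of the region sets.
#' @param region_sets named list (by scene) of `region_set`s with raw
#'   predictors filled in.
#' @param subjects optional subject table; defaults to the configured group
#'   sizes.
#' @return Data frame with `subject`, `age_group`, `scene`, `region_id`,
#'   `fixated` and the z-standardized predictors used for generation.
#'   Deterministic given the config seed.
#' @export
simulate_fixation_indicators <- function(config, region_sets, subjects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(subjects)) subjects <- subject_table(config)
  regions <- do.call(rbind, lapply(region_sets, as.data.frame))
  preds <- setdiff(names(config$beta), "(Intercept)")
  raw_cols <- paste0("raw_", preds)
  miss <- setdiff(raw_cols, names(regions))
  if (length(miss))
    stop("beta names a predictor absent from the regions: ",
         paste(sub("^raw_", "", miss), collapse = ", "))
  regions <- standardize(regions, raw_cols)

  is_object <- attr(region_sets[[1]], "kind") == "object" &&
    "object" %in% names(config$re_sd)
  set.seed(substream_seed(config$seed, "indicators"))
  u_subj <- rnorm(nrow(subjects), 0, config$re_sd[["subject"]])
  names(u_subj) <- subjects$subject
  scene_ids <- unique(regions$scene_id)
  u_scene <- rnorm(length(scene_ids), 0, config$re_sd[["scene"]])
  names(u_scene) <- scene_ids
  u_obj <- NULL
  if (is_object) {
    u_obj <- rnorm(nrow(regions), 0, config$re_sd[["object"]])
    names(u_obj) <- regions$region_id
  }

  n_reg <- nrow(regions)
  n_sub <- nrow(subjects)
  out <- regions[rep(seq_len(n_reg), times = n_sub),
                 c("scene_id", "region_id", paste0("z_", preds))]
  names(out)[1] <- "scene"
  out$subject <- rep(subjects$subject, each = n_reg)
  out$age_group <- rep(subjects$age_group, each = n_reg)
  age01 <- as.numeric(out$age_group == "old")

  eta <- config$beta[["(Intercept)"]] +
    age01 * get_coef(config$beta_age_delta, "(Intercept)")
  for (p in preds) {
    z <- out[[paste0("z_", p)]]
    eta <- eta + z * (config$beta[[p]] + age01 * get_coef(config$beta_age_delta, p))
  }
  eta <- eta + u_subj[out$subject] + u_scene[out$scene]
  if (is_object) eta <- eta + u_obj[out$region_id]
  out$fixated <- rbinom(length(eta), 1L, plogis(eta))
  rownames(out) <- NULL
  out[, c("subject", "age_group", "scene", "region_id", "fixated",
          paste0("z_", preds))]
}

get_coef <- function(v, name) if (name %in% names(v)) v[[name]] else 0

#' Simulate scanpaths over a generated scene set
#'
#' End-to-end fixture generator: per (subject, scene) trial it produces an
#' initial central fixation followed by a sequence of fixations whose targets
#' are chosen among annotated objects with probability increasing in their
#' generating logit (or background locations with a centre-biased,
#' horizontally elongated spread), with immediate within-object refixations
#' at a configured rate. Within-object landing points follow the 2D Gaussian
#' preferred-viewing-location model: a launch-relative normalized offset with
#' mean `pvl_mean_offset` (negative = undershoot of the object centre toward
#' the launch site) and SD `pvl_sd`, truncated to the box. Durations are
#' lognormal. Exactly `n_missing_trials` randomly chosen (subject, scene)
#' trials are absent. The sequential target-selection rule is a pragmatic
#' stand-in for real scanpath generation -- data generated this way follow
#' the fitted fixation-probability model only approximately.
#'
#' @param config a [sim_config()].
#' @param scene_set output of [generate_scene_set()].
#' @param subjects optional subject table.
#' @return A `fixation_report` data frame.
#' @export
simulate_scanpaths <- function(config, scene_set, subjects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(subjects)) subjects <- subject_table(config)
  scene_ids <- names(scene_set$geometry)

  # per-scene object tables with z predictors and selection weights
  regions <- lapply(scene_ids, function(sc)
    regions_from_objects(scene_set$geometry[[sc]],
                         scene_set$annotations[scene_set$annotations$scene == sc, ],
                         salience_map = scene_set$salience_maps[[sc]]))
  names(regions) <- scene_ids
  all_regions <- do.call(rbind, lapply(regions, as.data.frame))
  preds <- setdiff(names(config$beta), "(Intercept)")
  all_regions <- standardize(all_regions, paste0("raw_", preds))

  logit_base <- rep(config$beta[["(Intercept)"]], nrow(all_regions))
  logit_delta <- rep(get_coef(config$beta_age_delta, "(Intercept)"),
                     nrow(all_regions))
  for (p in preds) {
    z <- all_regions[[paste0("z_", p)]]
    logit_base <- logit_base + z * config$beta[[p]]
    logit_delta <- logit_delta + z * get_coef(config$beta_age_delta, p)
  }
  all_regions$logit_base <- logit_base
  all_regions$logit_delta <- logit_delta

  # missing trials: sampled once from their own substream
  set.seed(substream_seed(config$seed, "missing"))
  n_sub <- nrow(subjects)
  all_trials <- expand.grid(si = seq_len(n_sub), ci = seq_along(scene_ids))
  missing_idx <- sample(nrow(all_trials), config$n_missing_trials)
  missing_keys <- paste(subjects$subject[all_trials$si[missing_idx]],
                        scene_ids[all_trials$ci[missing_idx]], sep = "\r")

  out <- vector("list", n_sub * length(scene_ids)); n_out <- 0L
  for (si in seq_len(n_sub)) {
    subj <- subjects$subject[si]
    old <- subjects$age_group[si] == "old"
    set.seed(substream_seed(config$seed, "scanpath", si))
    scene_order <- sample(seq_along(scene_ids))
    for (ti in seq_along(scene_order)) {
      sc <- scene_ids[scene_order[ti]]
      if (paste(subj, sc, sep = "\r") %in% missing_keys) next
      geom <- scene_set$geometry[[sc]]
      robj <- all_regions[all_regions$scene_id == sc, ]
      w <- exp(robj$logit_base + if (old) robj$logit_delta else 0)
      n_fix <- 1L + rpois(1L, max(config$fixations_per_trial_mean - 1, 0))
      xs <- ys <- numeric(n_fix)
      xs[1] <- clamp(geom$centre[1] + rnorm(1L, 0, 10), 0, geom$width_px - 1)
      ys[1] <- clamp(geom$centre[2] + rnorm(1L, 0, 10), 0, geom$height_px - 1)
      cur_obj <- 0L
      for (k in seq_len(n_fix)[-1]) {
        refix <- cur_obj > 0L && runif(1L) < config$p_refixation
        if (refix) {
          j <- cur_obj
          xs[k] <- trunc_norm(robj$centre_x[j], robj$width[j] / 4,
                              robj$x_min[j], robj$x_min[j] + robj$width[j] - 1)
          ys[k] <- trunc_norm(robj$centre_y[j], robj$height[j] / 4,
                              robj$y_min[j], robj$y_min[j] + robj$height[j] - 1)
        } else if (runif(1L) < config$p_object_target) {
          j <- sample.int(nrow(robj), 1L, prob = w)
          land <- pvl_landing(config, robj[j, ], xs[k - 1], ys[k - 1])
          xs[k] <- land[1]; ys[k] <- land[2]
          cur_obj <- j
        } else {
          xs[k] <- trunc_norm(geom$centre[1], geom$width_px / 4.5,
                              0, geom$width_px - 1)
          ys[k] <- trunc_norm(geom$centre[2],
                              0.45 * geom$width_px / 4.5,
                              0, geom$height_px - 1)
          cur_obj <- 0L
        }
      }
      dur <- rlnorm(n_fix, config$fixation_duration_log_mean,
                    config$fixation_duration_log_sd)
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        subject = subj, age_group = subjects$age_group[si], scene = sc,
        trial_index = ti, fix_index = seq_len(n_fix),
        x_px = round(xs, 1), y_px = round(ys, 1),
        duration_ms = round(dur, 1), stringsAsFactors = FALSE)
    }
  }
  as_fixation_report(do.call(rbind, out[seq_len(n_out)]))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

trunc_norm <- function(mean, sd, lo, hi) {
  for (i in seq_len(50L)) {
    v <- rnorm(1L, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  clamp(rnorm(1L, mean, sd), lo, hi)
}

# launch-relative 2D Gaussian landing point inside an object's box
pvl_landing <- function(config, obj, launch_x, launch_y) {
  sx <- sign(obj$centre_x - launch_x); if (sx == 0) sx <- 1
  sy <- sign(obj$centre_y - launch_y); if (sy == 0) sy <- 1
  mx <- rnorm(1L, config$pvl_mean_offset[1], config$pvl_sd[1])
  my <- rnorm(1L, config$pvl_mean_offset[2], config$pvl_sd[2])
  x <- obj$centre_x + sx * mx * obj$width
  y <- obj$centre_y + sy * my * obj$height
  c(clamp(x, obj$x_min, obj$x_min + obj$width - 1),
    clamp(y, obj$y_min, obj$y_min + obj$height - 1))
}

#' Generate a complete synthetic dataset
#'
#' Runs the scene, scanpath and memory generators with the configured seed
#' and bundles their outputs with the generating parameters.
#'
#' @param config a [sim_config()].
#' @return A list of class `scene_sim` with `geometry`, `annotations`,
#'   `salience_maps`, `fixation_report`, `memory` and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  scene_set <- generate_scene_set(config)
  subjects <- subject_table(config)
  report <- simulate_scanpaths(config, scene_set, subjects)
  memory <- simulate_memory_responses(config, subjects)
  structure(list(geometry = scene_set$geometry,
                 annotations = scene_set$annotations,
                 salience_maps = scene_set$salience_maps,
                 fixation_report = report,
                 memory = memory,
                 config = config),
            class = "scene_sim")
}

#' @exportS3Method base::print
print.scene_sim <- function(x, ...) {
  cat(sprintf("<scene_sim> %d scenes, %d objects, %d fixations in %d trials, seed %d\n",
              length(x$geometry), nrow(x$annotations),
              nrow(x$fixation_report), n_trials(x$fixation_report),
              x$config$seed))
  invisible(x)
}
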