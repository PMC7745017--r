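#' Annotation table input/output
#'
#' CSV dialect: `scene,object_id,x_min,y_min,width,height,label`.
#'
#' @param annotations annotation data frame.
#' @param path CSV file path.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("scene", "object_id", "x_min", "y_min", "width", "height", "label")
  if (is.null(annotations$label)) annotations$label <- ""
  utils::write.csv(annotations[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Per-scene region sets for a dataset
#'
#' @param dataset a `scene_sim` (or a list with `geometry`, `annotations`,
#'   `salience_maps`).
#' @param kind `"grid"` or `"object"`.
#' @param grid_cols,grid_rows grid dimensions (grid kind).
#' @param vertical_scale central-bias anisotropy.
#' @return Named list of `region_set`s, one per scene.
#' @export
region_sets_for <- function(dataset, kind = c("grid", "object"),
                            grid_cols = 8L, grid_rows = 6L,
                            vertical_scale = DEFAULT_VERTICAL_SCALE) {
  kind <- match.arg(kind)
  scenes <- names(dataset$geometry)
  out <- lapply(scenes, function(sc) {
    if (kind == "grid") {
      make_grid(dataset$geometry[[sc]], grid_cols, grid_rows,
                salience_map = dataset$salience_maps[[sc]],
                vertical_scale = vertical_scale)
    } else {
      regions_from_objects(dataset$geometry[[sc]],
                           dataset$annotations[dataset$annotations$scene == sc, ],
                           salience_map = dataset$salience_maps[[sc]],
                           vertical_scale = vertical_scale)
    }
  })
  names(out) <- scenes
  out
}

#' Join object predictors onto a per-object analysis table
#'
#' Adds the raw central-bias, size and salience predictors of each row's
#' object and z-transforms them over that table's rows (each analysis is
#' standardized over its own observation rows).
#'
#' @param table data frame with an `object_id` column (e.g. from
#'   [object_fixation_times()]).
#' @param object_sets named list of object `region_set`s.
#' @return `table` with raw and `z_` predictor columns.
#' @export
attach_object_predictors <- function(table, object_sets) {
  pred <- do.call(rbind, lapply(object_sets, function(rs)
    data.frame(object_id = rs$region_id,
               raw_central_bias = rs$raw_central_bias,
               raw_size = rs$raw_size,
               raw_salience = rs$raw_salience, stringsAsFactors = FALSE)))
  m <- match(table$object_id, pred$object_id)
  table$raw_central_bias <- pred$raw_central_bias[m]
  table$raw_size <- pred$raw_size[m]
  table$raw_salience <- pred$raw_salience[m]
  standardize(table, c("raw_central_bias", "raw_size", "raw_salience"))
}

#' Validate analysis inputs
#'
#' Report-only diagnostics for a loaded dataset: salience-map normalization,
#' bounding-box bounds, fixation bounds, and trial completeness (missing
#' (subject, scene) pairs).
#'
#' @param dataset a `scene_sim`-like list (`geometry`, `annotations`,
#'   `salience_maps`, `fixation_report`).
#' @return A list with `issues` (character vector, empty when clean) and
#'   `n_missing_trials`.
#' @export
validate_inputs <- function(dataset) {
  issues <- character(0)
  for (sc in names(dataset$salience_maps)) {
    s <- sum(dataset$salience_maps[[sc]])
    if (abs(s - 1) > 1e-6)
      issues <- c(issues, sprintf("salience map %s not unit-integral (sum %.6f)", sc, s))
  }
  an <- dataset$annotations
  for (i in seq_len(nrow(an))) {
    g <- dataset$geometry[[an$scene[i]]]
    if (is.null(g)) { issues <- c(issues, paste("no geometry for scene", an$scene[i])); next }
    if (an$width[i] <= 0 || an$height[i] <= 0 ||
        an$x_min[i] < 0 || an$y_min[i] < 0 ||
        an$x_min[i] + an$width[i] > g$width_px ||
        an$y_min[i] + an$height[i] > g$height_px)
      issues <- c(issues, paste("bad bounding box for object", an$object_id[i]))
  }
  fr <- dataset$fixation_report
  for (sc in unique(fr$scene)) {
    g <- dataset$geometry[[sc]]
    if (is.null(g)) next
    rows <- fr$scene == sc
    n_oob <- sum(fr$x_px[rows] < 0 | fr$x_px[rows] > g$width_px |
                   fr$y_px[rows] < 0 | fr$y_px[rows] > g$height_px)
    if (n_oob > 0)
      issues <- c(issues, sprintf("%d out-of-bounds fixation(s) in scene %s", n_oob, sc))
  }
  subjects <- unique(fr$subject)
  scenes <- names(dataset$geometry)
  present <- unique(paste(fr$subject, fr$scene, sep = "\r"))
  n_missing <- length(subjects) * length(scenes) - length(present)
  list(issues = issues, n_missing_trials = n_missing,
       n_trials = length(present), n_subjects = length(subjects),
       n_scenes = length(scenes))
}

#' Run the full analysis pipeline
#'
#' One-call orchestration: simulate (or load) a dataset, run the requested
#' analysis families, and write result tables plus a run manifest to
#' `out_dir`. Analyses: group descriptives, grid GLMM, object GLMM,
#' fixation-time LMMs (log first-fixation and gaze durations), PVL LMMs
#' (horizontal/vertical normalized landing positions) with density grids,
#' and memory-test signal detection. All numeric output is written at full
#' precision; any stage error aborts with the stage name and removes partial
#' outputs.
#'
#' @param config a [sim_config()] describing the corpus (and, in load mode,
#'   the geometry/grid settings).
#' @param out_dir output directory (created if needed).
#' @param paths `NULL` to simulate from `config`, or a list with `fixations`
#'   (CSV), `annotations` (CSV) and `maps_dir` (directory of
#'   `<scene>.txt` matrices) to load.
#' @param analyses subset of
#'   `c("descriptives", "grid", "object", "times", "pvl", "sdt")`.
#' @param random_structure `"intercepts"` fits random-intercept models
#'   (fast); `"paper"` fits the maximal by-subject (and, for the grid model,
#'   by-scene) random-slope structures of the emulated study.
#' @return Invisibly, a list of fitted objects and tables; results are also
#'   on disk.
#' @export
run_pipeline <- function(config, out_dir, paths = NULL,
                         analyses = c("descriptives", "grid", "object",
                                      "times", "pvl", "sdt"),
                         random_structure = c("intercepts", "paper")) {
  random_structure <- match.arg(random_structure)
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  results <- list()
  tryCatch({
    stage <- "data"
    dataset <- if (is.null(paths)) generate_dataset(config) else
      load_dataset(config, paths)
    results$validation <- validate_inputs(dataset)

    stage <- "regions"
    grids <- if (any(c("grid") %in% analyses))
      region_sets_for(dataset, "grid", config$grid_cols, config$grid_rows)
    objects <- if (any(c("object", "times", "pvl") %in% analyses))
      region_sets_for(dataset, "object")

    manifest <- list(config = unclass(config), seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version = as.character(utils::packageVersion("scenefix")),
                     analyses = analyses, random_structure = random_structure,
                     n_trials = n_trials(dataset$fixation_report),
                     n_missing_trials = results$validation$n_missing_trials,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

    if ("descriptives" %in% analyses) {
      stage <- "descriptives"
      d <- descriptive_stats(dataset$fixation_report, dataset$geometry)
      emit(d$per_subject, "descriptives_per_subject.csv")
      emit(d$summary, "descriptives_summary.csv")
      emit(d$tests, "descriptives_tests.csv")
      results$descriptives <- d
    }
    if ("grid" %in% analyses) {
      stage <- "grid GLMM"
      om <- build_grid_observation_matrix(dataset$fixation_report, grids)
      manifest$grid_matrix_rows <- nrow(om)
      f <- if (random_structure == "paper")
        "fixated ~ 1 + age + z_central_bias + z_central_bias:age + z_salience + z_salience:age + (1 + z_central_bias + z_salience | subject) + (1 + z_central_bias + z_salience | scene)"
      else
        "fixated ~ 1 + age + z_central_bias + z_central_bias:age + z_salience + z_salience:age + (1 | subject) + (1 | scene)"
      fit <- fit_binomial_glmm(f, om)
      s <- summarize_fit(fit, "grid", derive_old = TRUE)
      emit(s$fixed, "grid_glmm_fixed.csv")
      emit(s$random, "grid_glmm_random.csv")
      results$grid <- list(matrix = om, fit = fit)
    }
    if ("object" %in% analyses) {
      stage <- "object GLMM"
      om <- build_object_observation_matrix(dataset$fixation_report, objects)
      manifest$object_matrix_rows <- nrow(om)
      manifest$n_initial_coincident <- attr(om, "n_coincident")
      f <- if (random_structure == "paper")
        "fixated ~ 1 + age + z_central_bias + z_central_bias:age + z_size + z_size:age + z_salience + z_salience:age + (1 + z_central_bias + z_size + z_salience | subject) + (1 | region_id) + (1 | scene)"
      else
        "fixated ~ 1 + age + z_central_bias + z_central_bias:age + z_size + z_size:age + z_salience + z_salience:age + (1 | subject) + (1 | region_id) + (1 | scene)"
      fit <- fit_binomial_glmm(f, om)
      s <- summarize_fit(fit, "object", derive_old = TRUE)
      emit(s$fixed, "object_glmm_fixed.csv")
      emit(s$random, "object_glmm_random.csv")
      results$object <- list(matrix = om, fit = fit)
    }
    if ("times" %in% analyses) {
      stage <- "fixation-time LMMs"
      ft <- object_fixation_times(dataset$fixation_report, objects)
      manifest$n_fixation_time_visits <- nrow(ft)
      manifest$n_coincident_excluded <- attr(ft, "n_coincident_excluded")
      manifest$n_last_excluded <- attr(ft, "n_last_excluded")
      ft <- attach_object_predictors(ft, objects)
      ft$log_first_fix <- log(ft$first_fix_ms)
      ft$log_gaze <- log(ft$gaze_ms)
      rand <- if (random_structure == "paper")
        "(1 + z_central_bias + z_size + z_salience | subject) + (1 | object_id) + (1 | scene)"
      else "(1 | subject) + (1 | object_id) + (1 | scene)"
      fixed <- "1 + age + z_central_bias + z_central_bias:age + z_size + z_size:age + z_salience + z_salience:age"
      fit_ff <- fit_lmm(paste("log_first_fix ~", fixed, "+", rand), ft)
      fit_gz <- fit_lmm(paste("log_gaze ~", fixed, "+", rand), ft)
      emit(summarize_fit(fit_ff, "times")$fixed, "times_first_fixation_fixed.csv")
      emit(summarize_fit(fit_ff, "times")$random, "times_first_fixation_random.csv")
      emit(summarize_fit(fit_gz, "times")$fixed, "times_gaze_fixed.csv")
      emit(summarize_fit(fit_gz, "times")$random, "times_gaze_random.csv")
      results$times <- list(table = ft, first_fixation = fit_ff, gaze = fit_gz)
    }
    if ("pvl" %in% analyses) {
      stage <- "PVL analysis"
      pv <- pvl_table(dataset$fixation_report, objects)
      manifest$n_pvl_landings <- nrow(pv)
      pv$z_size <- as.vector(scale(pv$raw_size))
      rand <- if (random_structure == "paper")
        "(1 + z_size | subject) + (1 | object_id) + (1 | scene)"
      else "(1 | subject) + (1 | object_id)"
      fit_x <- fit_lmm(paste("nx ~ 1 + age + z_size + z_size:age +", rand),
                       pv, reduce = random_structure == "paper")
      fit_y <- fit_lmm(paste("ny ~ 1 + age + z_size + z_size:age +", rand),
                       pv, reduce = random_structure == "paper")
      emit(summarize_fit(fit_x, "pvl")$fixed, "pvl_horizontal_fixed.csv")
      emit(summarize_fit(fit_y, "pvl")$fixed, "pvl_vertical_fixed.csv")
      summ <- pvl_summary(pv)
      emit(summ$group_stats, "pvl_group_stats.csv")
      for (gp in names(summ$density)) {
        p <- file.path(out_dir, sprintf("pvl_density_%s.txt", gp))
        utils::write.table(summ$density[[gp]], p, row.names = FALSE,
                           col.names = FALSE)
        written <- c(written, p)
      }
      results$pvl <- list(table = pv, horizontal = fit_x, vertical = fit_y,
                          summary = summ)
    }
    if ("sdt" %in% analyses) {
      stage <- "memory SDT"
      scored <- score_sdt(dataset$memory)
      emit(scored, "sdt_subjects.csv")
      emit(sdt_group_compare(scored), "sdt_tests.csv")
      results$sdt <- scored
    }
    stage <- "manifest"
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$manifest <- manifest
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(results)
}

# load-mode counterpart of generate_dataset()
load_dataset <- function(config, paths) {
  annotations <- read_annotations(paths$annotations)
  scenes <- unique(annotations$scene)
  geometry <- lapply(scenes, function(sc)
    scene_geometry(sc, config$image_width_px, config$image_height_px))
  names(geometry) <- scenes
  maps <- lapply(scenes, function(sc) {
    p <- file.path(paths$maps_dir, paste0(sc, ".txt"))
    if (!file.exists(p)) stop("missing salience map: ", p)
    read_salience_map(p)
  })
  names(maps) <- scenes
  report <- load_fixation_report(paths$fixations, geometry = geometry)
  memory <- if (!is.null(paths$memory)) {
    utils::read.csv(paths$memory, stringsAsFactors = FALSE)
  } else simulate_memory_responses(config)
  list(geometry = geometry, annotations = annotations, salience_maps = maps,
       fixation_report = report, memory = memory, config = config)
}
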