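#' Build the grid observation matrix
#'
#' One row per analysed trial and grid cell, with a binary `fixated` outcome.
#' Per trial, the cell containing the trial's initial (central) fixation is
#' dropped, so a complete design yields
#' `subjects x scenes x (cells - 1)` rows, reduced by missing trials; a
#' 76-subject, 150-scene corpus with 10 missing trials and an 8 x 6 grid
#' yields 535,330 rows. A cell counts as fixated when any non-initial
#' fixation of the trial falls inside it (the last fixation is included, as
#' in all position analyses).
#'
#' @param report a [as_fixation_report()] object.
#' @param region_sets named list (by scene id) of grid `region_set`s with
#'   `raw_salience` filled in.
#' @param standardize_predictors z-transform central bias and salience over
#'   the assembled rows (the default, as required for model fitting).
#' @return A data frame of class `observation_matrix` with columns `subject`,
#'   `age_group`, `scene`, `region_id`, `fixated` and raw plus z-scored
#'   predictors. Attributes: `analysis` ("grid"), `n_trials`,
#'   `excluded_cells` (one per trial), `standardization`.
#' @export
build_grid_observation_matrix <- function(report, region_sets,
                                          standardize_predictors = TRUE) {
  stopifnot(inherits(report, "fixation_report"))
  scenes <- unique(report$scene)
  if (!all(scenes %in% names(region_sets)))
    stop("region_sets must contain a grid for every scene in the report")
  cells <- region_sets[[scenes[1]]]$region_id
  n_cells <- length(cells)

  # cell assignment for every fixation
  report$cell <- NA_character_
  for (sc in scenes) {
    rows <- which(report$scene == sc)
    report$cell[rows] <- assign_fixation_to_regions(
      report$x_px[rows], report$y_px[rows], region_sets[[sc]])
  }

  init <- report[report$is_initial, c("subject", "age_group", "scene", "cell")]
  names(init)[4] <- "cell0"
  n_tr <- nrow(init)

  hit_keys <- unique(with(report[report$include_position & !is.na(report$cell), ],
                          paste(subject, scene, cell, sep = "\r")))

  long <- init[rep(seq_len(n_tr), each = n_cells), ]
  long$region_id <- rep(cells, times = n_tr)
  keep <- is.na(long$cell0) | long$region_id != long$cell0
  long <- long[keep, c("subject", "age_group", "scene", "region_id")]
  long$fixated <- as.integer(
    paste(long$subject, long$scene, long$region_id, sep = "\r") %in% hit_keys)

  pred <- do.call(rbind, lapply(scenes, function(sc) {
    rs <- region_sets[[sc]]
    data.frame(scene = sc, region_id = rs$region_id,
               central_bias = rs$raw_central_bias,
               salience = rs$raw_salience, stringsAsFactors = FALSE)
  }))
  m <- match(paste(long$scene, long$region_id, sep = "\r"),
             paste(pred$scene, pred$region_id, sep = "\r"))
  long$central_bias <- pred$central_bias[m]
  long$salience <- pred$salience[m]
  if (standardize_predictors)
    long <- standardize(long, c("central_bias", "salience"))
  rownames(long) <- NULL
  structure(long,
            analysis = "grid", n_trials = n_tr,
            excluded_cells = init,
            class = c("observation_matrix", "data.frame"))
}

#' Build the object observation matrix
#'
#' One row per subject x annotated object; `fixated` is 1 when any
#' non-initial fixation of that subject's trial on the object's scene lands
#' inside the object's inclusive bounding box (overlapping boxes each credit
#' the fixation). Rows of missing trials are dropped. Cases in which the
#' initial central fixation was the subject's first fixation on an object are
#' counted (attribute `n_coincident`) for downstream exclusion from
#' fixation-time and landing-position tables; in this binary matrix the
#' initial fixation never sets the outcome (it is excluded from all
#' analyses), but later visits may.
#'
#' @inheritParams build_grid_observation_matrix
#' @param region_sets named list (by scene id) of object `region_set`s with
#'   `raw_salience` filled in.
#' @return An `observation_matrix` data frame with predictors central bias,
#'   size (log px^2) and salience, raw and z-scored.
#' @export
build_object_observation_matrix <- function(report, region_sets,
                                            standardize_predictors = TRUE) {
  stopifnot(inherits(report, "fixation_report"))
  scenes <- names(region_sets)
  if (!all(unique(report$scene) %in% scenes))
    stop("region_sets must contain object regions for every scene in the report")
  subj <- unique(as.data.frame(report)[, c("subject", "age_group")])
  trial_keys <- unique(paste(report$subject, report$scene, sep = "\r"))

  hit_keys <- character(0)
  coincident <- 0L
  pred <- vector("list", length(scenes))
  for (si in seq_along(scenes)) {
    sc <- scenes[si]
    rs <- region_sets[[sc]]
    pred[[si]] <- data.frame(scene = sc, region_id = rs$region_id,
                             central_bias = rs$raw_central_bias,
                             size = rs$raw_size,
                             salience = rs$raw_salience,
                             stringsAsFactors = FALSE)
    fx <- report[report$scene == sc, ]
    if (!nrow(fx) || !nrow(rs)) next
    pos <- fx[fx$include_position, ]
    if (nrow(pos)) {
      hits <- object_hits(pos$x_px, pos$y_px, rs)
      idx <- which(hits, arr.ind = TRUE)
      if (nrow(idx))
        hit_keys <- c(hit_keys, unique(
          paste(pos$subject[idx[, 1]], sc, rs$region_id[idx[, 2]], sep = "\r")))
    }
    ini <- fx[fx$is_initial, ]
    if (nrow(ini))
      coincident <- coincident + sum(object_hits(ini$x_px, ini$y_px, rs))
  }
  pred <- do.call(rbind, pred)

  long <- merge(subj, pred[, c("scene", "region_id")], by = NULL)
  long <- long[paste(long$subject, long$scene, sep = "\r") %in% trial_keys, ]
  long <- long[order(long$subject, long$scene, long$region_id), ]
  long$fixated <- as.integer(
    paste(long$subject, long$scene, long$region_id, sep = "\r") %in% hit_keys)
  m <- match(paste(long$scene, long$region_id, sep = "\r"),
             paste(pred$scene, pred$region_id, sep = "\r"))
  long$central_bias <- pred$central_bias[m]
  long$size <- pred$size[m]
  long$salience <- pred$salience[m]
  if (standardize_predictors && nrow(long))
    long <- standardize(long, c("central_bias", "size", "salience"))
  rownames(long) <- NULL
  structure(long,
            analysis = "object", n_trials = length(trial_keys),
            n_coincident = coincident,
            class = c("observation_matrix", "data.frame"))
}
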