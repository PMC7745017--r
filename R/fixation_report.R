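#' Fixation reports and exclusion flags
#'
#' A fixation report is a long data frame with one row per fixation:
#' `subject`, `age_group` (`young`/`old`), `scene`, `trial_index`,
#' `fix_index`, `x_px`, `y_px`, `duration_ms`. Rows are grouped into trials
#' by (subject, scene). On construction the standard exclusion flags are
#' computed: the initial (central) fixation of a trial is excluded from all
#' analyses; the last fixation of a trial is included in position analyses
#' but excluded from duration analyses. The flags are stored as logical
#' columns `is_initial`, `is_last`, `include_position` and
#' `include_duration`.
#'
#' @param df data frame with the columns listed above.
#' @param geometry optional [scene_geometry()] (or list of them, one per
#'   scene) used to warn about fixations outside the image bounds; such
#'   fixations are retained but will be assignable to no region.
#' @return A data frame of class `fixation_report`, ordered by subject,
#'   scene and fixation index.
#' @export
as_fixation_report <- function(df, geometry = NULL) {
  required <- c("subject", "age_group", "scene", "trial_index", "fix_index",
                "x_px", "y_px", "duration_ms")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("fixation report lacks column(s): ", paste(miss, collapse = ", "))
  num <- c("trial_index", "fix_index", "x_px", "y_px", "duration_ms")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at row %d", col, bad[1]))
    df[[col]] <- v
  }
  if (any(df$duration_ms <= 0))
    stop("fixation durations must be strictly positive (row ",
         which(df$duration_ms <= 0)[1], ")")
  if (!all(df$age_group %in% c("young", "old")))
    stop("age_group must be 'young' or 'old'")
  df$subject <- as.character(df$subject)
  df$scene <- as.character(df$scene)
  df <- df[order(df$subject, df$scene, df$fix_index), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    key <- paste(df$subject, df$scene, sep = "\r")
    first_of <- !duplicated(key)
    last_of <- !duplicated(key, fromLast = TRUE)
    df$is_initial <- first_of
    df$is_last <- last_of
  } else {
    df$is_initial <- logical(0)
    df$is_last <- logical(0)
  }
  df$include_position <- !df$is_initial
  df$include_duration <- !df$is_initial & !df$is_last
  if (!is.null(geometry)) {
    geoms <- geometry_list(geometry)
    oob <- 0L
    for (sc in unique(df$scene)) {
      g <- geoms[[sc]]
      if (is.null(g)) next
      rows <- df$scene == sc
      oob <- oob + sum(df$x_px[rows] < 0 | df$x_px[rows] > g$width_px |
                         df$y_px[rows] < 0 | df$y_px[rows] > g$height_px)
    }
    if (oob > 0)
      warning(oob, " fixation(s) outside the image bounds; retained but ",
              "assignable to no region")
  }
  class(df) <- c("fixation_report", "data.frame")
  df
}

geometry_list <- function(geometry) {
  if (inherits(geometry, "scene_geometry"))
    return(setNames(list(geometry), geometry$scene_id))
  geometry
}

#' Load a fixation report from CSV
#'
#' Reads the UTF-8 CSV dialect written by [write_fixation_report()] (header
#' `subject,age_group,scene,trial_index,fix_index,x_px,y_px,duration_ms`) and
#' applies the exclusion flags of [as_fixation_report()]. Missing trials are
#' simply absent from the file.
#'
#' @param path CSV file path.
#' @inheritParams as_fixation_report
#' @return A `fixation_report` data frame.
#' @export
load_fixation_report <- function(path, geometry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  as_fixation_report(df, geometry = geometry)
}

#' @rdname load_fixation_report
#' @param report a `fixation_report`.
#' @export
write_fixation_report <- function(report, path) {
  cols <- c("subject", "age_group", "scene", "trial_index", "fix_index",
            "x_px", "y_px", "duration_ms")
  utils::write.csv(as.data.frame(report)[, cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Count trials present in a report
#' @param report a `fixation_report`.
#' @return Number of (subject, scene) pairs with data.
#' @export
n_trials <- function(report) {
  length(unique(paste(report$subject, report$scene, sep = "\r")))
}

#' Assign fixations to regions
#'
#' For a grid region set every in-bounds fixation belongs to exactly one cell
#' (cells are half-open; the right/bottom image edge belongs to the last
#' cell). For an object region set a fixation belongs to every object whose
#' inclusive bounding box contains it -- possibly none, possibly several when
#' boxes overlap.
#'
#' @param x,y fixation coordinates in pixels (vectors of equal length).
#' @param region_set a `region_set` from [make_grid()] or
#'   [regions_from_objects()].
#' @return For grids, a character vector of region ids (`NA` when out of
#'   bounds); for objects, a list of character vectors of region ids.
#' @export
assign_fixation_to_regions <- function(x, y, region_set) {
  geom <- attr(region_set, "geometry")
  if (attr(region_set, "kind") == "grid") {
    cw <- region_set$width[1]; ch <- region_set$height[1]
    cols <- geom$width_px %/% cw
    rows <- geom$height_px %/% ch
    cx <- floor(x / cw); cy <- floor(y / ch)
    cx[x == geom$width_px] <- cols - 1   # image edge owned by the last cell
    cy[y == geom$height_px] <- rows - 1
    idx <- cy * cols + cx + 1
    oob <- x < 0 | x > geom$width_px | y < 0 | y > geom$height_px
    idx[oob] <- NA
    region_set$region_id[idx]
  } else {
    lapply(seq_along(x), function(i) {
      inb <- x[i] >= region_set$x_min & x[i] <= region_set$x_min + region_set$width - 1 &
        y[i] >= region_set$y_min & y[i] <= region_set$y_min + region_set$height - 1
      region_set$region_id[inb]
    })
  }
}

# Incidence matrix (fixations x objects) for one scene's object region set.
object_hits <- function(x, y, region_set) {
  outer(x, region_set$x_min, ">=") &
    outer(x, region_set$x_min + region_set$width - 1, "<=") &
    outer(y, region_set$y_min, ">=") &
    outer(y, region_set$y_min + region_set$height - 1, "<=")
}
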