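#' Region sets: grid- and object-based scene parcellations
#'
#' A region set is a data frame with one row per region (grid cell or object
#' bounding box) carrying the region bounds and the raw per-region predictors:
#' anisotropic central-bias distance, log bounding-box area, and mean salience
#' under a unit-integral map. A box with corner `(x_min, y_min)` and size
#' `width x height` covers the inclusive pixel range
#' `[x_min, x_min + width - 1] x [y_min, y_min + height - 1]`; its centre is
#' the midpoint of that range.
#'
#' @name region_set
NULL

region_centre <- function(x_min, extent) x_min + (extent - 1) / 2

new_region_set <- function(df, geometry, kind) {
  rownames(df) <- NULL
  structure(df, geometry = geometry, kind = kind,
            class = c("region_set", "data.frame"))
}

#' Divide a scene into a regular grid of cells
#'
#' Tiles the image exactly with `cols x rows` non-overlapping cells, indexed
#' row-major from the top-left. In continuous coordinates each cell is
#' half-open, owning `[i*w, (i+1)*w) x [j*h, (j+1)*h)`; the right/bottom image
#' edge belongs to the last cell. An 8 x 6 grid on an 800 x 600 image yields
#' 48 square 100 x 100 px cells.
#'
#' @param geometry a [scene_geometry()].
#' @param cols,rows number of grid columns and rows; image dimensions must be
#'   divisible by them.
#' @param salience_map optional unit-integral salience matrix
#'   (`height_px x width_px`) used to fill `raw_salience`.
#' @param vertical_scale anisotropy factor for the central-bias predictor.
#'
#' @return A `region_set` data frame with columns `scene_id`, `region_id`,
#'   `kind`, `x_min`, `y_min`, `width`, `height`, `centre_x`, `centre_y`,
#'   `raw_central_bias`, `raw_size` and (if a map is given) `raw_salience`.
#' @export
make_grid <- function(geometry, cols, rows, salience_map = NULL,
                      vertical_scale = DEFAULT_VERTICAL_SCALE) {
  stopifnot(inherits(geometry, "scene_geometry"))
  if (cols <= 0 || rows <= 0) stop("grid dimensions must be positive")
  rem_x <- geometry$width_px %% cols
  rem_y <- geometry$height_px %% rows
  if (rem_x != 0 || rem_y != 0)
    stop(sprintf(
      "image dimensions not divisible by grid: %d px x %d px over %d x %d cells leaves remainder (%d, %d)",
      geometry$width_px, geometry$height_px, cols, rows, rem_x, rem_y))
  cw <- geometry$width_px %/% cols
  ch <- geometry$height_px %/% rows
  ix <- rep(seq_len(cols) - 1L, times = rows)   # column index, row-major order
  iy <- rep(seq_len(rows) - 1L, each = cols)
  df <- data.frame(
    scene_id = geometry$scene_id,
    region_id = sprintf("cell_%02d", seq_len(cols * rows)),
    kind = "grid-cell",
    grid_row = iy, grid_col = ix,
    x_min = ix * cw, y_min = iy * ch,
    width = cw, height = ch,
    stringsAsFactors = FALSE)
  df$centre_x <- region_centre(df$x_min, df$width)
  df$centre_y <- region_centre(df$y_min, df$height)
  df$raw_central_bias <- central_bias(cbind(df$centre_x, df$centre_y),
                                      geometry$centre, vertical_scale)
  df$raw_size <- log(as.numeric(df$width) * df$height)
  if (!is.null(salience_map)) df$raw_salience <- region_salience(salience_map, df)
  new_region_set(df, geometry, "grid")
}

#' Region set from object bounding-box annotations
#'
#' One region per annotated object. Annotations must provide `object_id`,
#' `x_min`, `y_min`, `width`, `height` (and may carry `label`); boxes must be
#' non-degenerate and fully inside the image.
#'
#' @param geometry a [scene_geometry()].
#' @param annotations data frame of bounding boxes for this scene.
#' @inheritParams make_grid
#' @return A `region_set` data frame (empty if `annotations` has no rows).
#' @export
regions_from_objects <- function(geometry, annotations, salience_map = NULL,
                                 vertical_scale = DEFAULT_VERTICAL_SCALE) {
  stopifnot(inherits(geometry, "scene_geometry"))
  required <- c("object_id", "x_min", "y_min", "width", "height")
  miss <- setdiff(required, names(annotations))
  if (length(miss))
    stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  an <- annotations
  if (nrow(an)) {
    bad <- an$width <= 0 | an$height <= 0 | an$x_min < 0 | an$y_min < 0 |
      an$x_min + an$width > geometry$width_px |
      an$y_min + an$height > geometry$height_px
    if (any(bad))
      stop("degenerate or out-of-bounds bounding box for object(s): ",
           paste(an$object_id[bad], collapse = ", "))
  }
  df <- data.frame(
    scene_id = rep(geometry$scene_id, nrow(an)),
    region_id = as.character(an$object_id),
    kind = rep("object", nrow(an)),
    x_min = an$x_min, y_min = an$y_min,
    width = an$width, height = an$height,
    stringsAsFactors = FALSE)
  if (!is.null(an$label)) df$label <- as.character(an$label)
  df$centre_x <- region_centre(df$x_min, df$width)
  df$centre_y <- region_centre(df$y_min, df$height)
  df$raw_central_bias <- central_bias(cbind(df$centre_x, df$centre_y),
                                      geometry$centre, vertical_scale)
  df$raw_size <- log(as.numeric(df$width) * df$height)
  if (!is.null(salience_map)) df$raw_salience <- region_salience(salience_map, df)
  new_region_set(df, geometry, "object")
}

#' Mean salience of regions under a unit-integral map
#'
#' Arithmetic mean of map values over all pixels inside each region's
#' inclusive bounds. The map must be normalized to unit integral (sum of all
#' values equal to 1 within 1e-6); under such a map a uniform image has mean
#' value `1 / (width * height)` everywhere.
#'
#' @param map numeric matrix (`height_px x width_px`), non-negative, summing
#'   to 1.
#' @param regions a `region_set` or any data frame with `x_min`, `y_min`,
#'   `width`, `height` columns.
#' @return Numeric vector of per-region mean salience values.
#' @export
region_salience <- function(map, regions) {
  if (!is.matrix(map)) stop("salience map must be a matrix")
  s <- sum(map)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("salience map is not normalized to unit integral (sum = %.8f)", s))
  nr <- nrow(map); nc <- ncol(map)
  vapply(seq_len(nrow(regions)), function(i) {
    x0 <- regions$x_min[i]; y0 <- regions$y_min[i]
    x1 <- x0 + regions$width[i] - 1L
    y1 <- y0 + regions$height[i] - 1L
    if (x0 < 0 || y0 < 0 || x1 >= nc || y1 >= nr)
      stop("region bounds outside map for region ", regions$region_id[i])
    mean(map[(y0:y1) + 1L, (x0:x1) + 1L])
  }, numeric(1))
}

#' z-transform predictor columns
#'
#' Centres and scales each named column over all rows of the table, using the
#' sample (n - 1) standard deviation, and stores `z_<name>` columns. The
#' standardization constants are attached as attribute `"standardization"`
#' for reporting. Standardization is computed over the rows of the analysis'
#' observation matrix, pooled across age groups.
#'
#' @param rows data frame of observation rows.
#' @param predictors character vector of column names to standardize.
#' @return `rows` with added `z_<name>` columns and a `standardization`
#'   attribute (data frame of predictor, mean, sd).
#' @export
standardize <- function(rows, predictors) {
  miss <- setdiff(predictors, names(rows))
  if (length(miss)) stop("predictor column(s) not found: ",
                         paste(miss, collapse = ", "))
  consts <- data.frame(predictor = predictors, mean = NA_real_, sd = NA_real_)
  for (k in seq_along(predictors)) {
    p <- predictors[k]
    x <- rows[[p]]
    if (length(unique(x)) < 2L)
      stop("cannot standardize constant predictor: ", p)
    m <- mean(x); s <- sd(x)
    if (s == 0) stop("cannot standardize zero-variance predictor: ", p)
    rows[[paste0("z_", sub("^raw_", "", p))]] <- (x - m) / s
    consts$mean[k] <- m; consts$sd[k] <- s
  }
  attr(rows, "standardization") <- consts
  rows
}
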