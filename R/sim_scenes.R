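#' Generate synthetic scenes, object annotations and salience maps
#'
#' Emulates the stimulus side of a scene-viewing corpus. Per scene, an object
#' count is drawn from a Poisson distribution (truncated to >= 2 so that
#' inter-object distances exist) around `objects_per_scene_mean`; bounding
#' boxes are rejection-sampled so that they are non-degenerate, fully inside
#' the image, do not cross the vertical midline, and overlap pairwise by at
#' most 20% of the smaller box's area. Box widths/heights are drawn around
#' 2.5 degrees of visual angle. Salience maps are mixtures of 2D Gaussian
#' blobs -- some centred on objects, some on the background -- over a uniform
#' floor, normalized to unit integral.
#'
#' @param config a [sim_config()].
#' @param p_object_blob probability that an object contributes a salience
#'   blob.
#' @param n_background_blobs number of background blobs per scene.
#' @param background_mass fraction of total map mass assigned to the uniform
#'   floor.
#' @return A list with elements `geometry` (list of [scene_geometry()]),
#'   `annotations` (one data frame of boxes across scenes, with globally
#'   unique `object_id`) and `salience_maps` (named list of unit-integral
#'   matrices).
#' @export
generate_scene_set <- function(config, p_object_blob = 0.7,
                               n_background_blobs = 3L,
                               background_mass = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$image_width_px; h <- config$image_height_px
  ppd <- DEFAULT_PX_PER_DEGREE * w / 800  # keep angular size conventions
  geoms <- vector("list", config$n_scenes)
  anns <- vector("list", config$n_scenes)
  maps <- vector("list", config$n_scenes)
  scene_ids <- sprintf("scene_%03d", seq_len(config$n_scenes))
  labels <- c("cup", "book", "lamp", "plant", "chair", "bottle", "clock",
              "bowl", "shoe", "bag", "phone", "frame", "vase", "towel")
  for (i in seq_len(config$n_scenes)) {
    set.seed(substream_seed(config$seed, "scene", i))
    geom <- scene_geometry(scene_ids[i], w, h, px_per_degree = ppd)
    n_obj <- 0L
    while (n_obj < 2L) n_obj <- rpois(1L, config$objects_per_scene_mean)
    boxes <- place_boxes(geom, n_obj, ppd)
    boxes$scene <- scene_ids[i]
    boxes$object_id <- sprintf("obj_%03d_%02d", i, seq_len(n_obj))
    boxes$label <- sample(labels, n_obj, replace = TRUE)
    anns[[i]] <- boxes[, c("scene", "object_id", "x_min", "y_min",
                           "width", "height", "label")]
    maps[[i]] <- make_salience_map(geom, boxes, p_object_blob,
                                   n_background_blobs, background_mass)
    geoms[[i]] <- geom
  }
  names(geoms) <- scene_ids
  names(maps) <- scene_ids
  list(geometry = geoms,
       annotations = do.call(rbind, anns),
       salience_maps = maps)
}

# Rejection-sampled bounding boxes: sizes ~ 2.5 deg (SD 1.4 deg), centre
# eccentricity ~ 8.6 deg, no midline crossing, pairwise overlap <= 20% of the
# smaller box. Up to 1000 tries per object.
place_boxes <- function(geom, n_obj, ppd) {
  w <- geom$width_px; h <- geom$height_px
  mid <- w / 2
  size_px <- function(mean_deg, sd_deg) {
    repeat {
      s <- rnorm(1L, mean_deg * ppd, sd_deg * ppd)
      if (s >= 0.6 * ppd && s <= 8 * ppd) return(as.integer(round(s)))
    }
  }
  out <- data.frame(x_min = integer(n_obj), y_min = integer(n_obj),
                    width = integer(n_obj), height = integer(n_obj))
  for (k in seq_len(n_obj)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      bw <- size_px(2.5, 1.4); bh <- size_px(2.6, 1.5)
      ecc <- min(max(rnorm(1L, 8.6 * ppd, 2.6 * ppd), 1.5 * ppd), 12 * ppd)
      ang <- runif(1L, 0, 2 * pi)
      cx <- geom$centre[1] + ecc * cos(ang)
      cy <- geom$centre[2] + 0.7 * ecc * sin(ang)
      x0 <- as.integer(round(cx - (bw - 1) / 2))
      y0 <- as.integer(round(cy - (bh - 1) / 2))
      if (x0 < 0 || y0 < 0 || x0 + bw > w || y0 + bh > h) next
      if (!(x0 + bw <= mid || x0 >= mid)) next  # must not cross the midline
      ok <- TRUE
      if (k > 1L) for (j in seq_len(k - 1L)) {
        ov <- box_overlap(x0, y0, bw, bh,
                          out$x_min[j], out$y_min[j], out$width[j], out$height[j])
        if (ov > 0.2 * min(bw * bh, out$width[j] * out$height[j])) { ok <- FALSE; break }
      }
      if (!ok) next
      out[k, ] <- c(x0, y0, bw, bh)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place object ", k, " in scene ", geom$scene_id,
           " after 1000 tries")
  }
  out
}

box_overlap <- function(x0, y0, w0, h0, x1, y1, w1, h1) {
  dx <- min(x0 + w0, x1 + w1) - max(x0, x1)
  dy <- min(y0 + h0, y1 + h1) - max(y0, y1)
  if (dx <= 0 || dy <= 0) return(0)
  dx * dy
}

#' Synthetic salience map for one scene
#'
#' Mixture of axis-aligned 2D Gaussian blobs plus a uniform floor, normalized
#' to unit integral. Object blobs are centred near object centres with SDs of
#' 0.5--1.5 times the object half-extent, giving the object-salience
#' distribution an appreciable spread.
#'
#' @param geometry a [scene_geometry()].
#' @param boxes data frame of object boxes (`x_min`, `y_min`, `width`,
#'   `height`); may have zero rows.
#' @inheritParams generate_scene_set
#' @return A `height_px x width_px` matrix summing to 1.
#' @export
make_salience_map <- function(geometry, boxes, p_object_blob = 0.7,
                              n_background_blobs = 3L, background_mass = 0.1) {
  w <- geometry$width_px; h <- geometry$height_px
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  blob <- function(cx, cy, sx, sy)
    outer(dnorm(ys, cy, sy), dnorm(xs, cx, sx))
  m <- matrix(0, h, w)
  n_blob <- 0L
  if (nrow(boxes)) {
    take <- runif(nrow(boxes)) < p_object_blob
    if (!any(take) && n_background_blobs == 0L) take[1L] <- TRUE
    for (j in which(take)) {
      cx <- boxes$x_min[j] + (boxes$width[j] - 1) / 2 + rnorm(1L, 0, boxes$width[j] / 10)
      cy <- boxes$y_min[j] + (boxes$height[j] - 1) / 2 + rnorm(1L, 0, boxes$height[j] / 10)
      sx <- runif(1L, 0.5, 1.5) * boxes$width[j] / 2
      sy <- runif(1L, 0.5, 1.5) * boxes$height[j] / 2
      m <- m + runif(1L, 0.5, 2) * blob(cx, cy, sx, sy)
      n_blob <- n_blob + 1L
    }
  }
  if (n_background_blobs > 0L) for (j in seq_len(n_background_blobs)) {
    m <- m + runif(1L, 0.3, 1.2) *
      blob(runif(1L, 0, w - 1), runif(1L, 0, h - 1),
           runif(1L, 1.2, 4) * 30, runif(1L, 1.2, 4) * 30)
    n_blob <- n_blob + 1L
  }
  if (n_blob == 0L) return(matrix(1 / (w * h), h, w))
  m <- m / sum(m) * (1 - background_mass)
  m <- m + background_mass / (w * h)
  m / sum(m)
}

#' Write / read a salience map as a plain-text matrix
#'
#' Values are written row by row, whitespace-separated. The reader
#' re-normalizes to unit integral, so maps stored at reduced precision load
#' cleanly.
#'
#' @param map numeric matrix.
#' @param path file path.
#' @export
write_salience_map <- function(map, path) {
  utils::write.table(format(map, digits = 10, scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_salience_map
#' @export
read_salience_map <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (any(m < 0)) stop("salience map values must be non-negative: ", path)
  m / sum(m)
}
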