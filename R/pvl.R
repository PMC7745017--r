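#' Normalize a within-object landing position
#'
#' Landing positions are expressed per axis relative to the object centre,
#' scaled by the object's extent, and signed relative to the saccade's launch
#' site: `u = (landing - centre) / extent`, `n = sign(centre - launch) * u`
#' (with `sign(0)` taken as +1). Normalized coordinates range over
#' `[-0.5, 0.5]`; 0 is the object centre, negative values are undershoots of
#' the centre relative to the launch site, positive values overshoots. The
#' two axes are treated independently (no projection onto the saccade
#' vector), since launch site, landing site and object centre do not in
#' general fall on one straight line.
#'
#' @param landing numeric `c(x, y)` or two-column matrix of landing positions
#'   in pixels (must lie inside the box).
#' @param bounds numeric `c(x_min, y_min, width, height)` or four-column
#'   matrix of box bounds.
#' @param launch numeric `c(x, y)` or two-column matrix of launch positions
#'   in pixels.
#' @return Numeric `c(nx, ny)` or a two-column matrix.
#' @export
normalize_landing <- function(landing, bounds, launch) {
  landing <- rbind_coords(landing); launch <- rbind_coords(launch)
  if (!is.matrix(bounds)) bounds <- matrix(bounds, nrow = 1)
  centre <- cbind(region_centre(bounds[, 1], bounds[, 3]),
                  region_centre(bounds[, 2], bounds[, 4]))
  extent <- bounds[, 3:4, drop = FALSE]
  inside <-
    landing[, 1] >= bounds[, 1] & landing[, 1] <= bounds[, 1] + bounds[, 3] - 1 &
    landing[, 2] >= bounds[, 2] & landing[, 2] <= bounds[, 2] + bounds[, 4] - 1
  if (any(!inside))
    stop("landing position outside the object box (row ", which(!inside)[1], ")")
  u <- (landing - centre) / extent
  s <- sign(centre - launch)
  s[s == 0] <- 1
  n <- s * u
  if (nrow(n) == 1L) c(n) else n
}

rbind_coords <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Table of normalized first-pass landing positions
#'
#' One row per qualifying initial fixation in first-pass viewing: the entry
#' fixation of an object's first visit, launched from outside the object.
#' Refixations within the visit are excluded, as are cases in which the
#' initial central fixation was the first fixation on the object. Visits
#' containing the trial's last fixation are retained (position analyses keep
#' the last fixation).
#'
#' @inheritParams build_object_observation_matrix
#' @return Data frame with `subject`, `age_group`, `scene`, `object_id`,
#'   `nx`, `ny` (normalized landing coordinates in `[-0.5, 0.5]`),
#'   `raw_size` (log px^2 of the box) and launch coordinates.
#' @export
pvl_table <- function(report, region_sets) {
  fv <- first_visits(report, region_sets)
  fv <- fv[!fv$coincident, , drop = FALSE]
  if (!nrow(fv))
    return(data.frame(subject = character(0), age_group = character(0),
                      scene = character(0), object_id = character(0),
                      nx = numeric(0), ny = numeric(0), raw_size = numeric(0),
                      launch_x = numeric(0), launch_y = numeric(0)))
  bounds <- matrix(NA_real_, nrow(fv), 4)
  for (sc in unique(fv$scene)) {
    rs <- region_sets[[sc]]
    rows <- which(fv$scene == sc)
    m <- match(fv$object_id[rows], rs$region_id)
    bounds[rows, ] <- cbind(rs$x_min[m], rs$y_min[m], rs$width[m], rs$height[m])
  }
  n <- normalize_landing(cbind(fv$landing_x, fv$landing_y), bounds,
                         cbind(fv$launch_x, fv$launch_y))
  n <- rbind_coords(n)
  data.frame(subject = fv$subject, age_group = fv$age_group,
             scene = fv$scene, object_id = fv$object_id,
             nx = n[, 1], ny = n[, 2],
             raw_size = log(bounds[, 3] * bounds[, 4]),
             launch_x = fv$launch_x, launch_y = fv$launch_y,
             stringsAsFactors = FALSE)
}

#' Summaries of the preferred viewing location
#'
#' Per age group: mean and SD of the normalized landing coordinates, 1D
#' histograms, and a smoothed 2D histogram over `[-0.5, 0.5]^2` on a fixed
#' lattice (Gaussian kernel, bandwidth by the normal reference rule).
#'
#' @param table output of [pvl_table()].
#' @param grid_n lattice resolution per axis for the 2D density.
#' @return A list with `group_stats`, `hist_x`, `hist_y` (per group) and
#'   `density` (per group, `grid_n x grid_n` matrix with axis attribute).
#' @export
pvl_summary <- function(table, grid_n = 51L) {
  if (!nrow(table)) stop("empty landing-position table")
  groups <- intersect(c("young", "old"), unique(table$age_group))
  stats_df <- do.call(rbind, lapply(groups, function(gp) {
    t2 <- table[table$age_group == gp, ]
    data.frame(age_group = gp, n = nrow(t2),
               mean_nx = mean(t2$nx), sd_nx = sd(t2$nx),
               mean_ny = mean(t2$ny), sd_ny = sd(t2$ny),
               stringsAsFactors = FALSE)
  }))
  breaks <- seq(-0.5, 0.5, length.out = 26L)
  hist_of <- function(v) graphics::hist(pmin(pmax(v, -0.5), 0.5),
                                        breaks = breaks, plot = FALSE)
  axis <- seq(-0.5, 0.5, length.out = grid_n)
  dens <- lapply(groups, function(gp) {
    t2 <- table[table$age_group == gp, ]
    d <- kde2d_grid(t2$nx, t2$ny, axis)
    attr(d, "axis") <- axis
    d
  })
  names(dens) <- groups
  list(group_stats = stats_df,
       hist_x = lapply(setNames(groups, groups),
                       function(gp) hist_of(table$nx[table$age_group == gp])),
       hist_y = lapply(setNames(groups, groups),
                       function(gp) hist_of(table$ny[table$age_group == gp])),
       density = dens)
}

# Gaussian-kernel 2D density on a fixed lattice; normal reference bandwidth.
kde2d_grid <- function(x, y, axis) {
  nrd <- function(v) {
    s <- sd(v)
    if (s == 0) s <- 1e-3
    1.06 * s * length(v)^(-1 / 5)
  }
  hx <- nrd(x); hy <- nrd(y)
  gx <- outer(axis, x, function(a, b) dnorm(a, b, hx))
  gy <- outer(axis, y, function(a, b) dnorm(a, b, hy))
  (gy %*% t(gx)) / length(x)  # rows = y axis, cols = x axis
}
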