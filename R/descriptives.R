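#' Per-subject scanning descriptives and group comparison
#'
#' Per subject: mean number of fixations per trial, mean fixation duration in
#' ms (initial and last fixations excluded), and mean saccade amplitude in
#' degrees (Euclidean distance between consecutive fixations within a trial,
#' divided by the pixel-per-degree scale). Group means/SDs and Welch
#' two-sample t-tests (fractional degrees of freedom) compare the age groups.
#'
#' @param report a [as_fixation_report()] object.
#' @param geometry a [scene_geometry()] (or list of them); supplies
#'   `px_per_degree`.
#' @return A list with `per_subject`, `summary` (group x measure means/SDs)
#'   and `tests` (Welch t, df, p per measure).
#' @export
descriptive_stats <- function(report, geometry) {
  stopifnot(inherits(report, "fixation_report"))
  g1 <- geometry_list(geometry)[[1]]
  ppd <- g1$px_per_degree
  df <- as.data.frame(report)
  tkey <- paste(df$subject, df$scene, sep = "\r")

  per_trial_n <- tapply(df$fix_index, tkey, length)
  t2s <- df$subject[match(names(per_trial_n), tkey)]
  n_fix <- tapply(as.numeric(per_trial_n), t2s, mean)

  dur <- df[df$include_duration, ]
  mean_dur <- tapply(dur$duration_ms, dur$subject, mean)

  same_trial <- c(tkey[-1] == tkey[-nrow(df)], FALSE)
  dx <- c(diff(df$x_px), NA); dy <- c(diff(df$y_px), NA)
  amp <- sqrt(dx^2 + dy^2)[same_trial] / ppd
  amp_subject <- df$subject[which(same_trial)]
  mean_amp <- tapply(amp, amp_subject, mean)

  subj <- unique(df[, c("subject", "age_group")])
  per_subject <- data.frame(
    subject = subj$subject, age_group = subj$age_group,
    fixations_per_trial = as.numeric(n_fix[subj$subject]),
    fixation_duration_ms = as.numeric(mean_dur[subj$subject]),
    saccade_amplitude_deg = as.numeric(mean_amp[subj$subject]),
    stringsAsFactors = FALSE)

  measures <- c("fixations_per_trial", "fixation_duration_ms",
                "saccade_amplitude_deg")
  summ <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(c("young", "old"), function(gp) {
      v <- per_subject[[m]][per_subject$age_group == gp]
      data.frame(measure = m, age_group = gp, mean = mean(v), sd = sd(v),
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(measures, function(m) {
    y <- per_subject[[m]][per_subject$age_group == "young"]
    o <- per_subject[[m]][per_subject$age_group == "old"]
    tt <- welch_t(y, o)
    data.frame(measure = m, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  list(per_subject = per_subject, summary = summ, tests = tests)
}

welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("Welch t-test needs at least two observations per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    stop("degenerate variances: Welch df undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Mean inter-object distance per scene
#'
#' For k objects in a scene there are k(k-1)/2 unique Euclidean distances
#' between box centres; scenes with fewer than two objects are omitted with a
#' notice.
#'
#' @param annotations annotation data frame (`scene`, `object_id`, `x_min`,
#'   `y_min`, `width`, `height`).
#' @return Data frame with `scene`, `k` and `mean_distance_px`.
#' @export
inter_object_distances <- function(annotations) {
  out <- lapply(split(annotations, annotations$scene), function(an) {
    k <- nrow(an)
    if (k < 2) {
      message("scene ", an$scene[1], " has fewer than 2 objects; omitted")
      return(NULL)
    }
    cx <- region_centre(an$x_min, an$width)
    cy <- region_centre(an$y_min, an$height)
    d <- stats::dist(cbind(cx, cy))
    data.frame(scene = an$scene[1], k = k, mean_distance_px = mean(d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Object versus scene salience summaries
#'
#' Under a unit-integral map the scene-mean salience is `1 / (width *
#' height)`. Reports (a) how many objects' box-mean salience exceeds the
#' scene mean, (b) how many scenes have their global salience maximum inside
#' at least one annotated box, and (c) a one-sample t-test of the object
#' means against the scene mean.
#'
#' @param annotations annotation data frame across scenes.
#' @param salience_maps named list (by scene) of unit-integral matrices.
#' @param geometry a [scene_geometry()] or list of them.
#' @return A list with `object_means`, `n_above`/`frac_above`,
#'   `n_max_in_object`/`frac_max_in_object`, and `t_test`.
#' @export
salience_summaries <- function(annotations, salience_maps, geometry) {
  g1 <- geometry_list(geometry)[[1]]
  scene_mean <- 1 / (as.numeric(g1$width_px) * g1$height_px)
  scenes <- unique(annotations$scene)
  obj_means <- numeric(0)
  max_in_obj <- logical(length(scenes))
  for (si in seq_along(scenes)) {
    sc <- scenes[si]
    an <- annotations[annotations$scene == sc, ]
    map <- salience_maps[[sc]]
    obj_means <- c(obj_means, region_salience(map, within_region_frame(an)))
    amax <- arrayInd(which.max(map), dim(map))
    mx <- amax[2] - 1L; my <- amax[1] - 1L
    max_in_obj[si] <- any(mx >= an$x_min & mx <= an$x_min + an$width - 1 &
                            my >= an$y_min & my <= an$y_min + an$height - 1)
  }
  tt <- if (sd(obj_means) > 0) {
    t0 <- stats::t.test(obj_means, mu = scene_mean)
    list(statistic = t0$statistic, parameter = t0$parameter, p.value = t0$p.value)
  } else list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  list(object_means = obj_means,
       scene_mean = scene_mean,
       n_above = sum(obj_means > scene_mean),
       frac_above = mean(obj_means > scene_mean),
       n_max_in_object = sum(max_in_obj),
       frac_max_in_object = mean(max_in_obj),
       t_test = list(t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value))
}

# annotation table -> minimal region frame for region_salience()
within_region_frame <- function(an) {
  data.frame(region_id = an$object_id, x_min = an$x_min, y_min = an$y_min,
             width = an$width, height = an$height, stringsAsFactors = FALSE)
}
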