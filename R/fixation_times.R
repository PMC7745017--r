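#' First-pass visits to objects
#'
#' Segments each trial's scanpath into object visits and extracts, per
#' subject x object, the first visit: the first maximal run of consecutive
#' fixations inside the object's box that was entered from outside. The
#' fixation preceding the entry is the launch site. Visits whose entry is the
#' trial's initial central fixation are flagged `coincident` (the emulated
#' study excluded such cases from all object-based analyses); visits that
#' contain the trial's last fixation are flagged `includes_last` (excluded
#' from fixation-time analyses, where the last fixation's duration is
#' unavailable, but retained for landing-position analyses).
#'
#' @inheritParams build_object_observation_matrix
#' @return Data frame with one row per first visit: identifiers, entry/exit
#'   fixation indices, launch and landing coordinates, `first_fix_ms`,
#'   `gaze_ms`, and the exclusion flags.
#' @export
first_visits <- function(report, region_sets) {
  stopifnot(inherits(report, "fixation_report"))
  df <- as.data.frame(report)
  key <- paste(df$subject, df$scene, sep = "\r")
  out <- vector("list", 256L); n_out <- 0L
  for (trial in split(df, key)) {
    rs <- region_sets[[trial$scene[1]]]
    if (is.null(rs) || !nrow(rs)) next
    hits <- object_hits(trial$x_px, trial$y_px, rs)
    n_fix <- nrow(trial)
    for (j in which(colSums(hits) > 0)) {
      inb <- hits[, j]
      i0 <- which(inb)[1]
      j0 <- i0
      while (j0 < n_fix && inb[j0 + 1]) j0 <- j0 + 1
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- data.frame(
        subject = trial$subject[1], age_group = trial$age_group[1],
        scene = trial$scene[1], object_id = rs$region_id[j],
        entry_index = i0, exit_index = j0,
        launch_x = if (i0 > 1) trial$x_px[i0 - 1] else NA_real_,
        launch_y = if (i0 > 1) trial$y_px[i0 - 1] else NA_real_,
        landing_x = trial$x_px[i0], landing_y = trial$y_px[i0],
        first_fix_ms = trial$duration_ms[i0],
        gaze_ms = sum(trial$duration_ms[i0:j0]),
        coincident = i0 == 1L,
        includes_last = j0 == n_fix,
        stringsAsFactors = FALSE)
    }
  }
  if (n_out == 0L)
    return(data.frame(subject = character(0), age_group = character(0),
                      scene = character(0), object_id = character(0),
                      entry_index = integer(0), exit_index = integer(0),
                      launch_x = numeric(0), launch_y = numeric(0),
                      landing_x = numeric(0), landing_y = numeric(0),
                      first_fix_ms = numeric(0), gaze_ms = numeric(0),
                      coincident = logical(0), includes_last = logical(0)))
  res <- do.call(rbind, out[seq_len(n_out)])
  rownames(res) <- NULL
  res
}

#' Object-based fixation times
#'
#' First-fixation duration (duration of the initial fixation of the first
#' visit) and first-pass gaze duration (summed durations from first entry to
#' first exit, including immediate refixations) per fixated object. Visits
#' containing the trial's last fixation and visits whose entry coincided with
#' the initial central fixation are excluded; the counts are reported as
#' attributes `n_last_excluded` and `n_coincident_excluded`.
#'
#' @inheritParams build_object_observation_matrix
#' @return Data frame with one row per analysable first visit; `gaze_ms >=
#'   first_fix_ms > 0` always holds.
#' @export
object_fixation_times <- function(report, region_sets) {
  fv <- first_visits(report, region_sets)
  keep <- !fv$coincident & !fv$includes_last
  res <- fv[keep, c("subject", "age_group", "scene", "object_id",
                    "entry_index", "first_fix_ms", "gaze_ms",
                    "launch_x", "launch_y")]
  rownames(res) <- NULL
  structure(res,
            n_coincident_excluded = sum(fv$coincident),
            n_last_excluded = sum(fv$includes_last & !fv$coincident))
}
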