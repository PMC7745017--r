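test_that("fixation reports round-trip through CSV with exclusion flags", {
  ds <- tiny_dataset()
  p <- withr::local_tempfile(fileext = ".csv")
  write_fixation_report(ds$fixation_report, p)
  r2 <- load_fixation_report(p)
  cols <- c("subject", "scene", "fix_index", "x_px", "y_px", "duration_ms")
  expect_equal(as.data.frame(ds$fixation_report)[, cols],
               as.data.frame(r2)[, cols])
  # flags: first fixation excluded everywhere, last kept for position only
  expect_true(all(!r2$include_position[r2$is_initial]))
  expect_true(all(!r2$include_duration[r2$is_initial | r2$is_last]))
  expect_true(all(r2$include_position[r2$is_last & !r2$is_initial]))
})

test_that("degenerate reports load cleanly", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject,age_group,scene,trial_index,fix_index,x_px,y_px,duration_ms", p)
  r <- load_fixation_report(p)
  expect_equal(nrow(r), 0)
  expect_equal(n_trials(r), 0)
  # a one-fixation trial has zero analysable fixations
  writeLines(c("subject,age_group,scene,trial_index,fix_index,x_px,y_px,duration_ms",
               "S1,young,sc1,1,1,400,300,250"), p)
  r1 <- load_fixation_report(p)
  expect_equal(sum(r1$include_position), 0)
  # malformed rows error with position information
  writeLines(c("subject,age_group,scene,trial_index,fix_index,x_px,y_px,duration_ms",
               "S1,young,sc1,1,1,400,oops,250"), p)
  expect_error(load_fixation_report(p), "y_px")
})

test_that("out-of-bounds fixations warn and stay unassigned", {
  g <- scene_geometry("sc1", 800, 600)
  df <- data.frame(subject = "S1", age_group = "young", scene = "sc1",
                   trial_index = 1, fix_index = 1:3,
                   x_px = c(400, 900, 100), y_px = c(300, 300, 50),
                   duration_ms = 200)
  expect_warning(r <- as_fixation_report(df, geometry = g), "outside")
  rs <- make_grid(g, 8, 6)
  ids <- assign_fixation_to_regions(r$x_px, r$y_px, rs)
  expect_true(is.na(ids[2]))
})

test_that("fixations inside overlapping boxes credit every containing object", {
  g <- scene_geometry("sc1", 800, 600)
  an <- data.frame(object_id = c("a", "b"), x_min = c(100, 140),
                   y_min = c(100, 100), width = c(60, 60), height = c(60, 60))
  rs <- regions_from_objects(g, an)
  hits <- assign_fixation_to_regions(150, 120, rs)
  expect_setequal(hits[[1]], c("a", "b"))
  expect_length(assign_fixation_to_regions(700, 500, rs)[[1]], 0)
})

test_that("grid observation matrix row counts follow the closed-form rule", {
  # two subjects, three scenes, 2x2 grid, no missing trials -> 6 * 3 = 18 rows
  set.seed(21)
  mk_trial <- function(s, sc) data.frame(
    subject = s, age_group = ifelse(s == "S1", "young", "old"), scene = sc,
    trial_index = 1, fix_index = 1:4,
    x_px = c(100, runif(3, 0, 199)), y_px = c(75, runif(3, 0, 149)),
    duration_ms = 200)
  df <- do.call(rbind, lapply(c("S1", "S2"), function(s)
    do.call(rbind, lapply(c("a", "b", "c"), function(sc) mk_trial(s, sc)))))
  rep2 <- as_fixation_report(df)
  uni <- matrix(1 / (200 * 150), 150, 200)
  grids <- lapply(c(a = "a", b = "b", c = "c"), function(sc) {
    rs <- make_grid(scene_geometry(sc, 200, 150), 2, 2, salience_map = uni)
    rs$raw_salience <- rs$raw_salience * c(0.9, 1.1, 1.05, 0.95) # break constancy
    rs
  })
  om <- build_grid_observation_matrix(rep2, grids,
                                      standardize_predictors = FALSE)
  expect_equal(nrow(om), 18)
  expect_equal(nrow(om), brute_grid_rows(rep2, 4))
  expect_true(all(om$fixated %in% c(0, 1)))
  # the initial fixation's cell is dropped per trial
  expect_false(any(paste(om$subject, om$scene) == "S1 a" &
                     om$region_id == assign_fixation_to_regions(100, 75, grids$a)))
})

test_that("trials fixating only the excluded cell yield all-zero rows", {
  uni <- matrix(1 / (200 * 150), 150, 200)
  df <- data.frame(subject = "S1", age_group = "young", scene = "a",
                   trial_index = 1, fix_index = 1:3,
                   x_px = c(40, 60, 55), y_px = c(30, 45, 50),
                   duration_ms = 200)
  rep1 <- as_fixation_report(df)
  rs <- make_grid(scene_geometry("a", 200, 150), 2, 2, salience_map = uni)
  rs$raw_salience <- rs$raw_salience * c(0.9, 1.1, 1.05, 0.95)
  om <- build_grid_observation_matrix(rep1, list(a = rs),
                                      standardize_predictors = FALSE)
  expect_equal(nrow(om), 3)
  expect_true(all(om$fixated == 0))
})

test_that("row-count formulas hold for random small configurations", {
  set.seed(31)
  for (i in 1:4) {
    cfg <- tiny_config(n_subjects_young = sample(2:4, 1),
                       n_subjects_old = sample(2:4, 1),
                       n_scenes = sample(3:5, 1),
                       n_missing_trials = sample(0:2, 1),
                       seed = 100 + i)
    ds <- generate_dataset(cfg)
    grids <- region_sets_for(ds, "grid", cfg$grid_cols, cfg$grid_rows)
    om <- build_grid_observation_matrix(ds$fixation_report, grids)
    n_cells <- cfg$grid_cols * cfg$grid_rows
    expect_equal(nrow(om), brute_grid_rows(ds$fixation_report, n_cells))
    objs <- region_sets_for(ds, "object")
    oo <- build_object_observation_matrix(ds$fixation_report, objs)
    # subjects x objects, minus objects of each subject's missing scenes
    n_sub <- cfg$n_subjects_young + cfg$n_subjects_old
    per_scene <- table(ds$annotations$scene)
    all_keys <- expand.grid(s = unique(ds$fixation_report$subject),
                            sc = names(per_scene))
    present <- paste(ds$fixation_report$subject, ds$fixation_report$scene)
    miss <- !(paste(all_keys$s, all_keys$sc) %in% present)
    expect_equal(nrow(oo),
                 n_sub * nrow(ds$annotations) -
                   sum(per_scene[as.character(all_keys$sc[miss])]))
    # any trial with an analysable fixation outside the excluded cell fixates
    # at least one of its rows
    agg <- tapply(om$fixated, paste(om$subject, om$scene), sum)
    fr <- ds$fixation_report
    init_cell <- character(0)
    for (sc in unique(fr$scene)) {
      rows <- fr$scene == sc
      fr$cell[rows] <- assign_fixation_to_regions(fr$x_px[rows], fr$y_px[rows],
                                                  grids[[sc]])
    }
    ini <- fr[fr$is_initial, ]
    ikey <- setNames(ini$cell, paste(ini$subject, ini$scene))
    pos <- fr[fr$include_position, ]
    has_outside <- tapply(pos$cell != ikey[paste(pos$subject, pos$scene)],
                          paste(pos$subject, pos$scene), any)
    expect_true(all(agg[names(has_outside)[has_outside]] >= 1))
  }
})

test_that("objects never fixated keep all-zero rows and matrices rebuild identically", {
  ds <- tiny_dataset()
  objs <- tiny_object_sets(ds)
  oo1 <- build_object_observation_matrix(ds$fixation_report, objs)
  oo2 <- build_object_observation_matrix(ds$fixation_report, objs)
  expect_identical(as.data.frame(oo1), as.data.frame(oo2))
  unfixated <- tapply(oo1$fixated, oo1$region_id, sum) == 0
  expect_true(any(unfixated))  # with ~30 objects and 6 subjects some are never hit
  expect_true(all(names(unfixated) %in% oo1$region_id))
})

test_that("first-pass gaze measures match a direct scan oracle", {
  # constructed example: run of 200 + 250 ms then exit
  df <- data.frame(subject = "S1", age_group = "young", scene = "a",
                   trial_index = 1, fix_index = 1:6,
                   x_px = c(100, 20, 25, 28, 150, 22),
                   y_px = c(75, 20, 22, 21, 100, 20),
                   duration_ms = c(111, 200, 250, 230, 140, 300))
  rep1 <- as_fixation_report(df)
  g <- scene_geometry("a", 200, 150)
  rs <- regions_from_objects(g, data.frame(object_id = "o1", x_min = 10,
                                           y_min = 10, width = 30, height = 30))
  ft <- object_fixation_times(rep1, list(a = rs))
  expect_equal(ft$first_fix_ms, 200)
  expect_equal(ft$gaze_ms, 200 + 250 + 230)
  expect_equal(ft$entry_index, 2)
  expect_equal(ft$launch_x, 100)
  # single-fixation visit: gaze equals first-fixation duration
  df2 <- df; df2$x_px <- c(100, 20, 150, 150, 150, 150)
  ft2 <- object_fixation_times(as_fixation_report(df2), list(a = rs))
  expect_equal(ft2$first_fix_ms, ft2$gaze_ms)
  # a visit containing the trial's last fixation is excluded
  df3 <- df; df3$x_px <- c(100, 150, 150, 150, 20, 25)
  ft3 <- object_fixation_times(as_fixation_report(df3), list(a = rs))
  expect_equal(nrow(ft3), 0)
  expect_equal(attr(ft3, "n_last_excluded"), 1)
})

test_that("gaze durations agree with the brute-force oracle on random scanpaths", {
  set.seed(41)
  g <- scene_geometry("a", 200, 150)
  box <- c(40, 40, 50, 40)
  rs <- regions_from_objects(g, data.frame(object_id = "o1", x_min = box[1],
                                           y_min = box[2], width = box[3],
                                           height = box[4]))
  for (i in 1:25) {
    nf <- sample(4:12, 1)
    df <- data.frame(subject = "S1", age_group = "young", scene = "a",
                     trial_index = 1, fix_index = seq_len(nf),
                     x_px = c(100, runif(nf - 1, 0, 199)),
                     y_px = c(75, runif(nf - 1, 0, 149)),
                     duration_ms = round(runif(nf, 100, 400)))
    rep1 <- as_fixation_report(df)
    oracle <- brute_gaze(df$x_px, df$y_px, df$duration_ms, box)
    ft <- object_fixation_times(rep1, list(a = rs))
    if (is.null(oracle) || oracle$includes_last || oracle$entry == 1) {
      expect_equal(nrow(ft), 0)
    } else {
      expect_equal(ft$first_fix_ms, oracle$first)
      expect_equal(ft$gaze_ms, oracle$gaze)
    }
  }
})

test_that("descriptives compute amplitudes in degrees and Welch tests", {
  ppd <- 31.03
  g <- scene_geometry("a", 800, 600, px_per_degree = ppd)
  df <- data.frame(subject = rep(c("S1", "S2", "S3", "S4"), each = 3),
                   age_group = rep(c("young", "old"), each = 6),
                   scene = "a", trial_index = 1, fix_index = rep(1:3, 4),
                   x_px = rep(c(0, ppd * 3, ppd * 6), 4), y_px = 0,
                   duration_ms = rep(c(200, 220, 240), 4))
  d <- descriptive_stats(as_fixation_report(df), g)
  expect_equal(d$per_subject$saccade_amplitude_deg, rep(3, 4))
  expect_equal(d$per_subject$fixation_duration_ms, rep(220, 4))
  # identical groups: Welch t = 0 (degenerate variance handled)
  expect_equal(d$tests$t[d$tests$measure == "saccade_amplitude_deg"], 0)
})

test_that("inter-object distances cover the k(k-1)/2 pairs", {
  an <- data.frame(scene = c("a", "a", "a", "b", "b", "c"),
                   object_id = paste0("o", 1:6),
                   x_min = c(0, 100, 0, 0, 300, 10),
                   y_min = c(0, 0, 100, 0, 0, 10),
                   width = 10, height = 10)
  expect_message(d <- inter_object_distances(an), "fewer than 2")
  expect_equal(nrow(d), 2)  # scene c omitted
  expect_equal(d$mean_distance_px[d$scene == "b"], 300)
  expect_equal(d$k[d$scene == "a"], 3)  # 3 objects -> 3 pairwise distances
})

test_that("salience summaries count objects above the scene mean and scene maxima", {
  g <- scene_geometry("a", 200, 150)
  geoms <- list(a = g, b = scene_geometry("b", 200, 150))
  uni <- matrix(1 / (200 * 150), 150, 200)
  an <- data.frame(scene = c("a", "b"), object_id = c("o1", "o2"),
                   x_min = 50, y_min = 50, width = 20, height = 20)
  # uniform maps: no object exceeds the scene mean (strict inequality fails)
  s_uni <- salience_summaries(an, list(a = uni, b = uni), geoms)
  expect_equal(s_uni$n_above, 0)
  # single blob centred on each object: max inside a box for 100% of scenes
  mk <- function() {
    set.seed(13)
    make_salience_map(g, data.frame(object_id = "o", x_min = 50, y_min = 50,
                                    width = 20, height = 20),
                      p_object_blob = 1, n_background_blobs = 0)
  }
  s_blob <- salience_summaries(an, list(a = mk(), b = mk()), geoms)
  expect_equal(s_blob$frac_max_in_object, 1)
  expect_equal(s_blob$n_above, 2)
  expect_equal(s_blob$scene_mean, 1 / 30000)
})
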