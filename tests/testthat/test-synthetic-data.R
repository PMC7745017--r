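test_that("generation is deterministic given the config seed", {
  cfg <- tiny_config()
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$salience_maps, d2$salience_maps)
  expect_identical(as.data.frame(d1$fixation_report),
                   as.data.frame(d2$fixation_report))
  expect_identical(d1$memory, d2$memory)
})

test_that("salience maps are unit-integral and fixations in bounds across seeds", {
  for (seed in 1:20) {
    cfg <- sim_config(n_subjects_young = 1L, n_subjects_old = 1L,
                      n_scenes = 1L, n_missing_trials = 0L,
                      image_width_px = 200L, image_height_px = 150L,
                      grid_cols = 4L, grid_rows = 3L,
                      objects_per_scene_mean = 4, seed = seed)
    ds <- generate_dataset(cfg)
    expect_equal(sum(ds$salience_maps[[1]]), 1, tolerance = 1e-9)
    fr <- ds$fixation_report
    g <- ds$geometry[[1]]
    expect_true(all(fr$x_px >= 0 & fr$x_px <= g$width_px - 1))
    expect_true(all(fr$y_px >= 0 & fr$y_px <= g$height_px - 1))
    expect_true(all(fr$duration_ms > 0))
    an <- ds$annotations
    expect_true(all(an$x_min >= 0 & an$x_min + an$width <= g$width_px))
    expect_true(all(an$y_min >= 0 & an$y_min + an$height <= g$height_px))
    # boxes never cross the vertical midline
    mid <- g$width_px / 2
    expect_true(all(an$x_min + an$width <= mid | an$x_min >= mid))
  }
})

test_that("object counts match the configured mean at corpus scale", {
  cfg <- sim_config(seed = 7)
  ss <- generate_scene_set(cfg)
  per_scene <- table(ss$annotations$scene)
  expect_true(all(per_scene >= 2))
  # mean within Poisson sampling error of 6.9 (3 SE of the mean of 150 draws)
  expect_lt(abs(mean(per_scene) - 6.9), 3 * sqrt(6.9 / 150) + 0.1)
})

test_that("a single object blob puts the salience maximum inside the box", {
  g <- scene_geometry("s1", 200, 150)
  box <- data.frame(object_id = "o1", x_min = 120, y_min = 40,
                    width = 30, height = 24)
  set.seed(5)
  m <- make_salience_map(g, box, p_object_blob = 1, n_background_blobs = 0)
  expect_equal(sum(m), 1, tolerance = 1e-9)
  amax <- arrayInd(which.max(m), dim(m))
  x <- amax[2] - 1; y <- amax[1] - 1
  expect_true(x >= 120 && x <= 149 && y >= 40 && y <= 63)
})

test_that("exactly the configured number of trials is missing", {
  cfg <- tiny_config()
  ds <- generate_dataset(cfg)
  n_expected <- 6 * 4 - cfg$n_missing_trials
  expect_equal(n_trials(ds$fixation_report), n_expected)
})

test_that("fixation counts and durations are calibrated", {
  cfg <- desk_config(n_scenes = 20L, n_subjects_young = 6L,
                     n_subjects_old = 6L, n_missing_trials = 0L, seed = 3)
  ds <- generate_dataset(cfg)
  d <- descriptive_stats(ds$fixation_report, ds$geometry)
  m <- mean(d$per_subject$fixations_per_trial)
  expect_lt(abs(m - 21.03) / 21.03, 0.10)
  # degenerate duration distribution
  cfg0 <- tiny_config(fixation_duration_log_mean = log(250),
                      fixation_duration_log_sd = 0)
  ds0 <- generate_dataset(cfg0)
  expect_true(all(ds0$fixation_report$duration_ms == 250))
})

test_that("degenerate landing model puts every within-object landing at the box centre", {
  # controlled scene set: two well-separated objects, every saccade targets an
  # object, so every first-visit entry comes from the landing model
  cfg <- tiny_config(pvl_mean_offset = c(0, 0), pvl_sd = c(1e-12, 1e-12),
                     p_object_target = 1, n_scenes = 1L)
  g <- scene_geometry("scene_001", 800, 600)
  an <- data.frame(scene = "scene_001", object_id = c("o1", "o2"),
                   x_min = c(100, 600), y_min = c(100, 400),
                   width = c(40, 60), height = c(30, 44), label = "x")
  ss <- list(geometry = list(scene_001 = g), annotations = an,
             salience_maps = list(scene_001 = matrix(1 / 480000, 600, 800)))
  # beta without salience: uniform map has zero variance across two objects
  cfg$beta <- c("(Intercept)" = 0, size = 0.1)
  cfg$beta_age_delta <- c("(Intercept)" = 0)
  rep1 <- simulate_scanpaths(cfg, ss)
  objs <- list(scene_001 = regions_from_objects(g, an))
  pv <- pvl_table(rep1, objs)
  expect_gt(nrow(pv), 0)
  expect_equal(max(abs(pv$nx)), 0, tolerance = 1e-9)
  expect_equal(max(abs(pv$ny)), 0, tolerance = 1e-9)
})

test_that("indicator generator hits configured logit probabilities", {
  g <- scene_geometry("s1", 200, 150)
  set.seed(9)
  box <- data.frame(object_id = sprintf("o%02d", 1:30),
                    x_min = sample(0:150, 30), y_min = sample(0:100, 30),
                    width = 20, height = 20)
  m <- matrix(1 / (200 * 150), 150, 200)
  rs <- list(s1 = regions_from_objects(g, box, salience_map = NULL))
  rs$s1$raw_salience <- runif(30)
  # null model: everything at logit 0 -> proportion 0.5
  cfg0 <- tiny_config(beta = c("(Intercept)" = 0, salience = 0),
                      beta_age_delta = c("(Intercept)" = 0),
                      re_sd = c(subject = 0, scene = 0, object = 0),
                      n_subjects_young = 40L, n_subjects_old = 40L)
  ind0 <- simulate_fixation_indicators(cfg0, rs)
  expect_lt(abs(mean(ind0$fixated) - 0.5), 0.03)
  # the emulated intercept corresponds to probability 0.44
  cfg1 <- tiny_config(beta = c("(Intercept)" = -0.2278, salience = 0),
                      beta_age_delta = c("(Intercept)" = 0),
                      re_sd = c(subject = 0, scene = 0, object = 0),
                      n_subjects_young = 40L, n_subjects_old = 40L)
  ind1 <- simulate_fixation_indicators(cfg1, rs)
  expect_lt(abs(mean(ind1$fixated) - 0.4433), 0.03)
  # unknown predictor in beta is a configuration error
  cfgx <- tiny_config(beta = c("(Intercept)" = 0, clutter = 1))
  expect_error(simulate_fixation_indicators(cfgx, rs), "clutter")
})

test_that("a positive salience effect raises fixation rates in salient regions", {
  g <- scene_geometry("s1", 200, 150)
  set.seed(11)
  box <- data.frame(object_id = sprintf("o%02d", 1:40),
                    x_min = sample(0:150, 40), y_min = sample(0:100, 40),
                    width = 20, height = 20)
  rs <- list(s1 = regions_from_objects(g, box))
  rs$s1$raw_salience <- runif(40)
  top_q <- rs$s1$region_id[rs$s1$raw_salience >=
                             quantile(rs$s1$raw_salience, 0.75)]
  rates <- sapply(1:10, function(seed) {
    mk <- function(b) {
      cfg <- tiny_config(beta = c("(Intercept)" = 0, salience = b),
                        beta_age_delta = c("(Intercept)" = 0),
                        re_sd = c(subject = 0.1, scene = 0.1, object = 0),
                        n_subjects_young = 15L, n_subjects_old = 15L,
                        seed = seed)
      ind <- simulate_fixation_indicators(cfg, rs)
      mean(ind$fixated[ind$region_id %in% top_q])
    }
    c(with_effect = mk(0.38), without = mk(0))
  })
  expect_true(all(rates["with_effect", ] > rates["without", ]))
})

test_that("memory responses follow the configured rates", {
  # perfect subject: hit rate 1, false-alarm rate 0
  cfg <- tiny_config(memory_hit_rate = c(young = 1, old = 1),
                     memory_fa_rate = c(young = 0, old = 0))
  mem <- simulate_memory_responses(cfg)
  expect_true(all(mem$hits == 15 & mem$false_alarms == 0))
  expect_true(all(mem$misses == 0 & mem$correct_rejections == 15))
  # equal hit and false-alarm rates give d-prime centred on zero
  cfg2 <- sim_config(n_subjects_young = 150L, n_subjects_old = 150L,
                     memory_hit_rate = c(young = 0.6, old = 0.6),
                     memory_fa_rate = c(young = 0.6, old = 0.6), seed = 4)
  sc <- score_sdt(simulate_memory_responses(cfg2))
  expect_lt(abs(mean(sc$d_prime)), 0.05)
  # closed-form inversion: rates chosen so that d-prime = 1.5 is recovered
  zH <- 0.75; zF <- -0.75   # d' = zH - zF = 1.5
  cfg3 <- sim_config(n_subjects_young = 100L, n_subjects_old = 100L,
                     memory_hit_rate = c(young = pnorm(zH), old = pnorm(zH)),
                     memory_fa_rate = c(young = pnorm(zF), old = pnorm(zF)),
                     seed = 8)
  sc3 <- score_sdt(simulate_memory_responses(cfg3))
  expect_lt(abs(mean(sc3$d_prime) - 1.5), 0.1)
  # invalid rates are rejected
  expect_error(tiny_config(memory_hit_rate = c(young = 1.2, old = 0.5)),
               "rates")
})

test_that("configs round-trip through YAML", {
  cfg <- tiny_config()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, p)
  cfg2 <- read_sim_config(p)
  expect_equal(cfg[names(cfg)], cfg2[names(cfg)], tolerance = 1e-12)
})
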