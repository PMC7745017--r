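#!/usr/bin/env Rscript
# Basic scanning behaviour and stimulus descriptives: fixations per trial,
# fixation durations, saccade amplitudes (with Welch group tests), mean
# inter-object distances per scene, and object- vs scene-level salience
# summaries under the unit-integral map convention.

suppressPackageStartupMessages(library(scenefix))

dat <- "results/data"
config <- read_sim_config(file.path(dat, "config.yaml"))
annotations <- read_annotations(file.path(dat, "annotations.csv"))
scenes <- unique(annotations$scene)
geometry <- setNames(lapply(scenes, scene_geometry,
                            width_px = config$image_width_px,
                            height_px = config$image_height_px), scenes)
maps <- setNames(lapply(scenes, function(sc)
  read_salience_map(file.path(dat, "maps", paste0(sc, ".txt")))), scenes)
report <- load_fixation_report(file.path(dat, "fixations.csv"), geometry)

d <- descriptive_stats(report, geometry)
print(d$summary, digits = 4)
print(d$tests, digits = 3)

iod <- inter_object_distances(annotations)
message(sprintf("mean inter-object distance: %.0f px (range %.0f-%.0f across %d scenes)",
                mean(iod$mean_distance_px), min(iod$mean_distance_px),
                max(iod$mean_distance_px), nrow(iod)))

sal <- salience_summaries(annotations, maps, geometry)
message(sprintf("objects above scene-mean salience: %d of %d (%.0f%%)",
                sal$n_above, length(sal$object_means), 100 * sal$frac_above))
message(sprintf("scene salience maximum inside an object box: %d of %d scenes (%.0f%%)",
                sal$n_max_in_object, length(scenes), 100 * sal$frac_max_in_object))
message(sprintf("object vs scene mean salience: t(%.0f) = %.2f", sal$t_test$df,
                sal$t_test$t))

dir.create("results", showWarnings = FALSE)
write.csv(d$summary, "results/descriptives_summary.csv", row.names = FALSE)
write.csv(d$tests, "results/descriptives_tests.csv", row.names = FALSE)
write.csv(iod, "results/inter_object_distances.csv", row.names = FALSE)
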