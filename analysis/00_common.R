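# Shared loader for the analysis steps: reads the corpus written by
# 01_simulate.R back from disk (nothing below depends on in-memory state).

suppressPackageStartupMessages(library(scenefix))

load_corpus <- function(dat = "results/data") {
  config <- read_sim_config(file.path(dat, "config.yaml"))
  annotations <- read_annotations(file.path(dat, "annotations.csv"))
  scenes <- unique(annotations$scene)
  geometry <- setNames(lapply(scenes, scene_geometry,
                              width_px = config$image_width_px,
                              height_px = config$image_height_px), scenes)
  maps <- setNames(lapply(scenes, function(sc)
    read_salience_map(file.path(dat, "maps", paste0(sc, ".txt")))), scenes)
  list(config = config, annotations = annotations, geometry = geometry,
       salience_maps = maps,
       fixation_report = load_fixation_report(file.path(dat, "fixations.csv"),
                                              geometry),
       memory = read.csv(file.path(dat, "memory.csv")))
}

write_fit_tables <- function(fit, style, prefix, derive_old = TRUE) {
  s <- summarize_fit(fit, style, derive_old = derive_old)
  write.csv(s$fixed, paste0("results/", prefix, "_fixed.csv"), row.names = FALSE)
  if (!is.null(s$random))
    write.csv(s$random, paste0("results/", prefix, "_random.csv"),
              row.names = FALSE)
  print(s$fixed, digits = 4)
  invisible(s)
}
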