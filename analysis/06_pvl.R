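#!/usr/bin/env Rscript
# Preferred viewing location: normalized landing positions of initial
# first-pass fixations within objects (launch-relative sign, so negative
# values are undershoots of the object centre), summarized per age group and
# modelled with linear mixed models per axis.

source("analysis/00_common.R")
corpus <- load_corpus()

objects <- region_sets_for(corpus, "object")
pv <- pvl_table(corpus$fixation_report, objects)
message(sprintf("normalized landings: %d", nrow(pv)))
pv$z_size <- as.vector(scale(pv$raw_size))

summ <- pvl_summary(pv)
print(summ$group_stats, digits = 3)
write.csv(summ$group_stats, "results/pvl_group_stats.csv", row.names = FALSE)
for (gp in names(summ$density))
  write.table(summ$density[[gp]],
              sprintf("results/pvl_density_%s.txt", gp),
              row.names = FALSE, col.names = FALSE)

rand <- "(1 | subject) + (1 | object_id)"
message("fitting horizontal landing-position LMM ...")
fit_x <- fit_lmm(paste("nx ~ 1 + age + z_size + z_size:age +", rand), pv)
write_fit_tables(fit_x, "pvl", "pvl_horizontal")
message("fitting vertical landing-position LMM ...")
fit_y <- fit_lmm(paste("ny ~ 1 + age + z_size + z_size:age +", rand), pv)
write_fit_tables(fit_y, "pvl", "pvl_vertical")
message(sprintf("undershoot (young intercepts): horizontal %.4f, vertical %.4f",
                fit_x$fixed$b[1], fit_y$fixed$b[1]))
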