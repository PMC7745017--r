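#!/usr/bin/env Rscript
# Object-based fixation times: first-fixation duration and first-pass gaze
# duration (entry to exit, including immediate refixations) per first visit,
# log-transformed and modelled with the same fixed-effects structure as the
# object GLMM. Visits containing the trial's last fixation and
# initial-fixation coincidences are excluded.

source("analysis/00_common.R")
corpus <- load_corpus()

objects <- region_sets_for(corpus, "object")
ft <- object_fixation_times(corpus$fixation_report, objects)
message(sprintf("analysable first visits: %d (excluded: %d with last fixation, %d coincident)",
                nrow(ft), attr(ft, "n_last_excluded"),
                attr(ft, "n_coincident_excluded")))
ft <- attach_object_predictors(ft, objects)
ft$log_first_fix <- log(ft$first_fix_ms)
ft$log_gaze <- log(ft$gaze_ms)

fixed <- paste("1 + age + z_central_bias + z_central_bias:age + z_size +",
               "z_size:age + z_salience + z_salience:age")
rand <- "(1 | subject) + (1 | object_id) + (1 | scene)"

message("fitting first-fixation duration LMM (REML) ...")
fit_ff <- fit_lmm(paste("log_first_fix ~", fixed, "+", rand), ft)
write_fit_tables(fit_ff, "times", "times_first_fixation")
message(sprintf("intercept %.3f -> %.0f ms typical first fixation",
                fit_ff$fixed$b[1], exp(fit_ff$fixed$b[1])))

message("fitting gaze duration LMM (REML) ...")
fit_gz <- fit_lmm(paste("log_gaze ~", fixed, "+", rand), ft)
write_fit_tables(fit_gz, "times", "times_gaze")
message(sprintf("intercept %.3f -> %.0f ms typical first-pass gaze",
                fit_gz$fixed$b[1], exp(fit_gz$fixed$b[1])))
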