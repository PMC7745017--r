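#!/usr/bin/env Rscript
# Object-based fixation-probability analysis: one binary outcome per subject
# x annotated object, with central bias, log box area and box-mean salience
# as z-scored predictors, age-group interactions, a maximal by-subject random
# structure and random intercepts for objects (nested in scenes via globally
# unique ids) and scenes.

source("analysis/00_common.R")
corpus <- load_corpus()

objects <- region_sets_for(corpus, "object")
om <- build_object_observation_matrix(corpus$fixation_report, objects)
message(sprintf("object observation matrix: %d rows; %d initial-fixation coincidences",
                nrow(om), attr(om, "n_coincident")))

f <- paste("fixated ~ 1 + age + z_central_bias + z_central_bias:age +",
           "z_size + z_size:age + z_salience + z_salience:age +",
           "(1 + z_central_bias + z_size + z_salience | subject) +",
           "(1 | region_id) + (1 | scene)")
message("fitting object GLMM (Laplace) ...")
fit <- fit_binomial_glmm(f, om, refine = FALSE)
print(fit)
s <- write_fit_tables(fit, "object", "object_glmm")

b <- fit$fixed$b
message(sprintf("fixation probability: young %.2f, old %.2f",
                inverse_logit(b[1]), inverse_logit(b[1] + b[2])))
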