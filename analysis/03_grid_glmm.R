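#!/usr/bin/env Rscript
# Grid-based fixation-probability analysis: an 8 x 6 parcellation of every
# scene, one binary outcome per trial x cell (the initially fixated cell is
# dropped per trial), and a binomial logit mixed model with age-group
# interactions and the maximal by-subject / by-scene random structure for
# central bias and salience.

source("analysis/00_common.R")
corpus <- load_corpus()

grids <- region_sets_for(corpus, "grid", corpus$config$grid_cols,
                         corpus$config$grid_rows)
om <- build_grid_observation_matrix(corpus$fixation_report, grids)
message(sprintf("grid observation matrix: %d rows (%d trials x %d cells)",
                nrow(om), attr(om, "n_trials"),
                corpus$config$grid_cols * corpus$config$grid_rows - 1))

f <- paste("fixated ~ 1 + age + z_central_bias + z_central_bias:age +",
           "z_salience + z_salience:age +",
           "(1 + z_central_bias + z_salience | subject) +",
           "(1 + z_central_bias + z_salience | scene)")
message("fitting grid GLMM (Laplace) ...")
fit <- fit_binomial_glmm(f, om, refine = FALSE)
print(fit)
s <- write_fit_tables(fit, "grid", "grid_glmm")

b0 <- fit$fixed$b[fit$fixed$term == "(Intercept)"]
message(sprintf("overall fixation probability per cell (young): %.3f",
                inverse_logit(b0)))
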