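#!/usr/bin/env Rscript
# Memory-test performance: per-subject sensitivity (d') and criterion (c)
# with the log-linear correction applied to all subjects, and Welch t-tests
# between age groups.

source("analysis/00_common.R")
corpus <- load_corpus()

scored <- score_sdt(corpus$memory)
comp <- sdt_group_compare(scored)
print(comp, digits = 3)
write.csv(scored, "results/sdt_subjects.csv", row.names = FALSE)
write.csv(comp, "results/sdt_tests.csv", row.names = FALSE)

message(sprintf("d': young %.2f (SD %.2f), old %.2f (SD %.2f), t(%.1f) = %.2f, p = %.3f",
                comp$mean_young[1], comp$sd_young[1], comp$mean_old[1],
                comp$sd_old[1], comp$df[1], comp$t[1], comp$p[1]))
message(sprintf("criterion c: young %.2f, old %.2f, t(%.1f) = %.2f, p = %.3f",
                comp$mean_young[2], comp$mean_old[2], comp$df[2], comp$t[2],
                comp$p[2]))
message(if (all(scored$criterion_c > -0.5)) "criteria are mostly conservative (c > 0 for most subjects)" else "")
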