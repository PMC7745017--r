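#' Signal detection measures with the log-linear correction
#'
#' Hit and false-alarm rates are computed with the log-linear correction
#' (0.5 added to each count, 1 to each trial total), applied uniformly to all
#' subjects, which keeps the corrected rates strictly inside (0, 1) and d'
#' finite even for perfect performance:
#' `H = (hits + 0.5) / (signal + 1)`, `F = (fa + 0.5) / (noise + 1)`,
#' `d' = qnorm(H) - qnorm(F)`, `c = -(qnorm(H) + qnorm(F)) / 2`. A positive
#' criterion c indicates a conservative tendency to classify present items as
#' absent.
#'
#' @param counts data frame with columns `hits`, `misses`, `false_alarms`,
#'   `correct_rejections` (and optionally `subject`, `age_group`, carried
#'   through).
#' @return The input with added columns `H`, `F`, `d_prime`, `criterion_c`.
#' @export
score_sdt <- function(counts) {
  required <- c("hits", "misses", "false_alarms", "correct_rejections")
  miss <- setdiff(required, names(counts))
  if (length(miss)) stop("counts table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(counts[required] < 0)) stop("counts must be non-negative")
  n_signal <- counts$hits + counts$misses
  n_noise <- counts$false_alarms + counts$correct_rejections
  if (any(n_signal < 1) || any(n_noise < 1))
    stop("each subject needs at least one signal and one noise trial")
  H <- (counts$hits + 0.5) / (n_signal + 1)
  F <- (counts$false_alarms + 0.5) / (n_noise + 1)
  counts$H <- H
  counts$F <- F
  counts$d_prime <- qnorm(H) - qnorm(F)
  counts$criterion_c <- -(qnorm(H) + qnorm(F)) / 2
  counts
}

#' Compare signal detection measures between age groups
#'
#' Welch unequal-variance two-sample t-tests (fractional degrees of freedom,
#' two-sided p) on d' and criterion c.
#'
#' @param results output of [score_sdt()] with an `age_group` column.
#' @return Data frame with one row per measure: group means/SDs, t, df, p.
#' @export
sdt_group_compare <- function(results) {
  if (is.null(results$age_group)) stop("results need an 'age_group' column")
  groups <- split(results, results$age_group)
  if (length(groups) < 2L) stop("need two age groups")
  if (any(vapply(groups, nrow, 1L) < 2L))
    stop("need at least two subjects per group")
  one <- function(measure) {
    y <- groups$young[[measure]]; o <- groups$old[[measure]]
    tt <- welch_t(y, o)
    data.frame(measure = measure,
               mean_young = mean(y), sd_young = sd(y), n_young = length(y),
               mean_old = mean(o), sd_old = sd(o), n_old = length(o),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  rbind(one("d_prime"), one("criterion_c"))
}

#' Simulate memory-test responses
#'
#' Per subject, `n_memory_trials / 2` signal (object present) and the same
#' number of noise trials; hits and false alarms are Bernoulli draws at the
#' configured per-group rates. The default rates invert the emulated study's
#' printed group d' and criterion values through the closed-form equal-
#' variance model.
#'
#' @param config a [sim_config()].
#' @param subjects optional subject table (`subject`, `age_group`); defaults
#'   to the configured group sizes.
#' @return SDT counts data frame suitable for [score_sdt()].
#' @export
simulate_memory_responses <- function(config, subjects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(subjects)) subjects <- subject_table(config)
  set.seed(substream_seed(config$seed, "memory"))
  n_signal <- config$n_memory_trials %/% 2L
  n_noise <- config$n_memory_trials - n_signal
  hr <- config$memory_hit_rate[subjects$age_group]
  fr <- config$memory_fa_rate[subjects$age_group]
  hits <- rbinom(nrow(subjects), n_signal, hr)
  fas <- rbinom(nrow(subjects), n_noise, fr)
  data.frame(subject = subjects$subject, age_group = subjects$age_group,
             hits = hits, misses = n_signal - hits,
             false_alarms = fas, correct_rejections = n_noise - fas,
             stringsAsFactors = FALSE)
}

subject_table <- function(config) {
  n <- config$n_subjects_young + config$n_subjects_old
  data.frame(
    subject = sprintf("S%03d", seq_len(n)),
    age_group = rep(c("young", "old"),
                    c(config$n_subjects_young, config$n_subjects_old)),
    stringsAsFactors = FALSE)
}
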