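make_binary_data <- function(n = 400, seed = 1) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n),
                  age_group = sample(c("young", "old"), n, TRUE),
                  g = sample(sprintf("g%02d", 1:12), n, TRUE))
  eta <- -0.3 + 0.5 * d$x + 0.4 * (d$age_group == "old")
  d$y <- rbinom(n, 1, plogis(eta))
  d
}

test_that("design construction applies treatment coding with young as reference", {
  d <- data.frame(y = c(0, 1), age_group = c("young", "old"),
                  z_salience = c(0.7, -1.2), subject = c("a", "b"),
                  scene = c("s", "s2"))
  des <- build_design("y ~ 1 + age + z_salience + z_salience:age + (1 | subject)", d)
  expect_equal(colnames(des$X),
               c("(Intercept)", "age", "z_salience", "z_salience:age"))
  expect_equal(des$X[1, ], c("(Intercept)" = 1, age = 0, z_salience = 0.7,
                             "z_salience:age" = 0))  # young: age and interactions 0
  expect_equal(unname(des$X[2, "z_salience:age"]), -1.2) # old: interaction = z value
  # full fixation-probability fixed structure has six columns
  d2 <- data.frame(y = rbinom(20, 1, 0.5), age_group = rep(c("young", "old"), 10),
                   z_central_bias = rnorm(20), z_salience = rnorm(20),
                   subject = rep(letters[1:4], 5), scene = rep(LETTERS[1:5], 4))
  des2 <- build_design(paste(
    "y ~ 1 + age + z_central_bias + z_central_bias:age + z_salience +",
    "z_salience:age + (1 + z_central_bias + z_salience | subject) +",
    "(1 + z_central_bias + z_salience | scene)"), d2)
  expect_equal(ncol(des2$X), 6)
  expect_equal(length(des2$re), 2)
  expect_equal(des2$re[[1]]$k, 3)
  expect_error(build_design("y ~ 1 + z_missing + (1 | subject)", d), "z_missing")
  expect_error(build_design("y ~ 1 + (1 | cluster)", d), "cluster")
})

test_that("with no random terms the GLMM reduces exactly to logistic regression", {
  d <- make_binary_data()
  fit <- fit_binomial_glmm("y ~ 1 + age + x", d)
  gl <- glm(y ~ I(age_group == "old") + x, binomial, d)
  expect_lt(max(abs(fit$fixed$b - unname(coef(gl)))), 1e-6)
  expect_lt(max(abs(fit$fixed$se - unname(sqrt(diag(vcov(gl)))))), 1e-6)
  expect_lt(abs(fit$deviance - deviance(gl)), 1e-8)
  # Wald z and p are exact transforms of b and se
  expect_equal(fit$fixed$z, fit$fixed$b / fit$fixed$se)
  expect_equal(fit$fixed$p, 2 * (1 - pnorm(abs(fit$fixed$z))))
})

test_that("constraining the random-effect variance to zero recovers the GLM", {
  d <- make_binary_data()
  dev_at <- glmm_laplace_deviance("y ~ 1 + x + (1 | g)", d,
                                  beta = coef(glm(y ~ x, binomial, d)),
                                  theta = -20)  # sd = exp(-20), effectively 0
  expect_lt(abs(dev_at - deviance(glm(y ~ x, binomial, d))), 1e-6)
})

test_that("the Laplace objective matches adaptive Gauss-Hermite quadrature", {
  # scalar-random-intercept fixture, 20 clusters x 20 observations, in the
  # small-dispersion regime where the Laplace approximation coincides with
  # the exact likelihood: an implementation error (penalty, log-determinant,
  # mode search) would appear as an O(1) gap
  set.seed(19)
  ng <- 20; m <- 20
  g <- rep(sprintf("c%02d", 1:ng), each = m)
  x <- rnorm(ng * m)
  u <- rnorm(ng, 0, 0.1)
  y <- rbinom(ng * m, 1, plogis(0.2 + 0.4 * x + u[as.integer(factor(g))]))
  d <- data.frame(y = y, x = x, g = g)
  for (sg in c(0.05, 0.1)) {
    lap <- glmm_laplace_deviance("y ~ 1 + x + (1 | g)", d,
                                 beta = c(0.2, 0.4), theta = log(sg))
    agq <- agq_m2ll(0.2 + 0.4 * x, g, y, sg, order = 25)
    expect_lt(abs(lap - agq), 1e-3)
  }
})

test_that("GLMM estimates agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(11)
  ng <- 30; m <- 25
  g <- rep(sprintf("s%02d", 1:ng), each = m)
  x <- rnorm(ng * m)
  u <- rnorm(ng, 0, 0.8)
  y <- rbinom(ng * m, 1, plogis(-0.4 + 0.6 * x + u[as.integer(factor(g))]))
  d <- data.frame(y = y, x = x, g = g)
  fit <- fit_binomial_glmm("y ~ 1 + x + (1 | g)", d)
  fl <- lme4::glmer(y ~ x + (1 | g), d, binomial)
  expect_lt(max(abs(fit$fixed$b - unname(lme4::fixef(fl)))), 5e-3)
  expect_lt(abs(fit$ranef[[1]]$sd - sqrt(unlist(lme4::VarCorr(fl)))), 5e-3)
  expect_lt(abs(fit$deviance - (-2 * as.numeric(stats::logLik(fl)))), 0.01)
})

test_that("REML variance components equal closed-form ANOVA estimators", {
  set.seed(42)
  m <- 8; ng <- 15
  g <- rep(sprintf("g%02d", 1:ng), each = m)
  u <- rnorm(ng, 0, 2)
  y <- 5 + u[as.integer(factor(g))] + rnorm(ng * m, 0, 1.3)
  d <- data.frame(y = y, g = g)
  fit <- fit_lmm("y ~ 1 + (1 | g)", d)
  msa <- m * var(tapply(y, g, mean))
  mse <- sum((y - ave(y, g))^2) / (ng * (m - 1))
  expect_lt(abs(fit$ranef[[1]]$Sigma[1, 1] - (msa - mse) / m), 1e-8)
  expect_lt(abs(fit$sigma^2 - mse), 1e-8)
  expect_equal(fit$fixed$b[1], mean(tapply(y, g, mean)), tolerance = 1e-8)
})

test_that("LMM with correlated random slopes matches an independent fitter", {
  skip_if_not_installed("lme4")
  set.seed(7)
  ng <- 30; m <- 10
  g <- rep(sprintf("s%02d", 1:ng), each = m)
  x <- rnorm(ng * m)
  b0 <- rnorm(ng, 0, 1); b1 <- 0.4 * b0 + rnorm(ng, 0, sqrt(0.5 - 0.16))
  y <- 2 + 1.5 * x + b0[as.integer(factor(g))] + b1[as.integer(factor(g))] * x +
    rnorm(ng * m)
  d <- data.frame(y = y, x = x, g = g)
  fit <- fit_lmm("y ~ 1 + x + (1 + x | g)", d)
  fl <- lme4::lmer(y ~ x + (1 + x | g), d, REML = TRUE)
  expect_lt(max(abs(fit$fixed$b - unname(lme4::fixef(fl)))), 1e-5)
  expect_lt(max(abs(fit$fixed$se - unname(sqrt(diag(as.matrix(vcov(fl))))))), 1e-4)
  expect_lt(abs(fit$deviance - lme4::REMLcrit(fl)), 1e-6)
  vc <- as.data.frame(lme4::VarCorr(fl))
  expect_lt(abs(fit$ranef[[1]]$Sigma[1, 1] - vc$vcov[1]), 1e-4)
  expect_lt(abs(fit$ranef[[1]]$Sigma[2, 2] - vc$vcov[2]), 1e-4)
})

test_that("zero between-group variance flags a singular fit", {
  set.seed(5)
  d <- data.frame(y = rnorm(200), g = rep(sprintf("g%02d", 1:10), each = 20))
  fit <- fit_lmm("y ~ 1 + (1 | g)", d)
  expect_true(fit$singular)
  expect_lt(fit$ranef[[1]]$sd, 1e-3)
})

test_that("estimates are invariant to row permutation", {
  d <- make_binary_data(300, seed = 3)
  f <- "y ~ 1 + x + (1 | g)"
  fit1 <- fit_binomial_glmm(f, d)
  set.seed(4)
  fit2 <- fit_binomial_glmm(f, d[sample(nrow(d)), ])
  expect_lt(max(abs(fit1$fixed$b - fit2$fixed$b)), 1e-8)
  expect_lt(max(abs(fit1$theta - fit2$theta)), 1e-6)
})

test_that("the fitted deviance beats the generating parameters on simulated data", {
  set.seed(12)
  wins <- 0L
  for (i in 1:5) {
    ng <- 20; m <- 15
    g <- rep(sprintf("s%02d", 1:ng), each = m)
    x <- rnorm(ng * m)
    u <- rnorm(ng, 0, 0.5)
    y <- rbinom(ng * m, 1, plogis(0.3 * x + u[as.integer(factor(g))]))
    d <- data.frame(y = y, x = x, g = g)
    f <- "y ~ 1 + x + (1 | g)"
    fit <- fit_binomial_glmm(f, d)
    dev_true <- glmm_laplace_deviance(f, d, beta = c(0, 0.3), theta = log(0.5))
    if (fit$deviance <= dev_true + 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("stepwise reduction removes near-zero random terms", {
  set.seed(6)
  ng <- 20; m <- 12
  g <- rep(sprintf("s%02d", 1:ng), each = m)
  x <- rnorm(ng * m)
  u <- rnorm(ng, 0, 1)
  y <- 1 + x + u[as.integer(factor(g))] + rnorm(ng * m, 0, 1) # no slope variance
  d <- data.frame(y = y, x = x, g = g)
  # threshold chosen above the spurious slope SD this sample supports, so the
  # stepwise machinery has something to remove
  expect_message(fit <- fit_lmm("y ~ 1 + x + (1 + x | g)", d, reduce = TRUE,
                                control = mm_control(sd_tol = 0.15)),
                 "dropping random term")
  expect_equal(length(fit$ranef[[1]]$names), 1L)
  expect_equal(fit$ranef[[1]]$names, "(Intercept)")
})

test_that("report tables mirror the study layout including derived old coefficients", {
  d <- make_binary_data(500, seed = 8)
  d$z_x <- as.vector(scale(d$x))
  fit <- fit_binomial_glmm("y ~ 1 + age + z_x + z_x:age + (1 | g)", d)
  s <- summarize_fit(fit, "object", derive_old = TRUE)
  expect_true(all(c("young", "old-young") %in% s$fixed$description))
  derived <- s$fixed[s$fixed$description == "old (derived)" &
                       s$fixed$term == "(Intercept)", ]
  young <- s$fixed$b[s$fixed$term == "(Intercept)" &
                       s$fixed$description == "young"]
  delta <- s$fixed$b[s$fixed$term == "(Intercept)" &
                       s$fixed$description == "old-young"]
  expect_equal(derived$b, young + delta)
  expect_true("correlations" %in% names(s$random))
  # the derived-coefficient arithmetic of the emulated study
  expect_equal(-0.2278 + (-0.208), -0.4358)
})
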