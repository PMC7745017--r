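#' Mixed-model estimation core
#'
#' Binomial logit GLMMs are fitted by the Laplace approximation: an inner
#' penalized iteratively reweighted least squares (PIRLS) loop solves for the
#' conditional modes of the spherical random effects (and, while profiling,
#' the fixed effects), and an outer optimization runs over a log-Cholesky
#' parametrization of the relative covariance factors, guaranteeing positive
#' semi-definite covariance matrices. Linear mixed models are estimated by
#' the profiled REML criterion, with fixed effects and residual variance
#' profiled out in closed form per covariance parameter value. Sparse
#' random-effect structures use the Matrix package throughout. Wald standard
#' errors come from the fixed-effects block of the inverse observed
#' information, conditional on the covariance parameters; p-values (normal
#' approximation) are reported for GLMMs only, while LMM coefficients are
#' judged by the two-tailed |t| > 1.96 criterion.
#'
#' @name mixed_core
NULL

#' Control parameters for the mixed-model fitters
#'
#' @param pirls_maxit,pirls_tol inner-loop iteration cap and relative
#'   tolerance on the penalized deviance.
#' @param outer_maxit,outer_reltol outer optimization cap and relative
#'   convergence tolerance.
#' @param refine_maxit iteration cap of the joint (theta, beta) Laplace
#'   refinement of GLMM fits.
#' @param sd_tol random-effect standard deviations below `sd_tol` times the
#'   response scale flag the fit as singular.
#' @export
mm_control <- function(pirls_maxit = 50L, pirls_tol = 1e-10,
                       outer_maxit = 500L, outer_reltol = 1e-8,
                       refine_maxit = 100L, sd_tol = 1e-4) {
  list(pirls_maxit = pirls_maxit, pirls_tol = pirls_tol,
       outer_maxit = outer_maxit, outer_reltol = outer_reltol,
       refine_maxit = refine_maxit, sd_tol = sd_tol)
}

clamp_mu <- function(mu) pmin(pmax(mu, 1e-10), 1 - 1e-10)

binom_deviance <- function(y, mu) {
  mu <- clamp_mu(mu)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# stable Bernoulli deviance from the linear predictor:
# log L = y*eta - log(1 + exp(eta))
binom_deviance_eta <- function(y, eta) {
  -2 * (sum(y * eta) - sum(pmax(eta, 0)) - sum(log1p(exp(-abs(eta)))))
}

# scale the rows of a sparse matrix without a diagonal matmult
row_scale <- function(U, s) {
  U@x <- U@x * s[U@i + 1L]
  U
}

# One Laplace evaluation at (theta, beta); beta = NULL profiles the fixed
# effects inside the PIRLS loop. `state` is an environment carrying warm
# starts across calls.
glmm_laplace_eval <- function(design, theta, beta = NULL, state = new.env(),
                              control = mm_control()) {
  y <- design$y; X <- design$X; n <- design$n; p <- design$p
  lam <- if (design$q > 0L) lambda_from_theta(design, theta) else NULL
  U <- if (design$q > 0L) design$Z %*% lam$Lambda else NULL
  q <- design$q
  profiled <- is.null(beta)

  u <- if (!is.null(state$u) && length(state$u) == q) state$u else rep(0, q)
  b <- if (profiled) {
    if (!is.null(state$beta) && length(state$beta) == p) state$beta else rep(0, p)
  } else beta
  eta <- as.vector(X %*% b) + if (q > 0L) as.vector(U %*% u) else 0

  pdev_of <- function(eta, u) binom_deviance_eta(y, eta) + sum(u^2)
  pdev <- pdev_of(eta, u)
  H <- NULL
  for (iter in seq_len(control$pirls_maxit)) {
    mu <- clamp_mu(plogis(eta))
    W <- mu * (1 - mu)
    sW <- sqrt(W)
    zw <- eta + (y - mu) / W
    zs <- zw * sW
    Xs <- X * sW
    if (q > 0L) {
      Us <- row_scale(U, sW)
      H <- Matrix::crossprod(Us) + Matrix::Diagonal(q)
      ch <- chol_of(H, state)
      Utz <- Matrix::crossprod(Us, zs)
      if (profiled) {
        UtX <- Matrix::crossprod(Us, Xs)
        HiUX <- Matrix::solve(ch, UtX)
        S <- crossprod(Xs) - as.matrix(Matrix::crossprod(UtX, HiUX))
        cb <- crossprod(Xs, zs) - as.matrix(Matrix::crossprod(UtX, Matrix::solve(ch, Utz)))
        b_new <- solve(S, cb)[, 1]
        u_new <- as.vector(Matrix::solve(ch, Utz - UtX %*% b_new))
      } else {
        b_new <- b
        Xb <- Xs %*% b
        u_new <- as.vector(Matrix::solve(ch, Utz - Matrix::crossprod(Us, Xb)))
      }
    } else {
      S <- crossprod(Xs)
      b_new <- solve(S, crossprod(Xs, zs))[, 1]
      u_new <- u
    }
    eta_new <- as.vector(X %*% b_new) + if (q > 0L) as.vector(U %*% u_new) else 0
    # step-halving on the penalized deviance
    s <- 1
    repeat {
      eta_try <- eta + s * (eta_new - eta)
      u_try <- u + s * (u_new - u)
      pdev_try <- pdev_of(eta_try, u_try)
      if (pdev_try <= pdev + 1e-8 || s < 1e-4) break
      s <- s / 2
    }
    b <- b + s * (b_new - b)
    u <- u_try; eta <- eta_try
    done <- abs(pdev - pdev_try) < control$pirls_tol * (abs(pdev_try) + 1)
    pdev <- pdev_try
    if (done) break
  }
  mu <- clamp_mu(plogis(eta))
  W <- mu * (1 - mu)
  ldL2 <- 0
  if (q > 0L) {
    Us <- row_scale(U, sqrt(W))
    H <- Matrix::crossprod(Us) + Matrix::Diagonal(q)
    ldL2 <- as.numeric(Matrix::determinant(H, logarithm = TRUE)$modulus)
  }
  state$u <- u
  if (profiled) state$beta <- b
  dev <- binom_deviance_eta(y, eta) + sum(u^2) + ldL2
  list(dev = dev, beta = b, u = u, mu = mu, W = W, L = if (q > 0L) lam$L else list())
}

chol_of <- function(H, state) {
  if (is.null(state$chol_sym)) {
    state$chol_sym <- Matrix::Cholesky(H, LDL = FALSE)
  } else {
    state$chol_sym <- tryCatch(Matrix::update(state$chol_sym, H),
                               error = function(e) Matrix::Cholesky(H, LDL = FALSE))
  }
  state$chol_sym
}

# Wald covariance of the fixed effects at the converged fit (Schur complement
# of the random-effects block of the weighted information matrix).
glmm_beta_cov <- function(design, theta, W) {
  X <- design$X
  sW <- sqrt(W)
  Xs <- X * sW
  if (design$q == 0L) return(solve(crossprod(Xs)))
  lam <- lambda_from_theta(design, theta)
  Us <- Matrix::Diagonal(x = sW) %*% (design$Z %*% lam$Lambda)
  H <- Matrix::crossprod(Us) + Matrix::Diagonal(design$q)
  UtX <- Matrix::crossprod(Us, Xs)
  S <- crossprod(Xs) - as.matrix(Matrix::crossprod(UtX, Matrix::solve(H, UtX)))
  solve(S)
}

#' Fit a binomial logit GLMM by the Laplace approximation
#'
#' Maximizes the Laplace-approximated marginal likelihood over the fixed
#' effects and a log-Cholesky parametrization of the random-effect
#' covariances. The covariance parameters are first optimized with the fixed
#' effects profiled inside the PIRLS loop; with `refine = TRUE` (default) a
#' Newton polish of the fixed effects on the exact Laplace objective follows
#' at the optimized covariance parameters (profiling ignores the
#' log-determinant's dependence on the fixed effects; the polish removes that
#' discrepancy). Fits are deterministic given the data: starting values are the
#' null fixed-effects vector and unit random-effect standard deviations.
#'
#' @param formula model formula (see [parse_mm_formula()]).
#' @param data observation rows (e.g. an observation matrix).
#' @param refine run the joint Laplace refinement after the profiled stage.
#' @param control a [mm_control()] list.
#' @return An object of class `mm_fit` with elements `fixed` (term, b, se,
#'   z, p), `ranef` (per grouping factor: covariance matrix, SDs,
#'   correlations), `theta`, `deviance`, `logLik`, `converged`, `singular`.
#' @export
fit_binomial_glmm <- function(formula, data, refine = TRUE,
                              control = mm_control()) {
  design <- build_design(formula, data)
  if (!all(design$y %in% c(0, 1))) stop("binomial GLMM needs a 0/1 response")
  state <- new.env(parent = emptyenv())
  conv <- 0L
  if (design$q > 0L) {
    th0 <- theta_init(design)
    obj_prof <- function(th) glmm_laplace_eval(design, th, NULL, state, control)$dev
    opt1 <- if (length(th0) == 1L) {
      stats::optim(th0, obj_prof, method = "Brent", lower = -10, upper = 5)
    } else {
      stats::optim(th0, obj_prof, method = "Nelder-Mead",
                   control = list(maxit = control$outer_maxit,
                                  reltol = control$outer_reltol))
    }
    theta <- opt1$par
    conv <- opt1$convergence
    ev <- glmm_laplace_eval(design, theta, NULL, state, control)
    beta <- ev$beta
    if (refine) {
      # Newton polish of the fixed effects on the full Laplace objective at
      # the optimized covariance parameters. Profiling inside PIRLS ignores
      # the log-determinant's dependence on beta; the polish removes that
      # (small) discrepancy at the cost of a few gradient evaluations.
      p <- design$p
      F_of <- function(b) glmm_laplace_eval(design, theta, b, state, control)$dev
      f0 <- ev$dev
      for (step in seq_len(4L)) {
        Vb <- glmm_beta_cov(design, theta, ev$W)
        g <- numeric(p)
        for (i in seq_len(p)) {
          h <- 1e-4 * (1 + abs(beta[i]))
          ei <- replace(numeric(p), i, h)
          g[i] <- (F_of(beta + ei) - F_of(beta - ei)) / (2 * h)
        }
        delta <- as.vector(Vb %*% g) / 2
        if (max(abs(delta)) < 1e-8) break
        beta_new <- beta - delta
        f_new <- F_of(beta_new)
        if (!is.finite(f_new) || f_new > f0 + 1e-10) break
        beta <- beta_new
        ev <- glmm_laplace_eval(design, theta, beta, state, control)
        if (f0 - f_new < 1e-9 * (abs(f_new) + 1)) { f0 <- f_new; break }
        f0 <- f_new
      }
    }
  } else {
    theta <- numeric(0)
    ev <- glmm_laplace_eval(design, theta, NULL, state, control)
    beta <- ev$beta
  }
  Vb <- glmm_beta_cov(design, theta, ev$W)
  se <- sqrt(diag(Vb))
  z <- beta / se
  fixed <- data.frame(term = colnames(design$X), b = beta, se = se, z = z,
                      p = 2 * pnorm(-abs(z)), row.names = NULL,
                      stringsAsFactors = FALSE)
  ranef <- ranef_summary(design, ev$L, sigma = 1)
  singular <- any(unlist(lapply(ranef, function(r) r$sd)) < control$sd_tol)
  structure(list(family = "binomial", spec = design$spec, fixed = fixed,
                 ranef = ranef, theta = theta, deviance = ev$dev,
                 logLik = -ev$dev / 2, sigma = NA_real_,
                 converged = conv == 0L, singular = singular,
                 n = design$n, p = design$p, q = design$q,
                 vcov = Vb),
            class = "mm_fit")
}

ranef_summary <- function(design, Ls, sigma = 1) {
  out <- list()
  for (ti in seq_along(design$re)) {
    L <- Ls[[ti]]
    Sigma <- sigma^2 * (L %*% t(L))
    nm <- colnames(design$re[[ti]]$M)
    dimnames(Sigma) <- list(nm, nm)
    sds <- sqrt(diag(Sigma))
    corr <- if (length(sds) > 1L) Sigma / outer(sds, sds) else matrix(1, 1, 1)
    out[[ti]] <- list(group = design$re[[ti]]$group, names = nm,
                      Sigma = Sigma, sd = sds, corr = corr)
  }
  out
}

# ---------------------------------------------------------------------------
# Linear mixed models: profiled REML

lmm_profiled_eval <- function(pre, theta, REML = TRUE) {
  design <- pre$design
  n <- design$n; p <- design$p; q <- design$q
  if (q > 0L) {
    lam <- lambda_from_theta(design, theta)
    Lb <- lam$Lambda
    H <- Matrix::crossprod(Lb, pre$ZtZ %*% Lb) + Matrix::Diagonal(q)
    UtX <- Matrix::crossprod(Lb, pre$ZtX)
    Uty <- Matrix::crossprod(Lb, pre$Zty)
    HiUX <- Matrix::solve(H, UtX)
    S <- pre$XtX - as.matrix(Matrix::crossprod(UtX, HiUX))
    cb <- pre$Xty - as.vector(Matrix::crossprod(UtX, Matrix::solve(H, Uty)))
    beta <- solve(S, cb)
    u <- as.vector(Matrix::solve(H, Uty - UtX %*% beta))
    fitted <- as.vector(design$X %*% beta) +
      as.vector(design$Z %*% (Lb %*% u))
    r2 <- sum((design$y - fitted)^2) + sum(u^2)
    ldL2 <- as.numeric(Matrix::determinant(H, logarithm = TRUE)$modulus)
    Ls <- lam$L
  } else {
    S <- pre$XtX
    beta <- solve(S, pre$Xty)
    u <- numeric(0)
    fitted <- as.vector(design$X %*% beta)
    r2 <- sum((design$y - fitted)^2)
    ldL2 <- 0
    Ls <- list()
  }
  ldRX2 <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  crit <- if (REML) {
    ldL2 + ldRX2 + (n - p) * (1 + log(2 * pi * r2 / (n - p)))
  } else {
    ldL2 + n * (1 + log(2 * pi * r2 / n))
  }
  list(crit = crit, beta = beta, u = u, r2 = r2, S = S, L = Ls)
}

#' Fit a linear mixed model by restricted maximum likelihood
#'
#' The covariance parameters are estimated by minimizing the profiled REML
#' criterion (fixed effects and residual variance profiled out in closed
#' form); a Nelder-Mead search is followed by a quasi-Newton polish so that
#' variance components match closed-form estimators to high precision on
#' balanced designs. `t = b / SE` is reported per coefficient; significance
#' is conventionally judged by |t| > 1.96.
#'
#' @inheritParams fit_binomial_glmm
#' @param REML use the REML criterion (default) rather than ML.
#' @param reduce simplify the random-effects structure stepwise by removing
#'   random terms whose estimated SD falls below `control$sd_tol` times the
#'   response SD, re-fitting after each removal.
#' @return An `mm_fit` object (with `t` in place of `z`, no p-values, and a
#'   residual `sigma`).
#' @export
fit_lmm <- function(formula, data, REML = TRUE, reduce = FALSE,
                    control = mm_control()) {
  spec <- if (inherits(formula, "mm_spec")) formula else parse_mm_formula(formula)
  repeat {
    fit <- fit_lmm_once(spec, data, REML, control)
    if (!reduce || fit$q == 0L) return(fit)
    resp_sd <- sd(data[[spec$response]])
    small <- NULL
    for (ti in seq_along(fit$ranef)) {
      idx <- which(fit$ranef[[ti]]$sd < control$sd_tol * resp_sd)
      if (length(idx)) { small <- list(ti = ti, name = fit$ranef[[ti]]$names[idx[1]]); break }
    }
    if (is.null(small)) return(fit)
    spec <- drop_random_term(spec, small$ti, small$name)
    message("dropping random term '", small$name, "' for group '",
            fit$ranef[[small$ti]]$group, "' (estimated SD below threshold)")
  }
}

drop_random_term <- function(spec, ti, name) {
  tm <- if (name == "(Intercept)") "1" else name
  spec$random[[ti]]$terms <- setdiff(spec$random[[ti]]$terms, tm)
  if (!length(spec$random[[ti]]$terms)) spec$random[[ti]] <- NULL
  spec$random <- Filter(Negate(is.null), spec$random)
  spec
}

# Newton refinement with central-difference derivatives; bails out when a
# step does not decrease the objective (e.g. boundary/singular fits).
newton_polish <- function(obj, par, h = 1e-5, maxit = 10L) {
  np <- length(par)
  f0 <- obj(par)
  for (it in seq_len(maxit)) {
    g <- numeric(np)
    Hm <- matrix(0, np, np)
    fp <- fm <- numeric(np)
    for (i in seq_len(np)) {
      ei <- replace(numeric(np), i, h)
      fp[i] <- obj(par + ei); fm[i] <- obj(par - ei)
      g[i] <- (fp[i] - fm[i]) / (2 * h)
      Hm[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
    }
    if (np > 1L) for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      eij <- replace(numeric(np), c(i, j), h)
      Hm[i, j] <- Hm[j, i] <-
        (obj(par + eij) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] +
           obj(par - eij)) / (2 * h^2)
    }
    step <- tryCatch(solve(Hm, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    par_new <- par - step
    f_new <- obj(par_new)
    if (!is.finite(f_new) || f_new > f0 + 1e-12) break
    improved <- f0 - f_new
    par <- par_new; f0 <- f_new
    if (improved < 1e-13 * (abs(f0) + 1)) break
  }
  par
}

fit_lmm_once <- function(spec, data, REML, control) {
  design <- build_design(spec, data)
  pre <- list(design = design,
              XtX = crossprod(design$X),
              Xty = as.vector(crossprod(design$X, design$y)))
  if (design$q > 0L) {
    pre$ZtZ <- Matrix::crossprod(design$Z)
    pre$ZtX <- Matrix::crossprod(design$Z, design$X)
    pre$Zty <- as.vector(Matrix::crossprod(design$Z, design$y))
  }
  conv <- 0L
  if (design$q > 0L) {
    obj <- function(th) lmm_profiled_eval(pre, th, REML)$crit
    th0 <- theta_init(design)
    opt <- if (length(th0) == 1L) {
      stats::optim(th0, obj, method = "Brent", lower = -12, upper = 6)
    } else {
      stats::optim(th0, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000L, reltol = 1e-13))
    }
    # quasi-Newton then Newton polish for high-precision variance components
    opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                         control = list(maxit = 200L, reltol = 1e-14,
                                        ndeps = rep(1e-6, length(opt$par))))
    opt <- if (opt2$value <= opt$value) opt2 else opt
    theta <- newton_polish(obj, opt$par)
    conv <- opt$convergence
  } else theta <- numeric(0)
  ev <- lmm_profiled_eval(pre, theta, REML)
  n <- design$n; p <- design$p
  sigma2 <- ev$r2 / if (REML) (n - p) else n
  Vb <- sigma2 * solve(ev$S)
  se <- sqrt(diag(Vb))
  beta <- ev$beta
  tval <- beta / se
  fixed <- data.frame(term = colnames(design$X), b = beta, se = se,
                      t = tval, row.names = NULL, stringsAsFactors = FALSE)
  ranef <- ranef_summary(design, ev$L, sigma = sqrt(sigma2))
  singular <- any(unlist(lapply(ranef, function(r) r$sd)) <
                    control$sd_tol * sqrt(sigma2) * 10)
  structure(list(family = "gaussian", spec = design$spec, fixed = fixed,
                 ranef = ranef, theta = theta,
                 deviance = ev$crit, logLik = -ev$crit / 2,
                 sigma = sqrt(sigma2), REML = REML,
                 converged = conv == 0L, singular = singular,
                 n = n, p = p, q = design$q, vcov = Vb),
            class = "mm_fit")
}

#' Evaluate the Laplace-approximated deviance of a binomial GLMM
#'
#' Exposes the objective the fitter minimizes, for validation against
#' independent likelihood computations (e.g. adaptive Gauss-Hermite
#' quadrature on scalar random-intercept models).
#'
#' @inheritParams fit_binomial_glmm
#' @param beta fixed-effects vector.
#' @param theta covariance parameter vector (log-Cholesky scale).
#' @return Minus twice the Laplace-approximated marginal log-likelihood.
#' @export
glmm_laplace_deviance <- function(formula, data, beta, theta) {
  design <- build_design(formula, data)
  glmm_laplace_eval(design, theta, beta, new.env(parent = emptyenv()))$dev
}

#' @exportS3Method base::print
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> %s %s, n = %d, %s\n",
              x$family,
              if (x$family == "gaussian") ifelse(isTRUE(x$REML), "LMM (REML)", "LMM (ML)")
              else "logit GLMM (Laplace)",
              x$n,
              if (x$converged) "converged" else "NOT converged"))
  if (x$singular) cat("  note: singular fit (near-zero variance component)\n")
  print(x$fixed, digits = 4)
  for (r in x$ranef) {
    cat(sprintf("  random (%s): SD %s\n", r$group,
                paste(sprintf("%s=%.4f", r$names, r$sd), collapse = ", ")))
  }
  if (!is.na(x$sigma)) cat(sprintf("  residual sigma = %.4f\n", x$sigma))
  invisible(x)
}

#' Paper-style report table for a fitted mixed model
#'
#' Fixed-effect rows (coefficient, SE, z or t, p for GLMMs, |t| > 1.96
#' significance for LMMs) plus a random-effects block of variances/SDs and
#' correlations. With `derive_old = TRUE`, derived coefficients for the older
#' group (young coefficient + old-young interaction) are appended.
#'
#' @param fit an `mm_fit`.
#' @param style label recorded in the table (`grid`, `object`, `times`,
#'   `pvl`).
#' @param derive_old append derived old-group coefficients.
#' @return A list of data frames `fixed` and `random`.
#' @export
summarize_fit <- function(fit, style = c("grid", "object", "times", "pvl"),
                          derive_old = FALSE) {
  style <- match.arg(style)
  fx <- fit$fixed
  stat <- if (fit$family == "binomial") fx$z else fx$t
  base <- sub(":age$", "", fx$term)
  is_int <- grepl(":age$", fx$term) | fx$term == "age"
  fixed <- data.frame(
    analysis = style,
    term = ifelse(fx$term == "age", "(Intercept)", base),
    description = ifelse(is_int, "old-young", "young"),
    b = fx$b, se = fx$se, statistic = stat,
    stringsAsFactors = FALSE)
  if (fit$family == "binomial") fixed$p <- fx$p
  else fixed$significant <- abs(stat) > 1.96
  if (derive_old) {
    for (i in which(is_int)) {
      b_term <- if (fx$term[i] == "age") "(Intercept)" else base[i]
      j <- which(fx$term == b_term)
      if (length(j) == 1L) {
        row <- fixed[i, ]
        row$description <- "old (derived)"
        row$b <- fx$b[j] + fx$b[i]
        row$se <- NA_real_; row$statistic <- NA_real_
        if (fit$family == "binomial") row$p <- NA_real_
        fixed <- rbind(fixed, row)
      }
    }
  }
  random_blocks <- lapply(fit$ranef, function(r) {
    df <- data.frame(group = r$group, name = r$names,
                     variance = diag(r$Sigma), sd = r$sd,
                     correlations = "", stringsAsFactors = FALSE)
    if (length(r$names) > 1L) {
      pairs <- which(lower.tri(r$corr), arr.ind = TRUE)
      for (kk in seq_len(nrow(pairs)))
        df$correlations[pairs[kk, 1]] <-
          trimws(paste(df$correlations[pairs[kk, 1]],
                       sprintf("%.2f", r$corr[pairs[kk, 1], pairs[kk, 2]])))
    }
    df
  })
  if (!is.na(fit$sigma))
    random_blocks <- c(random_blocks, list(
      data.frame(group = "residual", name = "sigma",
                 variance = fit$sigma^2, sd = fit$sigma,
                 correlations = "", stringsAsFactors = FALSE)))
  random <- do.call(rbind, random_blocks)
  rownames(fixed) <- NULL
  if (!is.null(random)) rownames(random) <- NULL
  list(fixed = fixed, random = random)
}
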