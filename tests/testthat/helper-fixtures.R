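# Shared fixtures and independent oracles for the test suite.

tiny_config <- function(...) {
  args <- list(n_scenes = 4L, n_subjects_young = 3L, n_subjects_old = 3L,
               n_missing_trials = 1L, grid_cols = 4L, grid_rows = 3L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(desk_config, args)
}

tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(tiny_config())
    cache
  }
})

tiny_object_sets <- function(ds = tiny_dataset()) region_sets_for(ds, "object")
tiny_grid_sets <- function(ds = tiny_dataset(), cols = 4, rows = 3)
  region_sets_for(ds, "grid", cols, rows)

# --- Gauss-Hermite nodes via Golub-Welsch (independent of the package) ------
gh_rule <- function(n) {
  i <- seq_len(n - 1)
  M <- matrix(0, n, n)
  b <- sqrt(i / 2)
  M[cbind(i, i + 1)] <- b
  M[cbind(i + 1, i)] <- b
  E <- eigen(M, symmetric = TRUE)
  list(x = E$values, w = sqrt(pi) * E$vectors[1, ]^2)
}

# Adaptive Gauss-Hermite marginal -2 log-likelihood for a Bernoulli model
# with a scalar random intercept per cluster: an oracle for the Laplace
# objective, implemented by direct numerical integration.
agq_m2ll <- function(eta_fixed, cluster, y, sigma, order = 25) {
  nodes <- gh_rule(order)
  tot <- 0
  for (cl in unique(cluster)) {
    idx <- cluster == cl
    eta0 <- eta_fixed[idx]
    yy <- y[idx]
    cll <- function(u)
      sum(ifelse(yy == 1, plogis(eta0 + sigma * u, log.p = TRUE),
                 plogis(-(eta0 + sigma * u), log.p = TRUE)))
    h <- function(u) -cll(u) + u^2 / 2
    uhat <- optimize(h, c(-15, 15))$minimum
    hpp <- (h(uhat + 1e-4) - 2 * h(uhat) + h(uhat - 1e-4)) / 1e-8
    s <- 1 / sqrt(hpp)
    z <- uhat + sqrt(2) * s * nodes$x
    lt <- log(sqrt(2) * s) + log(nodes$w) + nodes$x^2 +
      vapply(z, cll, numeric(1)) + dnorm(z, log = TRUE)
    m <- max(lt)
    tot <- tot + m + log(sum(exp(lt - m)))
  }
  -2 * tot
}

# --- brute-force oracles ----------------------------------------------------

# first-pass gaze durations by a direct linear scan over one trial
brute_gaze <- function(xs, ys, durs, box) {
  inb <- xs >= box[1] & xs <= box[1] + box[3] - 1 &
    ys >= box[2] & ys <= box[2] + box[4] - 1
  if (!any(inb)) return(NULL)
  i0 <- which(inb)[1]
  j0 <- i0
  while (j0 < length(inb) && inb[j0 + 1]) j0 <- j0 + 1
  list(entry = i0, first = durs[i0], gaze = sum(durs[i0:j0]),
       includes_last = j0 == length(inb))
}

# mean map value over a box by an explicit pixel loop
brute_region_mean <- function(map, x0, y0, w, h) {
  acc <- 0
  for (yy in y0:(y0 + h - 1)) for (xx in x0:(x0 + w - 1))
    acc <- acc + map[yy + 1, xx + 1]
  acc / (w * h)
}

# expected grid observation-matrix row count by enumeration over trials
brute_grid_rows <- function(report, n_cells) {
  keys <- unique(paste(report$subject, report$scene))
  length(keys) * (n_cells - 1)
}
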