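#' Mixed-model formulas and design construction
#'
#' Models are specified in Wilkinson notation with lme4-style random-effect
#' terms, e.g.
#' `fixated ~ 1 + age + z_central_bias + z_central_bias:age + z_salience +
#'  z_salience:age + (1 + z_central_bias + z_salience | subject) +
#'  (1 + z_central_bias + z_salience | scene)`.
#' `age` is the age-group factor with treatment coding (young = 0, old = 1);
#' age enters only through the main effect and `predictor:age` interactions.
#' Random-effect terms `(expr | group)` give each level of `group` its own
#' coefficients for the terms in `expr`, with a fully parameterized
#' (correlated) covariance. Object-within-scene nesting is expressed simply
#' by using globally unique object ids as a grouping factor.
#'
#' @param formula model formula (or a string).
#' @return A `mm_spec` list with elements `response`, `fixed` (term labels)
#'   and `random` (list of `group` + `terms`).
#' @export
parse_mm_formula <- function(formula) {
  f <- stats::as.formula(formula)
  if (length(f) != 3L) stop("model formula needs a response")
  response <- deparse(f[[2]])
  fixed <- character(0)
  random <- list()
  walk <- function(e) {
    if (is.call(e) && identical(e[[1]], as.name("+"))) {
      walk(e[[2]]); walk(e[[3]])
    } else if (is.call(e) && identical(e[[1]], as.name("(")) &&
               is.call(e[[2]]) && identical(e[[2]][[1]], as.name("|"))) {
      bar <- e[[2]]
      terms <- character(0)
      collect <- function(x) {
        if (is.call(x) && identical(x[[1]], as.name("+"))) {
          collect(x[[2]]); collect(x[[3]])
        } else terms <<- c(terms, deparse(x))
      }
      collect(bar[[2]])
      random[[length(random) + 1L]] <<-
        list(group = deparse(bar[[3]]), terms = terms)
    } else {
      fixed <<- c(fixed, deparse(e))
    }
  }
  walk(f[[3]])
  fixed <- normalize_terms(fixed)
  random <- lapply(random, function(r) {
    r$terms <- normalize_terms(r$terms); r
  })
  structure(list(response = response, fixed = fixed, random = random),
            class = "mm_spec")
}

normalize_terms <- function(terms) {
  vapply(terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      parts <- trimws(strsplit(tm, ":", fixed = TRUE)[[1]])
      if (length(parts) != 2L || !"age" %in% parts)
        stop("only predictor:age interactions are supported, got: ", tm)
      paste0(setdiff(parts, "age"), ":age")
    } else trimws(tm)
  }, character(1), USE.NAMES = FALSE)
}

#' Build fixed and random designs from an observation table
#'
#' @param spec an `mm_spec` from [parse_mm_formula()] (or a formula).
#' @param data observation rows; must contain the response, every predictor
#'   named in the spec, and `age_group` if `age` is used.
#' @return A list with the response vector `y`, dense fixed-effects matrix
#'   `X`, sparse random-effects matrix `Z` (columns blocked by term,
#'   level-major within term) and per-term metadata used to build the
#'   relative covariance factor.
#' @export
build_design <- function(spec, data) {
  if (!inherits(spec, "mm_spec")) spec <- parse_mm_formula(spec)
  n <- nrow(data)
  if (is.null(data[[spec$response]]))
    stop("response column not found: ", spec$response)
  y <- as.numeric(data[[spec$response]])

  needs_age <- any(grepl("(^age$|:age$)", c(spec$fixed,
                                            unlist(lapply(spec$random, `[[`, "terms")))))
  age01 <- NULL
  if (needs_age) {
    if (is.null(data$age_group)) stop("column 'age_group' required for age terms")
    age01 <- as.numeric(data$age_group == "old")  # treatment coding, young = 0
  }
  col_of <- function(tm) {
    if (tm == "1") return(rep(1, n))
    if (tm == "age") return(age01)
    if (grepl(":age$", tm)) {
      v <- sub(":age$", "", tm)
      if (is.null(data[[v]])) stop("predictor column not found: ", v)
      return(as.numeric(data[[v]]) * age01)
    }
    if (is.null(data[[tm]])) stop("predictor column not found: ", tm)
    as.numeric(data[[tm]])
  }
  X <- do.call(cbind, lapply(spec$fixed, col_of))
  colnames(X) <- ifelse(spec$fixed == "1", "(Intercept)", spec$fixed)

  re <- list()
  if (length(spec$random)) {
    for (r in spec$random) {
      if (is.null(data[[r$group]]))
        stop("grouping factor column not found: ", r$group)
      f <- factor(data[[r$group]])
      if (nlevels(f) < 2L)
        stop("grouping factor needs >= 2 levels: ", r$group)
      M <- do.call(cbind, lapply(r$terms, col_of))
      colnames(M) <- ifelse(r$terms == "1", "(Intercept)", r$terms)
      re[[length(re) + 1L]] <- list(group = r$group, f = f, M = M,
                                    k = ncol(M), nlev = nlevels(f))
    }
  }
  q <- 0L
  for (t in re) q <- q + t$k * t$nlev
  Z <- NULL
  if (q > 0L) {
    ii <- jj <- xx <- list()
    off <- 0L
    for (ti in seq_along(re)) {
      t <- re[[ti]]
      ii[[ti]] <- rep(seq_len(n), t$k)
      jj[[ti]] <- off + (as.integer(t$f) - 1L) * t$k +
        rep(seq_len(t$k), each = n)
      xx[[ti]] <- as.vector(t$M)
      re[[ti]]$offset <- off
      off <- off + t$k * t$nlev
    }
    Z <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(n, q))
  }
  list(spec = spec, y = y, X = X, Z = Z, re = re, q = q, n = n,
       p = ncol(X))
}

# --- relative covariance factor (log-Cholesky parametrization) --------------

# per-term parameter count: k log-diagonal entries + k(k-1)/2 off-diagonals
theta_template <- function(design) {
  out <- list()
  for (ti in seq_along(design$re)) {
    k <- design$re[[ti]]$k
    nm <- colnames(design$re[[ti]]$M)
    diag_names <- paste0(design$re[[ti]]$group, ".log_sd.", nm)
    off_names <- character(0)
    if (k > 1L) {
      pairs <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
      off_names <- paste0(design$re[[ti]]$group, ".chol.",
                          nm[pairs[, 2]], ".", nm[pairs[, 1]])
    }
    out[[ti]] <- list(k = k, n_par = k + (k * (k - 1L)) %/% 2L,
                      names = c(diag_names, off_names))
  }
  out
}

theta_init <- function(design, sd0 = 1) {
  tpl <- theta_template(design)
  unlist(lapply(tpl, function(t)
    c(rep(log(sd0), t$k), rep(0, t$n_par - t$k))))
}

# lower-triangular factor of one term from its parameter block
term_chol <- function(theta_t, k) {
  L <- matrix(0, k, k)
  diag(L) <- exp(theta_t[seq_len(k)])
  if (k > 1L) L[lower.tri(L)] <- theta_t[-seq_len(k)]
  L
}

lambda_from_theta <- function(design, theta) {
  tpl <- theta_template(design)
  blocks <- list()
  pos <- 0L
  Ls <- list()
  for (ti in seq_along(design$re)) {
    np <- tpl[[ti]]$n_par
    L <- term_chol(theta[pos + seq_len(np)], tpl[[ti]]$k)
    Ls[[ti]] <- L
    blocks[[ti]] <- Matrix::kronecker(Matrix::Diagonal(design$re[[ti]]$nlev),
                                      methods::as(L, "sparseMatrix"))
    pos <- pos + np
  }
  list(Lambda = Matrix::bdiag(blocks), L = Ls)
}
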