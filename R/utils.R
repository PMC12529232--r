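# Small numerical helpers shared across modules.

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

#' Derive a reproducible sub-stream seed from a master seed
#'
#' A single user-facing seed is expanded into independent per-stage seeds by
#' hashing the stage tag, so adding a pipeline stage never perturbs the draws
#' of earlier stages.  The result is always a valid 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stage (e.g. `"trial"`, `"survey-2004"`).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + k) %% 2147483629
  }
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 31 + h) %% 2147483629)
}

# Gauss-Hermite nodes/weights (Golub-Welsch via symmetric tridiagonal
# eigenproblem), returned already transformed for integrals against the
# standard normal density: E[f(Z)] ~ sum(w * f(x)).
gauss_hermite_normal <- function(n = 25L) {
  i <- seq_len(n - 1L)
  a <- rep(0, n)
  b <- sqrt(i / 2)
  J <- diag(a)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1L, ]^2  # weights sum to 1 after normal transform
  ord <- order(x)
  list(nodes = sqrt(2) * x[ord], weights = w[ord])
}

# Marginal success probability of a random-intercept logistic model:
# E_u[expit(eta + u)], u ~ N(0, sigma_u^2), by Gauss-Hermite quadrature.
# Vectorised over eta.
marginal_expit <- function(eta, sigma_u, gh = NULL) {
  if (sigma_u == 0) return(expit(eta))
  if (is.null(gh)) gh <- gauss_hermite_normal(25L)
  p <- numeric(length(eta))
  for (k in seq_along(gh$nodes)) {
    p <- p + gh$weights[k] * expit(eta + sigma_u * gh$nodes[k])
  }
  p
}

# Run an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
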