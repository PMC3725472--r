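#' Quadratic expansion of a signal
#'
#' Maps `x` to all monomials of degree one and two: the `N` inputs followed
#' by all products `x_i * x_j` for `i <= j` in lexicographic `(i, j)` order,
#' giving `N + N(N+1)/2` outputs. The (usually quadratic) expansion is what
#' lets linear SFA find nonlinear input-output functions.
#'
#' @param x Numeric vector (length `N`) or `T x N` matrix (expanded row-wise).
#' @return Expanded vector or `T x M` matrix, `M = N + N(N+1)/2`.
#' @export
quadratic_expand <- function(x) {
  if (is.matrix(x)) {
    n <- ncol(x)
    out <- matrix(0, nrow(x), n + n * (n + 1) / 2)
    out[, seq_len(n)] <- x
    pos <- n
    for (i in seq_len(n)) {
      m <- n - i + 1L
      out[, pos + seq_len(m)] <- x[, i] * x[, i:n, drop = FALSE]
      pos <- pos + m
    }
    out
  } else {
    drop(quadratic_expand(matrix(x, 1)))
  }
}

expanded_dim <- function(n, expansion) {
  if (expansion == "quadratic") n + n * (n + 1) / 2 else n
}

#' Slowness (delta) value of a signal
#'
#' The mean squared temporal derivative `<y_dot^2>`, with the derivative
#' approximated by forward differences `y(t+1) - y(t)`. Smaller is slower.
#'
#' @param y Numeric vector (time-ordered) or `T x k` matrix (per column).
#' @param normalize Standardise to zero mean / unit (population) variance
#'   first, making values comparable across signals.
#' @return Scalar, or vector of per-column delta values.
#' @export
delta_value <- function(y, normalize = FALSE) {
  if (is.matrix(y)) return(apply(y, 2, delta_value, normalize = normalize))
  if (length(y) < 2) stopf("delta_value needs at least 2 samples")
  if (normalize) {
    s <- sqrt(mean((y - mean(y))^2))
    if (s == 0) stopf("cannot normalize a constant signal (zero variance)")
    y <- (y - mean(y)) / s
  }
  mean(diff(y)^2)
}

# ---- streaming moment accumulation -----------------------------------------
# Second moments and forward-difference second moments are accumulated
# additively over batches. Two conventions make the accumulation exactly
# independent of the batch partition: the last sample of each batch is
# carried into the next (differences span batch boundaries), and sums are
# always taken over fixed 256-sample micro-chunks aligned to the absolute
# sample index, so the floating-point summation order never depends on the
# batch size. The accumulated sums are therefore bit-equivalent to a single
# pass; fitted parameters can still differ by machine rounding where an
# intermediate projection is evaluated per batch.

MOMENT_CHUNK <- 256L

moments_new <- function(d) {
  list(d = d, n = 0, s = numeric(d), C = matrix(0, d, d),
       nd = 0, D = matrix(0, d, d), last = NULL, buf = NULL)
}

moments_ingest <- function(acc, Y) {
  acc$n <- acc$n + nrow(Y)
  acc$s <- acc$s + colSums(Y)
  acc$C <- acc$C + crossprod(Y)
  Yd <- if (is.null(acc$last)) Y else rbind(acc$last, Y)
  if (nrow(Yd) >= 2) {
    dY <- diff(Yd)
    acc$D <- acc$D + crossprod(dY)
    acc$nd <- acc$nd + nrow(dY)
  }
  acc$last <- Y[nrow(Y), , drop = FALSE]
  acc
}

moments_update <- function(acc, X) {
  stopifnot(ncol(X) == acc$d)
  buf <- if (is.null(acc$buf)) X else rbind(acc$buf, X)
  while (nrow(buf) >= MOMENT_CHUNK) {
    acc <- moments_ingest(acc, buf[seq_len(MOMENT_CHUNK), , drop = FALSE])
    buf <- buf[-seq_len(MOMENT_CHUNK), , drop = FALSE]
  }
  acc$buf <- if (nrow(buf) > 0) buf else NULL
  acc
}

moments_finalize <- function(acc) {
  if (!is.null(acc$buf)) {
    acc <- moments_ingest(acc, acc$buf)
    acc$buf <- NULL
  }
  if (acc$n < 2) stopf("need at least 2 samples to fit SFA")
  mu <- acc$s / acc$n
  cov <- acc$C / acc$n - tcrossprod(mu)       # population covariance
  dcov <- acc$D / max(1, acc$nd)              # uncentered difference moments
  list(n = acc$n, nd = acc$nd, mean = mu, cov = cov, dcov = dcov)
}

# Solve the SFA eigenproblem from finalized moments.
sfa_from_moments <- function(mom, out_dim, rank_tol = 1e-7) {
  eg <- eigen((mom$cov + t(mom$cov)) / 2, symmetric = TRUE)
  keep <- eg$values > rank_tol * max(eg$values, 0)
  rank <- sum(keep)
  if (rank < out_dim) {
    stopf(paste0("input covariance is numerically rank deficient ",
                 "(rank %d < requested %d outputs); add regularizing noise ",
                 "(noise_sigma > 0) or reduce out_dim"), rank, out_dim)
  }
  W <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), rank)
  Dw <- crossprod(W, mom$dcov) %*% W
  e2 <- eigen((Dw + t(Dw)) / 2, symmetric = TRUE)
  sel <- rank:(rank - out_dim + 1)            # ascending slowness
  V <- e2$vectors[, sel, drop = FALSE]
  proj <- W %*% V
  # sign convention: largest-magnitude coefficient of each function positive
  for (k in seq_len(ncol(proj))) {
    if (proj[which.max(abs(proj[, k])), k] < 0) proj[, k] <- -proj[, k]
  }
  list(proj = proj, delta = e2$values[sel], rank = rank)
}

#' Fit Slow Feature Analysis
#'
#' Finds the `out_dim` linear (or quadratically expanded) input-output
#' functions with the smallest delta values, subject to the zero-mean,
#' unit-variance and decorrelation constraints over the training ensemble.
#' Pipeline: center, optionally expand, add seeded Gaussian regularisation
#' noise (fitting only), whiten, and eigen-decompose the covariance of the
#' forward differences; the eigenvectors with the smallest eigenvalues give
#' the slowest outputs, in ascending delta order.
#'
#' @param data `T x N` matrix or data frame of time-ordered samples.
#' @param out_dim Number of output signals `k`.
#' @param expansion `"none"` (linear SFA) or `"quadratic"`.
#' @param noise_sigma Standard deviation of the additive noise injected
#'   into the (expanded) training data; regularises rank-deficient
#'   covariances. `0` disables it.
#' @param seed Seed for the noise draw.
#' @return An object of class `sfa_model`.
#' @export
fit_sfa <- function(data, out_dim, expansion = c("none", "quadratic"),
                    noise_sigma = 0, seed = 1) {
  expansion <- match.arg(expansion)
  X <- as.matrix(data)
  if (!all(is.finite(X))) stopf("training data contains non-finite values")
  n <- ncol(X)
  m <- expanded_dim(n, expansion)
  if (out_dim > m) {
    stopf("out_dim (%d) exceeds expanded dimension (%d)", out_dim, m)
  }
  if (nrow(X) < m + 2) {
    stopf("need at least %d samples to fit %d expanded dimensions (got %d)",
          m + 2, m, nrow(X))
  }
  mu <- colMeans(X)
  Phi <- sweep(X, 2, mu)
  if (expansion == "quadratic") Phi <- quadratic_expand(Phi)
  if (noise_sigma > 0) {
    withr::with_seed(derive_seed(seed, 7L), {
      Phi <- Phi + matrix(stats::rnorm(length(Phi)), nrow(Phi)) * noise_sigma
    })
  }
  mom <- moments_finalize(moments_update(moments_new(m), Phi))
  sol <- sfa_from_moments(mom, out_dim)
  new_sfa_model(input_mean = mu, expansion = expansion, exp_mean = mom$mean,
                proj = sol$proj, delta = sol$delta, rank = sol$rank,
                noise_sigma = noise_sigma, seed = seed, n_train = nrow(X))
}

new_sfa_model <- function(input_mean, expansion, exp_mean, proj, delta, rank,
                          noise_sigma, seed, n_train) {
  structure(
    list(input_mean = input_mean, expansion = expansion, exp_mean = exp_mean,
         proj = proj, delta_values = delta, rank = rank,
         noise_sigma = noise_sigma, seed = seed, n_train = n_train,
         in_dim = length(input_mean),
         expanded_dim = length(exp_mean), out_dim = ncol(proj)),
    class = "sfa_model"
  )
}

#' @export
print.sfa_model <- function(x, ...) {
  cat(sprintf("<sfa_model> %d -> %s%d -> %d outputs; delta[1..3] = %s\n",
              x$in_dim,
              if (x$expansion == "quadratic") sprintf("quad %d -> ", x$expanded_dim) else "",
              x$expanded_dim, x$out_dim,
              paste(signif(utils::head(x$delta_values, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Apply a fitted SFA model
#'
#' Deterministic affine + expansion map; no noise is injected at
#' application time, and a single sample (`T = 1`) works: the model
#' responds from one visual frame.
#'
#' @param model An `sfa_model`.
#' @param data `T x N` matrix or length-`N` vector.
#' @return `T x k` matrix of output signals.
#' @export
apply_sfa <- function(model, data) {
  X <- if (is.matrix(data)) data else matrix(data, 1)
  if (ncol(X) != model$in_dim) {
    stopf("data has %d columns but the model expects %d", ncol(X), model$in_dim)
  }
  Phi <- sweep(X, 2, model$input_mean)
  if (model$expansion == "quadratic") Phi <- quadratic_expand(Phi)
  sweep(Phi, 2, model$exp_mean) %*% model$proj
}

#' Outputs on the exact training ensemble
#'
#' Re-applies the model to the training data including the regularisation
#' noise (regenerated from the stored seed), i.e. the ensemble with respect
#' to which the zero-mean / unit-variance / decorrelation constraints hold
#' exactly. On clean data the constraints hold only up to the noise level.
#'
#' @param model An `sfa_model` as returned by [fit_sfa()].
#' @param data The same `T x N` training data passed to [fit_sfa()].
#' @return `T x k` matrix of training outputs.
#' @export
sfa_training_outputs <- function(model, data) {
  X <- as.matrix(data)
  Phi <- sweep(X, 2, model$input_mean)
  if (model$expansion == "quadratic") Phi <- quadratic_expand(Phi)
  if (model$noise_sigma > 0) {
    withr::with_seed(derive_seed(model$seed, 7L), {
      Phi <- Phi + matrix(stats::rnorm(length(Phi)), nrow(Phi)) * model$noise_sigma
    })
  }
  sweep(Phi, 2, model$exp_mean) %*% model$proj
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sfa_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$delta_values),
                 delta = x$delta_values)
}

#' @export
glance.sfa_model <- function(x, ...) {
  tibble::tibble(in_dim = x$in_dim, expanded_dim = x$expanded_dim,
                 out_dim = x$out_dim, rank = x$rank,
                 expansion = x$expansion, noise_sigma = x$noise_sigma,
                 n_train = x$n_train)
}
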