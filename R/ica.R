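#' Sparse-coding rotation via ICA
#'
#' Fits the orthogonal rotation of (approximately white) SFA output signals
#' that maximises non-Gaussianity, the sparse-coding step that turns raw
#' slow signals into localised place fields. Fixed-point iteration with the
#' tanh negentropy contrast and symmetric decorrelation; because the input
#' is white, the unmixing matrix reduces to a pure rotation and output
#' variance is preserved.
#'
#' @param data `T x k` matrix of approximately white signals (e.g. SFA
#'   outputs); `T >= 10 k` recommended.
#' @param seed Seed for the random orthogonal initialisation.
#' @param tol Convergence tolerance on the rotation update.
#' @param max_iter Maximum number of fixed-point iterations.
#' @return An object of class `ica_model` with the orthogonal `rotation`
#'   matrix, a `converged` flag and the iteration count. On
#'   non-convergence a warning is raised and the best iterate returned.
#' @export
fit_ica <- function(data, seed = 1, tol = 1e-5, max_iter = 500) {
  X <- as.matrix(data)
  k <- ncol(X)
  if (nrow(X) < 10 * k) {
    warnf("fit_ica: only %d samples for %d signals (< 10k); estimate may be poor",
          nrow(X), k)
  }
  Xc <- sweep(X, 2, colMeans(X))
  Xt <- t(Xc)                                   # k x T
  T_ <- ncol(Xt)
  W <- withr::with_seed(derive_seed(seed, 13L), {
    matrix(stats::rnorm(k * k), k, k)
  })
  W <- sym_orth(W)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    U <- W %*% Xt                               # k x T
    G <- tanh(U)
    Wn <- (G %*% t(Xt)) / T_ - diag(rowMeans(1 - G^2), k) %*% W
    Wn <- sym_orth(Wn)
    # rotation-invariant convergence: directions aligned up to sign
    d <- max(abs(abs(diag(Wn %*% t(W))) - 1))
    W <- Wn
    if (d < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warnf("fit_ica did not converge in %d iterations (last change %.2e); returning best iterate",
          max_iter, d)
  }
  structure(list(rotation = W, converged = converged, iterations = iter,
                 seed = seed, k = k),
            class = "ica_model")
}

# symmetric orthogonalisation W <- (W W^T)^{-1/2} W
sym_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Apply an ICA rotation
#'
#' @param model An `ica_model`.
#' @param data `T x k` matrix (or length-`k` vector).
#' @return Rotated signals, same shape as `data`.
#' @export
apply_ica <- function(model, data) {
  X <- if (is.matrix(data)) data else matrix(data, 1)
  if (ncol(X) != model$k) {
    stopf("data has %d columns but the rotation is %d x %d",
          ncol(X), model$k, model$k)
  }
  X %*% t(model$rotation)
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> %d x %d rotation; %s after %d iterations\n",
              x$k, x$k, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}
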