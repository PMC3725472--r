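# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# Ray-segment intersection by explicit 2x2 linear solve, one segment at a
# time; returns the minimum positive hit distance (and u) over all segments.
oracle_raycast <- function(plan, origin, angle) {
  s <- plan$segments
  best <- list(distance = Inf, u = NA_real_, segment = NA_integer_)
  d <- c(cos(angle), sin(angle))
  for (i in seq_len(nrow(s))) {
    A <- cbind(d, c(s$x1[i] - s$x2[i], s$y1[i] - s$y2[i]))
    b <- c(s$x1[i] - origin[1], s$y1[i] - origin[2])
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    t <- unname(sol[1]); u <- unname(sol[2])
    if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9 && t < best$distance) {
      best <- list(distance = t, u = min(1, max(0, u)), segment = i)
    }
  }
  best
}

# Dense generalized-eigenproblem SFA solved via Cholesky reduction
# (B = L L^T, C = L^-1 A L^-T), entirely separate from the package's
# whitening pipeline. Returns training outputs for the slowest out_dim
# components, ascending.
oracle_sfa_outputs <- function(data, out_dim, expansion = "none") {
  X <- as.matrix(data)
  Phi <- sweep(X, 2, colMeans(X))
  if (expansion == "quadratic") {
    n <- ncol(Phi)
    ext <- matrix(0, nrow(Phi), n * (n + 1) / 2)
    pos <- 0L
    for (i in seq_len(n)) for (j in i:n) {
      pos <- pos + 1L
      ext[, pos] <- Phi[, i] * Phi[, j]
    }
    Phi <- cbind(Phi, ext)
  }
  Phi <- sweep(Phi, 2, colMeans(Phi))
  T_ <- nrow(Phi)
  B <- crossprod(Phi) / T_
  dPhi <- Phi[-1, , drop = FALSE] - Phi[-T_, , drop = FALSE]
  A <- crossprod(dPhi) / (T_ - 1)
  L <- t(chol(B + diag(1e-12 * max(diag(B)), ncol(B))))
  C <- solve(L, t(solve(L, t(A))))
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  m <- ncol(Phi)
  idx <- m:(m - out_dim + 1)
  vec <- solve(t(L), e$vectors[, idx, drop = FALSE])
  list(outputs = Phi %*% vec, delta = e$values[idx])
}

# tanh negentropy contrast of a 2-D whitened signal rotated by theta,
# summed over both components
oracle_ica_contrast <- function(X, theta) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  U <- X %*% t(R)
  g0 <- mean(log(cosh(stats::qnorm(seq(0.0005, 0.9995, by = 0.001)))))
  sum((colMeans(log(cosh(U))) - g0)^2)
}

# grid search over rotation angle maximizing the contrast (mod 90 deg)
oracle_ica_angle <- function(X, step_deg = 0.25) {
  grid <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  vals <- vapply(grid, function(th) oracle_ica_contrast(X, th), 0)
  grid[which.max(vals)] * 180 / pi
}

excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3
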