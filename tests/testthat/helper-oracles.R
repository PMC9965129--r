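# Independent numerical oracles and small fixtures shared across tests.

# Explicit finite-difference solution of the half-space heat equation
# dT/dt = D d2T/dz2 with Robin boundary dT/dz|0 = h T(0), unit plane source
# at z0. Second-order in space, ghost-node boundary treatment. Used as the
# independent oracle for greens_function().
fd_green_oracle <- function(z0, t_end, params, L = 6, dz = 0.002) {
  D <- params$diffusivity
  h <- params$heat_loss
  n <- round(L / dz) + 1L
  z <- (0:(n - 1)) * dz
  temp <- numeric(n)
  temp[which.min(abs(z - z0))] <- 1 / dz
  dt <- 0.4 * dz^2 / D
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  r <- D * dt / dz^2
  for (s in seq_len(nsteps)) {
    lap <- c(2 * (temp[2] - (1 + h * dz) * temp[1]),
             diff(diff(temp)),
             2 * (temp[n - 1] - temp[n]))
    temp <- temp + r * lap
  }
  list(z = z, temp = temp)
}

# Exhaustive-enumeration solution of min ||b - A x||, x >= 0 for tiny
# systems: tries every subset of variables as the passive (free) set,
# solves the unconstrained LS on it, and keeps the best feasible candidate.
nnls_enumeration_oracle <- function(A, b) {
  p <- ncol(A)
  best_x <- numeric(p)
  best_r <- sum(b^2)
  for (mask in seq_len(2^p) - 1L) {
    passive <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    x <- numeric(p)
    if (length(passive) > 0L) {
      xs <- tryCatch(qr.solve(A[, passive, drop = FALSE], b),
                     error = function(e) NULL)
      if (is.null(xs) || any(xs < 0)) next
      x[passive] <- xs
    }
    r <- sum((b - A %*% x)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best_x <- x
    }
  }
  best_x
}

# Small well-conditioned nonnegative test system with known solution
make_small_system <- function(n = 20L, seed = 101L, cond_boost = 1.0) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n, n) + cond_boost * n * diag(n) / 4
  x_true <- stats::runif(n)
  list(A = A, x_true = x_true, b = as.numeric(A %*% x_true))
}

# Scaled-down 532 nm-style kernel for inversion tests: 100 depth cells over
# 1.5 mm, 2 s at 200 fps
small_kernel_532 <- function() {
  build_kernel_matrix(depth_grid(100L, 1.5), time_grid(2.0, 0.005))
}

two_gaussian_profile <- function(grid, d1 = 0.10, w1 = 0.03, a1 = 0.6,
                                 d2 = 0.50, w2 = 0.10, a2 = 0.3) {
  tibble::tibble(
    depth_mm = grid$centers,
    delta_T_K = a1 * exp(-(grid$centers - d1)^2 / (2 * w1^2)) +
      a2 * exp(-(grid$centers - d2)^2 / (2 * w2^2))
  )
}

# shared scaled-down settings for fast full-pipeline tests
small_settings <- function() {
  list(`532` = list(depth_grid = depth_grid(100L, 2.0),
                    time_grid = time_grid(1.5, 0.005)),
       `1064` = list(depth_grid = depth_grid(100L, 3.0),
                     time_grid = time_grid(2.5, 0.005)))
}
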