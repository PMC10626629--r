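# Shared random fixtures, all built in code under explicit seeds.

random_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) + n * diag(n)
}

# Orthonormal n x N frame via QR.
random_frame <- function(n, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * N), n, N)))[, seq_len(N), drop = FALSE]
}

# Random tangent at C0 with singular values bounded by max_sv.
random_tangent <- function(C0, max_sv = pi / 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(C0); N <- ncol(C0)
  G <- matrix(rnorm(n * N), n, N)
  G <- G - C0 %*% crossprod(C0, G)
  sv <- svd(G)
  scale <- max_sv / max(sv$d)
  sv$u %*% ((sv$d * scale * runif(1, 0.2, 1)) * t(sv$v))
}

random_orthogonal <- function(N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(N * N), N, N)))
}

# History whose tangents are an exact linear image of the descriptors:
# Gamma_k = sum_j (W d_k)_j B_j with tangent basis B (list), plus the exact
# map as a function for oracle evaluation.
linear_map_history <- function(C0, n_basis = 3, N_d = 6, T_len = 12,
                               seed = 1) {
  set.seed(seed)
  B <- lapply(seq_len(n_basis), function(i) random_tangent(C0, max_sv = 0.2))
  W <- matrix(rnorm(n_basis * N_d, sd = 0.3), n_basis, N_d)
  f <- function(d) Reduce(`+`, Map(`*`, as.list(drop(W %*% d)), B))
  # quadratic-in-time descriptor trajectory (exactly representable by the
  # symmetric pairing for q_tilde >= 2)
  c0 <- runif(N_d); c1 <- rnorm(N_d, sd = 0.1); c2 <- rnorm(N_d, sd = 0.02)
  ds <- lapply(seq_len(T_len), function(t) c0 + c1 * t + c2 * t^2)
  gs <- lapply(ds, f)
  list(descriptors = ds, gammas = gs, map = f)
}

# Small geometry helpers.
dimer <- function(r, z = 1) {
  molecular_geometry(rbind(c(0, 0, 0), c(r, 0, 0)), charges = c(z, z))
}

random_geometry <- function(n, seed = NULL, box = 6) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    pos <- matrix(runif(3 * n, 0, box), n, 3)
    if (min(dist(pos)) > 1.2) break
  }
  molecular_geometry(pos, charges = rep(1, n))
}
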