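# Guess engines: quasi time-reversible Grassmann extrapolation (QTR), its
# fully time-reversible variant, the plain Grassmann extrapolation baseline
# (G-Ext), and the dissipative extended-Lagrangian baseline (XLBO).

#' Reduced system size of the symmetric extrapolation
#'
#' \eqn{\tilde q = q/2} for even \eqn{q}, \eqn{(q-1)/2} for odd \eqn{q}.
#'
#' @param q history depth.
#' @return integer \eqn{\tilde q}.
#' @export
q_tilde <- function(q) {
  q <- as.integer(q)
  if (q %% 2L == 0L) q %/% 2L else (q - 1L) %/% 2L
}

#' Extrapolation configuration
#'
#' @param strategy one of \code{"qtr"}, \code{"fully_tr"}, \code{"gext"},
#'   \code{"xlbo"}, \code{"previous"} (reuse last converged density) or
#'   \code{"core"} (no guess reuse at all).
#' @param q history depth (>= 3 for the symmetric schemes).
#' @param epsilon Tikhonov regularization parameter.
#' @param purify_xlbo purify the XLBO guess with McWeeny iterations before
#'   handing it to the SCF (the raw auxiliary density is not idempotent).
#' @return object of class \code{extrapolation_config}.
#' @export
extrapolation_config <- function(strategy = c("qtr", "fully_tr", "gext",
                                              "xlbo", "previous", "core"),
                                 q = 5L, epsilon = 0.005,
                                 purify_xlbo = TRUE) {
  strategy <- match.arg(strategy)
  q <- as.integer(q)
  if (strategy %in% c("qtr", "fully_tr") && q < 3L)
    stop("symmetric extrapolation needs q >= 3")
  if (epsilon < 0) stop("epsilon must be non-negative")
  structure(list(strategy = strategy, q = q, epsilon = epsilon,
                 q_tilde = q_tilde(q), purify_xlbo = purify_xlbo),
            class = "extrapolation_config")
}

#' Default extrapolation settings for an SCF threshold
#'
#' Good values found by grid search are \code{(q, epsilon) = (5, 0.005)} for a
#' 1e-5 RMS convergence threshold and \code{(4, 0.001)} for 1e-7.
#'
#' @param threshold SCF RMS convergence threshold.
#' @param strategy engine name, see \code{\link{extrapolation_config}}.
#' @return \code{extrapolation_config}.
#' @export
default_config <- function(threshold, strategy = "qtr") {
  if (threshold <= 1e-6) extrapolation_config(strategy, q = 4L, epsilon = 0.001)
  else extrapolation_config(strategy, q = 5L, epsilon = 0.005)
}

#' Assemble the symmetric Tikhonov least-squares system
#'
#' Builds the stacked system whose solution gives the extrapolation
#' coefficients: the top block of \code{b} is \eqn{d_n + d_{n-q}} and the top
#' block of column \eqn{i} of \code{A} is \eqn{d_{n-i} + d_{n-q+i}}
#' (\eqn{i = 1, \dots, \tilde q}); the bottom \eqn{\tilde q} rows are
#' \eqn{\epsilon I} and zeros.
#'
#' @param h \code{scf_history} holding at least \code{q} consecutive entries
#'   ending at step \code{n - 1}.
#' @param d_n descriptor of the current geometry.
#' @param n current step index.
#' @param cfg \code{extrapolation_config}.
#' @return list with the stacked \code{A}, \code{b}, the data blocks
#'   \code{A_top}, \code{b_top}, and \code{q_tilde}; \code{NULL} (cold-start
#'   signal) when the history is insufficient.
#' @export
build_ls_system <- function(h, d_n, n, cfg) {
  q <- cfg$q
  qt <- cfg$q_tilde
  if (!history_ready(h, n, q)) return(NULL)
  d_past <- lapply(seq_len(q), function(i) .history_descriptor(h, n - i))
  b_top <- d_n + d_past[[q]]
  A_top <- vapply(seq_len(qt),
                  function(i) d_past[[i]] + d_past[[q - i]],
                  numeric(length(d_n)))
  A_top <- matrix(A_top, nrow = length(d_n), ncol = qt)
  A <- rbind(A_top, cfg$epsilon * diag(qt))
  b <- c(b_top, numeric(qt))
  list(A = A, b = b, A_top = A_top, b_top = b_top, q_tilde = qt)
}

#' Solve a Tikhonov-regularized least-squares problem
#'
#' Minimizes \eqn{\|A\alpha - b\|^2 + \epsilon^2 \|\alpha\|^2} through the
#' stacked formulation: \eqn{\epsilon I} rows are appended to \code{A} and
#' zeros to \code{b}, and the augmented system is solved by QR. With
#' \code{epsilon = 0} this solves the plain least-squares problem, so it can
#' be applied directly to an already-stacked system.
#'
#' @param A data matrix (rows = observations, columns = unknowns).
#' @param b right-hand side.
#' @param epsilon regularization parameter (>= 0).
#' @return coefficient vector of length \code{ncol(A)}.
#' @export
solve_tikhonov <- function(A, b, epsilon = 0) {
  stopifnot(epsilon >= 0, nrow(A) == length(b))
  k <- ncol(A)
  if (epsilon > 0) {
    A <- rbind(A, epsilon * diag(k))
    b <- c(b, numeric(k))
  }
  unname(drop(qr.coef(qr(A, LAPACK = TRUE), b)))
}

#' Quasi time-reversible combination of stored tangents
#'
#' \deqn{\tilde\Gamma_n = \sum_{i=1}^{\tilde q} \alpha_i
#'   (\Gamma_{n-i} + \Gamma_{n-q+i}) - \Gamma_{n-q}.}
#' The weight of \eqn{\Gamma_{n-i}} equals that of \eqn{\Gamma_{n-q+i}} for
#' every \eqn{i}: the combination is symmetric under time reversal of the
#' history window, up to the single trailing \eqn{-\Gamma_{n-q}} term.
#'
#' @param h \code{scf_history}.
#' @param alpha coefficient vector of length \eqn{\tilde q}.
#' @param n current step index.
#' @param cfg \code{extrapolation_config}.
#' @param gamma_nq optional replacement for the converged
#'   \eqn{\Gamma_{n-q}} (the fully time-reversible variant substitutes its own
#'   previously emitted guess tangent here).
#' @return tangent matrix for step \code{n}.
#' @export
qtr_tangent <- function(h, alpha, n, cfg, gamma_nq = NULL) {
  qt <- cfg$q_tilde
  if (length(alpha) != qt)
    stop(sprintf("coefficient vector has length %d but q_tilde = %d",
                 length(alpha), qt))
  q <- cfg$q
  if (is.null(gamma_nq)) gamma_nq <- .history_gamma(h, n - q)
  G <- -gamma_nq
  for (i in seq_len(qt))
    G <- G + alpha[i] * (.history_gamma(h, n - i) + .history_gamma(h, n - q + i))
  G
}

#' Quasi time-reversible Grassmann extrapolation guess
#'
#' Fits the coefficients to the Coulomb-matrix descriptors by Tikhonov least
#' squares, forms the symmetric tangent combination and maps it back to the
#' manifold: the returned guess is an exact projector.
#'
#' @param h \code{scf_history}.
#' @param d_n descriptor of the current geometry.
#' @param n current step index.
#' @param cfg \code{extrapolation_config}.
#' @param C0 reference frame of the run.
#' @return guess density matrix, or \code{NULL} (cold-start signal) when the
#'   history is insufficient.
#' @export
qtr_guess <- function(h, d_n, n, cfg, C0) {
  sys <- build_ls_system(h, d_n, n, cfg)
  if (is.null(sys)) return(NULL)
  alpha <- solve_tikhonov(sys$A, sys$b, epsilon = 0)
  grassmann_exp(qtr_tangent(h, alpha, n, cfg), C0)
}

#' Fully time-reversible tangent combination
#'
#' Identical to \code{\link{qtr_tangent}} except that the converged
#' \eqn{\Gamma_{n-q}} is replaced by the engine's own guess tangent emitted at
#' step \eqn{n-q}, which makes the update exactly time reversible in exact
#' arithmetic. When no stored guess exists yet (warm-up), the converged
#' tangent is used, which reduces the step to the quasi time-reversible one.
#'
#' @inheritParams qtr_tangent
#' @param guess_store named list mapping step index (as character) to
#'   previously emitted guess tangents.
#' @return tangent matrix.
#' @export
fully_tr_tangent <- function(h, alpha, n, cfg, guess_store) {
  key <- as.character(n - cfg$q)
  gamma_nq <- guess_store[[key]]
  qtr_tangent(h, alpha, n, cfg, gamma_nq = gamma_nq)
}

#' Plain Grassmann extrapolation guess (G-Ext baseline)
#'
#' Tangent \eqn{\sum_{i=1}^{q} \alpha_i \Gamma_{n-i}} with coefficients
#' minimizing \eqn{\|\sum_i \alpha_i d_{n-i} - d_n\|^2 + \epsilon^2\|\alpha\|^2}
#' (default \eqn{\epsilon = 0.01}), then the Grassmann exponential.
#'
#' @param h \code{scf_history}.
#' @param d_n current descriptor.
#' @param n current step index.
#' @param C0 reference frame.
#' @param q history depth.
#' @param epsilon regularization parameter.
#' @return guess density, or \code{NULL} when fewer than \code{q} consecutive
#'   entries are available.
#' @export
gext_guess <- function(h, d_n, n, C0, q = 5L, epsilon = 0.01) {
  if (!history_ready(h, n, q)) return(NULL)
  D_mat <- vapply(seq_len(q), function(i) .history_descriptor(h, n - i),
                  numeric(length(d_n)))
  D_mat <- matrix(D_mat, nrow = length(d_n), ncol = q)
  alpha <- solve_tikhonov(D_mat, d_n, epsilon = epsilon)
  G <- Reduce(`+`, lapply(seq_len(q),
                          function(i) alpha[i] * .history_gamma(h, n - i)))
  grassmann_exp(G, C0)
}

# -- XLBO baseline ------------------------------------------------------------

.xlbo_kappa <- 1.86
.xlbo_c <- 0.0016
.xlbo_alpha <- c(-36, 99, -88, 11, 32, -25, 8, -1)

#' Fresh state for the dissipative extended-Lagrangian propagator
#'
#' The auxiliary density P is propagated by a Verlet-like update with a
#' harmonic restoring term towards the converged density (strength
#' \eqn{\kappa = 1.86}) and a dissipative linear combination of the last eight
#' auxiliary densities (\eqn{c = 0.0016},
#' \eqn{\alpha = (-36, 99, -88, 11, 32, -25, 8, -1)}; the \eqn{\alpha_k} sum
#' to zero so a stationary history is a fixed point).
#'
#' @return object of class \code{xlbo_state}.
#' @export
xlbo_state_new <- function() {
  structure(list(kappa = .xlbo_kappa, c = .xlbo_c, alpha = .xlbo_alpha,
                 P_history = list()),
            class = "xlbo_state")
}

#' One step of the XLBO auxiliary-density propagation
#'
#' \deqn{P_{n+1} = 2P_n - P_{n-1} + \kappa (D_n - P_n)
#'   + c \sum_{k=0}^{7} \alpha_k P_{n-k}.}
#' On the first call the history is filled with the converged density (the
#' first nine emitted guesses are warm-up). The returned guess is the raw
#' auxiliary density and is not idempotent in general.
#'
#' @param state \code{xlbo_state}.
#' @param D_converged converged density of the current step.
#' @return list with \code{guess} (matrix), \code{state} (updated) and
#'   \code{warm_up} (logical).
#' @export
xlbo_step <- function(state, D_converged) {
  stopifnot(inherits(state, "xlbo_state"))
  warm_up <- FALSE
  if (length(state$P_history) < 9L) {
    state$P_history <- rep(list(D_converged), 9L)
    warm_up <- TRUE
  }
  Ph <- state$P_history           # Ph[[1]] = P_n, Ph[[2]] = P_{n-1}, ...
  diss <- Reduce(`+`, Map(`*`, state$alpha, Ph[1:8]))
  P_next <- 2 * Ph[[1]] - Ph[[2]] +
    state$kappa * (D_converged - Ph[[1]]) + state$c * diss
  state$P_history <- c(list(P_next), Ph[1:8])
  list(guess = P_next, state = state, warm_up = warm_up)
}

#' McWeeny purification of a near-idempotent matrix
#'
#' Iterates \eqn{P \leftarrow 3P^2 - 2P^3} until \eqn{\|P^2 - P\|_{max} <
#' 10^{-12}}; eigenvalues below 1/2 flow to 0 and above 1/2 to 1, so the rank
#' of a near-projector is preserved.
#'
#' @param P symmetric matrix with eigenvalues in (-0.3, 1.3).
#' @param tol idempotency target.
#' @param max_iter iteration cap.
#' @return exact projector.
#' @export
mcweeny_purify <- function(P, tol = 1e-12, max_iter = 50L) {
  stopifnot(is.matrix(P))
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -0.3 || max(ev) >= 1.3)
    stop("matrix is too far from a projector for McWeeny purification")
  for (k in seq_len(max_iter)) {
    P2 <- P %*% P
    if (max(abs(P2 - P)) < tol) return(P)
    P <- 3 * P2 - 2 * P2 %*% P
    P <- (P + t(P)) / 2
  }
  stop("McWeeny purification did not converge in ", max_iter, " iterations")
}

#' Cold-start guess policy
#'
#' Before the extrapolation history is available, reuse the last converged
#' density; at the very first step, signal the backend to use its default
#' initial guess (\code{NULL}).
#'
#' @param previous last converged density, or \code{NULL} at step 0.
#' @return \code{previous} (possibly \code{NULL}).
#' @export
cold_start_guess <- function(previous = NULL) previous

#' Grid-search selection of history depth and regularization
#'
#' Replays the symmetric extrapolation over a stored trajectory of
#' (tangent, descriptor) snapshots for every grid pair and returns the pair
#' minimizing the mean prediction error
#' \eqn{\|\tilde\Gamma_n - \Gamma_n\|_F}; ties are broken by smaller
#' \code{q}, then smaller \code{epsilon}.
#'
#' @param gammas list of tangent matrices for consecutive steps.
#' @param descriptors list of matching descriptor vectors.
#' @param q_grid candidate history depths.
#' @param eps_grid candidate regularization parameters.
#' @return list with \code{q}, \code{epsilon} and the full \code{errors}
#'   data frame.
#' @export
select_parameters <- function(gammas, descriptors,
                              q_grid = 3:20,
                              eps_grid = c(0.001, 0.002, 0.005, 0.01,
                                           0.02, 0.05)) {
  T_len <- length(gammas)
  stopifnot(length(descriptors) == T_len)
  if (T_len < max(q_grid) + 1L)
    stop("trajectory shorter than max(q_grid) + 1 snapshots")
  h <- history_new(capacity = T_len)
  for (k in seq_len(T_len))
    history_push(h, k, gammas[[k]], descriptors[[k]])
  grid <- expand.grid(epsilon = eps_grid, q = q_grid)
  grid$error <- NA_real_
  for (r in seq_len(nrow(grid))) {
    q <- grid$q[r]; eps <- grid$epsilon[r]
    cfg <- extrapolation_config("qtr", q = q, epsilon = eps)
    errs <- vapply(seq.int(q + 1L, T_len), function(n) {
      sys <- build_ls_system(h, descriptors[[n]], n, cfg)
      alpha <- solve_tikhonov(sys$A, sys$b, epsilon = 0)
      pred <- qtr_tangent(h, alpha, n, cfg)
      sqrt(sum((pred - gammas[[n]])^2))
    }, numeric(1))
    grid$error[r] <- mean(errs)
  }
  # errors at the floating-point floor are exact ties, not rankings
  floor_tol <- 1e-12 * max(grid$error)
  grid$error[grid$error < floor_tol] <- 0
  ord <- order(grid$error, grid$q, grid$epsilon)
  best <- grid[ord[1], ]
  list(q = as.integer(best$q), epsilon = best$epsilon,
       errors = grid[, c("q", "epsilon", "error")])
}
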