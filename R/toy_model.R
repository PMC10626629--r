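# Charge-self-consistent tight-binding toy model: one basis function per
# atom, distance-decaying hopping and overlap, and a Hubbard-style on-site
# coupling that makes the Fock operator depend on its own density. The SCF
# fixed point, energy and finite-difference forces are cheap, so guess quality
# is measurable as iteration counts. A short-range Born-Mayer pair repulsion
# balances the attractive band energy so that geometries have bound minima
# and NVE dynamics is stable (the standard tight-binding construction).

#' Parameters of the toy self-consistent model
#'
#' @param n_sites number of atoms / basis functions.
#' @param N number of occupied orbitals (doubly counting is not modelled).
#' @param t0 hopping prefactor (Hartree).
#' @param r0 hopping and overlap decay length (Bohr).
#' @param U on-site density coupling (Hartree).
#' @param s0 overlap decay amplitude, in [0, 0.3) so the overlap matrix stays
#'   positive definite away from pathological geometries.
#' @param a_rep Born-Mayer repulsion amplitude (Hartree).
#' @param rho_rep repulsion decay length (Bohr), shorter than \code{r0}.
#' @return object of class \code{toy_model_spec}.
#' @export
toy_model_spec <- function(n_sites, N, t0 = 0.8, r0 = 1.5, U = 0.15,
                           s0 = 0.1, a_rep = 3.5, rho_rep = 0.5) {
  stopifnot(N <= n_sites, U >= 0, s0 >= 0, s0 < 0.3, t0 > 0, r0 > 0)
  structure(list(n_sites = as.integer(n_sites), N = as.integer(N),
                 t0 = t0, r0 = r0, U = U, s0 = s0,
                 a_rep = a_rep, rho_rep = rho_rep),
            class = "toy_model_spec")
}

#' One-electron (hopping) Hamiltonian
#'
#' Off-diagonal entries \eqn{-t_0 \exp(-r_{ij}/r_0)}, zero diagonal; depends
#' only on interatomic distances, so it is invariant under rigid motions.
#'
#' @param g \code{molecular_geometry}.
#' @param spec \code{toy_model_spec}.
#' @return symmetric n x n matrix (Hartree).
#' @export
build_h0 <- function(g, spec) {
  R <- .pair_distances(g$positions)
  H <- -spec$t0 * exp(-R / spec$r0)
  diag(H) <- 0
  H
}

# Fast symmetric pairwise-distance matrix for small systems.
.pair_distances <- function(pos) {
  s <- rowSums(pos^2)
  D2 <- outer(s, s, `+`) - 2 * tcrossprod(pos)
  D2[D2 < 0] <- 0
  sqrt(D2)
}

#' Overlap matrix of the toy basis
#'
#' Unit diagonal, off-diagonal \eqn{s_0 \exp(-r_{ij}/r_0)}; verified positive
#' definite.
#'
#' @param g \code{molecular_geometry}.
#' @param spec \code{toy_model_spec}.
#' @param check verify positive definiteness (skipped internally where the
#'   Lowdin factorization validates the spectrum anyway).
#' @return symmetric positive-definite n x n matrix.
#' @export
build_overlap <- function(g, spec, check = TRUE) {
  R <- .pair_distances(g$positions)
  S <- spec$s0 * exp(-R / spec$r0)
  diag(S) <- 1
  if (check) {
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 1e-10)
      stop(sprintf("geometry too compressed: overlap eigenvalue %.3e", ev_min))
  }
  S
}

#' Fock operator of the toy model
#'
#' \eqn{F(D) = h_0 + U\,\mathrm{diag}(D_{11}, \dots, D_{nn})}: a mean-field
#' on-site coupling that depends on the density only through its diagonal.
#' \code{h0} is expected in the same (orthonormal) basis as \code{D}.
#'
#' @param D density matrix (orthonormal basis).
#' @param h0 one-electron Hamiltonian in the orthonormal basis.
#' @param spec \code{toy_model_spec}.
#' @return symmetric Fock matrix.
#' @export
fock <- function(D, h0, spec) {
  h0 + diag(spec$U * diag(D), nrow = nrow(h0))
}

# Assemble the geometry-dependent operators once per geometry; the pairwise
# distance matrix is computed a single time and shared by hopping, overlap
# and repulsion terms.
model_operators <- function(g, spec) {
  pos <- if (is.matrix(g)) g else g$positions
  R <- .pair_distances(pos)
  decay <- exp(-R / spec$r0)
  h0 <- -spec$t0 * decay
  diag(h0) <- 0
  if (spec$s0 > 0) {
    S <- spec$s0 * decay
    diag(S) <- 1
    f <- lowdin_factor(S)
    h0_ortho <- f$s_inv_half %*% h0 %*% f$s_inv_half
    h0_ortho <- (h0_ortho + t(h0_ortho)) / 2
  } else {
    S <- diag(nrow(h0))
    f <- NULL
    h0_ortho <- h0
  }
  e_rep <- spec$a_rep * sum(exp(-R[upper.tri(R)] / spec$rho_rep))
  list(h0 = h0, S = S, lowdin = f, h0_ortho = h0_ortho, e_rep = e_rep)
}

# Aufbau density from a Fock matrix; errors out on a closed HOMO-LUMO gap.
.aufbau_density <- function(F_mat, N) {
  e <- eigen(F_mat, symmetric = TRUE)
  n <- nrow(F_mat)
  occ <- seq.int(n, n - N + 1L)       # eigen() sorts decreasing
  if (N < n && (e$values[n - N] - e$values[n - N + 1L]) < 1e-10)
    stop("degenerate HOMO-LUMO gap: aufbau occupation is ill-defined")
  tcrossprod(e$vectors[, occ, drop = FALSE])
}

#' Electronic energy of a density
#'
#' \eqn{E = \mathrm{tr}(D h_0) + (U/2) \sum_i D_{ii}^2} in the orthonormal
#' basis.
#'
#' @param D density matrix (orthonormal basis).
#' @param h0_ortho one-electron Hamiltonian in the orthonormal basis.
#' @param spec \code{toy_model_spec}.
#' @return energy in Hartree.
#' @export
electronic_energy <- function(D, h0_ortho, spec) {
  sum(D * h0_ortho) + 0.5 * spec$U * sum(diag(D)^2)
}

#' Born-Mayer pair repulsion of a geometry
#'
#' \eqn{E_{rep} = \sum_{i<j} a_{rep} \exp(-r_{ij}/\rho_{rep})}; the
#' short-range repulsive counterpart of the attractive band energy.
#'
#' @param g \code{molecular_geometry}.
#' @param spec \code{toy_model_spec}.
#' @return energy in Hartree.
#' @export
repulsion_energy <- function(g, spec) {
  R <- .pair_distances(g$positions)
  spec$a_rep * sum(exp(-R[upper.tri(R)] / spec$rho_rep))
}

#' Solve the toy SCF problem
#'
#' Fixed-point iteration in the Lowdin-orthonormalized basis: build the Fock
#' operator, diagonalize, occupy the N lowest levels (aufbau), and linearly
#' mix the input of the next Fock build. Convergence is monitored as the RMS
#' change \eqn{\|D_{k} - D_{k-1}\|_F / n} between successive aufbau
#' densities (the first iteration compares against the guess). The iteration
#' count equals the number of Fock builds, so a better guess converges in
#' fewer iterations.
#'
#' @param g \code{molecular_geometry}.
#' @param spec \code{toy_model_spec}.
#' @param guess initial density in the orthonormal basis, or \code{NULL} for
#'   the backend default (the zero-density core guess).
#' @param threshold RMS convergence threshold.
#' @param mixing linear mixing parameter in (0, 1].
#' @param max_iter iteration cap.
#' @param ops pre-assembled operators (internal reuse).
#' @return object of class \code{scf_result}: \code{density} (an exact
#'   projector), \code{energy} (electronic, Hartree), \code{iterations},
#'   \code{converged}, \code{rms_history}, and the \code{lowdin} factor.
#' @export
scf_solve <- function(g, spec, guess = NULL, threshold = 1e-7, mixing = 0.8,
                      max_iter = 200L, ops = NULL) {
  stopifnot(threshold > 0, mixing > 0, mixing <= 1)
  if (is.null(ops)) ops <- model_operators(g, spec)
  out <- .scf_core(ops, spec, guess, threshold, mixing, max_iter)
  if (!out$converged)
    stop(sprintf("SCF did not converge in %d iterations (last RMS %.3e)",
                 max_iter, out$rms_history[length(out$rms_history)]))
  structure(list(density = out$density, energy = out$energy,
                 iterations = out$iterations, converged = TRUE,
                 rms_history = out$rms_history, lowdin = ops$lowdin),
            class = "scf_result")
}

# Slim operator assembly for the force loop: only the orthonormal-basis
# Hamiltonian and the repulsion energy are needed there.
.ops_fast <- function(pos, spec) {
  R <- .pair_distances(pos)
  decay <- exp(-R / spec$r0)
  h0 <- -spec$t0 * decay
  diag(h0) <- 0
  if (spec$s0 > 0) {
    S <- spec$s0 * decay
    diag(S) <- 1
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) <= 1e-10)
      stop(sprintf("geometry too compressed: overlap eigenvalue %.3e",
                   min(e$values)))
    s_inv_half <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
    h0_ortho <- s_inv_half %*% h0 %*% s_inv_half
    h0_ortho <- (h0_ortho + t(h0_ortho)) / 2
  } else {
    h0_ortho <- h0
  }
  e_rep <- spec$a_rep * sum(exp(-R[upper.tri(R)] / spec$rho_rep))
  list(h0_ortho = h0_ortho, e_rep = e_rep)
}

# Fixed-point loop shared by scf_solve() and the force evaluator.
.scf_core <- function(ops, spec, guess, threshold, mixing, max_iter) {
  n <- spec$n_sites
  h0 <- ops$h0_ortho
  U <- spec$U
  N <- spec$N
  D <- if (is.null(guess)) matrix(0, n, n) else guess
  D_cmp <- D                  # convergence monitors successive aufbau outputs
  rms_history <- numeric(max_iter)
  for (k in seq_len(max_iter)) {
    F_mat <- h0
    diag(F_mat) <- diag(h0) + U * diag(D)
    D_raw <- .aufbau_density(F_mat, N)
    rms <- sqrt(sum((D_raw - D_cmp)^2)) / n
    rms_history[k] <- rms
    if (rms < threshold) {
      return(list(density = D_raw,
                  energy = sum(D_raw * h0) + 0.5 * U * sum(diag(D_raw)^2),
                  iterations = k, converged = TRUE,
                  rms_history = rms_history[seq_len(k)]))
    }
    D_cmp <- D_raw
    D <- (1 - mixing) * D + mixing * D_raw
  }
  list(density = D, energy = NA_real_, iterations = max_iter,
       converged = FALSE, rms_history = rms_history)
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("scf_result: E = %.10f Ha, %d iterations, converged = %s\n",
              x$energy, x$iterations, x$converged))
  invisible(x)
}

#' Total model potential energy at a geometry
#'
#' Electronic energy of the converged density plus the pair repulsion.
#'
#' @param g \code{molecular_geometry}.
#' @param spec \code{toy_model_spec}.
#' @param scf converged \code{scf_result} at \code{g}.
#' @return energy in Hartree.
#' @export
potential_energy <- function(g, spec, scf) {
  scf$energy + repulsion_energy(g, spec)
}

#' Finite-difference forces of the toy model
#'
#' Central finite differences (displacement 1e-4 Bohr per Cartesian
#' coordinate) of the total energy evaluated at the frozen converged density:
#' the fixed-density energy gradient, which is the standard Born-Oppenheimer
#' force. At exact SCF convergence it equals the full energy gradient by
#' variational stationarity; at a finite convergence threshold its error is
#' first order in the SCF residual, so guess-induced convergence bias
#' propagates into the dynamics the way it does in production codes.
#'
#' @param g \code{molecular_geometry}.
#' @param spec \code{toy_model_spec}.
#' @param D_converged converged density at \code{g} (orthonormal basis),
#'   frozen during the displacements.
#' @param h displacement (Bohr).
#' @return N x 3 force matrix (Hartree/Bohr).
#' @export
forces <- function(g, spec, D_converged, h = 1e-4) {
  pos0 <- if (is.matrix(g)) g else g$positions
  n_atoms <- nrow(pos0)
  E_at <- function(pos) {
    ops <- .ops_fast(pos, spec)
    sum(D_converged * ops$h0_ortho) +
      0.5 * spec$U * sum(diag(D_converged)^2) + ops$e_rep
  }
  F_out <- matrix(0, n_atoms, 3)
  for (a in seq_len(n_atoms)) {
    for (c in 1:3) {
      pos <- pos0
      pos[a, c] <- pos0[a, c] + h
      E_plus <- E_at(pos)
      pos[a, c] <- pos0[a, c] - h
      E_minus <- E_at(pos)
      F_out[a, c] <- -(E_plus - E_minus) / (2 * h)
    }
  }
  F_out
}

#' Smooth SCF-free subspace trajectory
#'
#' Generates densities \eqn{D(t) = \mathrm{Exp}(\sum_j A_j \sin(\omega_j t +
#' \phi_j)\, \Gamma_j)} along known tangent directions, so the exact tangent
#' representative of every frame is available as ground truth for
#' extrapolation-accuracy tests without any SCF.
#'
#' @param C0 reference frame.
#' @param tangents list of at least two tangent matrices at \code{C0}.
#' @param amplitudes numeric vector, one per tangent direction.
#' @param frequencies numeric vector (rad per time unit).
#' @param times evaluation times.
#' @param phases phase offsets, default zero.
#' @return list with \code{densities} and the exact \code{tangents} per time.
#' @export
subspace_trajectory <- function(C0, tangents, amplitudes, frequencies, times,
                                phases = NULL) {
  stopifnot(length(tangents) >= 2,
            length(amplitudes) == length(tangents),
            length(frequencies) == length(tangents))
  if (is.null(phases)) phases <- numeric(length(tangents))
  out_d <- vector("list", length(times))
  out_g <- vector("list", length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    G <- Reduce(`+`, Map(function(A, w, p, Tj) A * sin(w * t + p) * Tj,
                         amplitudes, frequencies, phases, tangents))
    D <- grassmann_exp(G, C0)
    G_check <- grassmann_log(D, C0)
    if (max(abs(G_check - G)) > 1e-8)
      stop("trajectory amplitude too large: Log(D(t)) does not recover the tangent")
    out_d[[k]] <- D
    out_g[[k]] <- G
  }
  list(densities = out_d, tangents = out_g)
}

#' Default dynamics fixture: a mildly disordered 10-atom chain
#'
#' Unit-charge sites spaced near the model's equilibrium bond length with a
#' small seeded jitter, half filling (N = 5), and light (1 amu) atoms so that
#' bond vibrations have periods of a few tens of fs, well resolved by the
#' 0.5 fs time step. The system is gapped at half filling, so cold-start SCF
#' converges quickly.
#'
#' @param n_atoms chain length.
#' @param seed jitter seed.
#' @param spacing nominal bond length (Bohr).
#' @param jitter Gaussian positional disorder (Bohr).
#' @return list with \code{geometry}, \code{spec} and \code{masses}.
#' @export
chain_fixture <- function(n_atoms = 10L, seed = 1L, spacing = 2.35,
                          jitter = 0.08) {
  rng <- .with_seed(seed, {
    matrix(stats::rnorm(3 * n_atoms, sd = jitter), n_atoms, 3)
  })
  pos <- cbind((seq_len(n_atoms) - 1) * spacing, 0, 0) + rng
  g <- molecular_geometry(pos, charges = rep(1, n_atoms),
                          elements = rep("H", n_atoms))
  spec <- toy_model_spec(n_sites = n_atoms, N = max(1L, n_atoms %/% 2L))
  list(geometry = g, spec = spec, masses = rep(1.0, n_atoms))
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
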