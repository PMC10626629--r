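# Grassmann-manifold machinery for one-particle density matrices.
#
# A converged SCF density in a Lowdin-orthonormalized basis is a symmetric
# idempotent rank-N projector D = C C^T, i.e. a point on (a manifold isomorphic
# to) the Grassmann manifold Gr(N, n). All extrapolation happens in the tangent
# space at a fixed reference frame C0; the Exp/Log maps between the manifold
# and that tangent space are computed via thin SVDs.

#' Lowdin factorization of an overlap matrix
#'
#' Computes the symmetric square root \eqn{S^{1/2}} and its inverse
#' \eqn{S^{-1/2}} through a symmetric eigendecomposition. These factors convert
#' between atomic-orbital and orthonormal representations of coefficient
#' matrices and densities.
#'
#' @param S symmetric positive-definite overlap matrix.
#' @return an object of class \code{overlap_factor}: a list with components
#'   \code{s_half} and \code{s_inv_half}.
#' @export
lowdin_factor <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-10)
    stop("overlap matrix is not symmetric")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) <= 1e-10)
    stop(sprintf(
      "overlap matrix is numerically linearly dependent (smallest eigenvalue %.3e <= 1e-10)",
      min(e$values)))
  sq <- sqrt(e$values)
  V <- e$vectors
  out <- list(
    s_half     = V %*% (sq * t(V)),
    s_inv_half = V %*% ((1 / sq) * t(V))
  )
  # symmetrize away roundoff
  out$s_half <- (out$s_half + t(out$s_half)) / 2
  out$s_inv_half <- (out$s_inv_half + t(out$s_inv_half)) / 2
  class(out) <- "overlap_factor"
  out
}

#' Lowdin-orthonormalize molecular-orbital coefficients
#'
#' Transforms S-orthonormal atomic-orbital coefficients \code{C_ao} (satisfying
#' \eqn{C^T S C = I}) into an orthonormal frame \eqn{\tilde C = S^{1/2} C}.
#'
#' @param C_ao n x N coefficient matrix, S-orthonormal columns.
#' @param f \code{overlap_factor} from \code{\link{lowdin_factor}}.
#' @return n x N matrix with orthonormal columns.
#' @export
orthonormalize <- function(C_ao, f) {
  stopifnot(inherits(f, "overlap_factor"))
  S <- f$s_half %*% f$s_half
  G <- t(C_ao) %*% S %*% C_ao
  if (max(abs(G - diag(ncol(C_ao)))) > 1e-8)
    stop("input coefficients are not S-orthonormal (C^T S C != I)")
  f$s_half %*% C_ao
}

#' Undo Lowdin orthonormalization of a frame
#'
#' @param C orthonormal n x N frame.
#' @param f \code{overlap_factor}.
#' @return the atomic-orbital coefficients \eqn{S^{-1/2} C}.
#' @export
deorthonormalize <- function(C, f) {
  stopifnot(inherits(f, "overlap_factor"))
  f$s_inv_half %*% C
}

#' Density matrix of an orthonormal frame
#'
#' @param C n x N matrix with orthonormal columns.
#' @return the rank-N projector \eqn{D = C C^T}.
#' @export
density_from_frame <- function(C) {
  stopifnot(is.matrix(C))
  tcrossprod(C)
}

#' Recover an orthonormal frame from a projector
#'
#' Returns the eigenvectors of \code{D} with eigenvalue above 0.5. Converged
#' SCF densities are numerically idempotent, so eigenvalues cluster at 0 and 1;
#' anything inside the guard band [0.1, 0.9] signals a corrupted density.
#'
#' @param D symmetric idempotent matrix.
#' @return n x N matrix whose columns span the occupied subspace.
#' @export
frame_from_density <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("density matrix is not symmetric")
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  if (any(e$values > 0.1 & e$values < 0.9))
    stop("density is not numerically idempotent: eigenvalue inside [0.1, 0.9]")
  N <- round(sum(diag(D)))
  occ <- which(e$values > 0.5)
  if (length(occ) != N)
    stop(sprintf("density has %d eigenvalues above 0.5 but trace %d",
                 length(occ), N))
  e$vectors[, occ, drop = FALSE]
}

#' Grassmann logarithm at a fixed reference
#'
#' Maps a density matrix to its tangent-space representative \eqn{\Gamma} at
#' the reference frame \code{C0}. With \eqn{L = (I - C_0 C_0^T) C (C_0^T C)^{-1}}
#' and thin SVD \eqn{L = U \Sigma V^T}, the logarithm is
#' \eqn{\Gamma = U \arctan(\Sigma) V^T}. The result is independent of which
#' orthonormal frame \code{C} of \code{D} is used (gauge invariance).
#'
#' @param D symmetric idempotent density matrix.
#' @param C0 reference frame (n x N, orthonormal columns), fixed for a run.
#' @return n x N tangent matrix satisfying \eqn{C_0^T \Gamma = 0}.
#' @export
grassmann_log <- function(D, C0) {
  C <- frame_from_density(D)
  M <- crossprod(C0, C)                     # C0^T C, N x N
  if (kappa(M, exact = FALSE) >= 1e8)
    stop(paste("density is outside the injectivity domain of the logarithm",
               "at this reference (C0^T C ill-conditioned);",
               "restart with a new reference frame"))
  L <- (C - C0 %*% M) %*% solve(M)          # (I - C0 C0^T) C (C0^T C)^{-1}
  sv <- svd(L)
  G <- sv$u %*% (atan(sv$d) * t(sv$v))
  # exact tangency up to roundoff
  G - C0 %*% crossprod(C0, G)
}

#' Grassmann exponential at a fixed reference
#'
#' Maps a tangent matrix back to a density. With thin SVD
#' \eqn{\Gamma = U \Sigma V^T}, the exponential is the density of the frame
#' \eqn{(C_0 V \cos\Sigma + U \sin\Sigma) V^T}, which is orthonormal by
#' construction, so the output is an exact projector for any \eqn{\Gamma}.
#'
#' @param G n x N tangent matrix (must satisfy \eqn{C_0^T \Gamma = 0}).
#' @param C0 reference frame.
#' @return symmetric idempotent density matrix with trace N.
#' @export
grassmann_exp <- function(G, C0) {
  stopifnot(is.matrix(G), all(dim(G) == dim(C0)))
  if (max(abs(crossprod(C0, G))) > 1e-8)
    stop("input is not tangent at the reference frame (C0^T G != 0)")
  sv <- svd(G)
  Cn <- (C0 %*% sv$v) %*% (cos(sv$d) * t(sv$v)) + sv$u %*% (sin(sv$d) * t(sv$v))
  density_from_frame(Cn)
}

#' Tangency residual of a tangent-space representative
#'
#' @param G candidate tangent matrix.
#' @param C0 reference frame.
#' @return max-abs of \eqn{C_0^T G}.
#' @export
tangency_error <- function(G, C0) max(abs(crossprod(C0, G)))

#' Check the projector invariants of a density matrix
#'
#' @param D matrix to check.
#' @param tol tolerance on symmetry, idempotency and integer trace.
#' @return \code{TRUE} if \code{D} is symmetric, idempotent and has an integer
#'   trace within \code{tol}.
#' @export
is_projector <- function(D, tol = 1e-10) {
  is.matrix(D) && nrow(D) == ncol(D) &&
    max(abs(D - t(D))) < tol &&
    max(abs(D %*% D - D)) < tol &&
    abs(sum(diag(D)) - round(sum(diag(D)))) < tol
}
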