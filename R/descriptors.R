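# Coulomb-matrix molecular descriptors: the map R -> d from nuclear
# configurations to the vectors against which extrapolation coefficients are
# fitted. Atomic units throughout (Bohr, elementary charges).

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

.bohr_per_angstrom <- 1.8897259886

#' Look up nuclear charges for element symbols
#'
#' @param elements character vector of element symbols (Z <= 54).
#' @return numeric vector of nuclear charges.
#' @export
element_charges <- function(elements) {
  z <- match(elements, .element_symbols)
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(z)]), collapse = ", "))
  as.numeric(z)
}

#' Construct a molecular geometry
#'
#' @param positions N x 3 matrix of nuclear positions in Bohr.
#' @param charges nuclear charges; derived from \code{elements} if missing.
#' @param elements element symbols; defaults to \code{"X"} placeholders when
#'   only charges are given.
#' @return object of class \code{molecular_geometry}.
#' @export
molecular_geometry <- function(positions, charges = NULL, elements = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (is.null(charges)) {
    if (is.null(elements)) stop("supply charges or elements")
    charges <- element_charges(elements)
  }
  if (is.null(elements)) elements <- rep("X", nrow(positions))
  charges <- as.numeric(charges)
  stopifnot(length(charges) == nrow(positions),
            length(elements) == nrow(positions))
  if (any(charges <= 0)) stop("nuclear charges must be positive")
  d <- stats::dist(positions)
  if (length(d) && min(d) <= 1e-6)
    stop("degenerate geometry: coincident atoms (pairwise distance <= 1e-6 Bohr)")
  structure(list(positions = positions, charges = charges,
                 elements = elements),
            class = "molecular_geometry")
}

#' @export
print.molecular_geometry <- function(x, ...) {
  cat(sprintf("molecular_geometry: %d atoms (%s)\n", nrow(x$positions),
              paste(unique(x$elements), collapse = ", ")))
  invisible(x)
}

#' Coulomb matrix of a geometry
#'
#' Off-diagonal entries are \eqn{z_k z_l / \|R_k - R_l\|}; diagonal entries
#' follow the standard convention \eqn{0.5\, z_k^{2.4}}. The matrix is
#' invariant under rigid rotations and translations of the geometry.
#'
#' @param g \code{molecular_geometry}.
#' @return symmetric N x N matrix in atomic units.
#' @export
coulomb_matrix <- function(g) {
  stopifnot(inherits(g, "molecular_geometry"))
  z <- g$charges
  n <- length(z)
  R <- .pair_distances(g$positions)
  M <- outer(z, z) / (R + diag(n))   # diagonal placeholder, overwritten next
  diag(M) <- 0.5 * z^2.4
  (M + t(M)) / 2
}

#' Vectorize the lower triangle of a symmetric matrix
#'
#' Row-major concatenation of the entries (i, j) with j <= i, diagonal
#' included; for an N x N matrix the result has length N(N+1)/2.
#'
#' @param M symmetric matrix.
#' @return numeric descriptor vector.
#' @export
vectorize_lower <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > 1e-10) stop("matrix is not symmetric")
  M[upper.tri(M, diag = TRUE)]     # column-major upper == row-major lower
}

#' Coulomb-matrix descriptor of a geometry
#'
#' @param g \code{molecular_geometry}.
#' @return vectorized lower triangle of the Coulomb matrix, length
#'   \eqn{N(N+1)/2}.
#' @export
geometry_descriptor <- function(g) {
  vectorize_lower(coulomb_matrix(g))
}

#' Read a standard XYZ file
#'
#' Element symbol plus Angstrom coordinates per line; coordinates are
#' converted to Bohr.
#'
#' @param path file path.
#' @return \code{molecular_geometry}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  elements <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecular_geometry(xyz * .bohr_per_angstrom, elements = elements)
}

#' Write a standard XYZ file
#'
#' @param g \code{molecular_geometry} (positions in Bohr, written in Angstrom).
#' @param path file path.
#' @param comment comment line.
#' @export
write_xyz <- function(g, path, comment = "") {
  xyz <- g$positions / .bohr_per_angstrom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", nrow(xyz)), comment), con)
  writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                     g$elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  invisible(path)
}
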