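# Bounded history of converged SCF solutions: per step, the tangent-space
# representative Gamma = Log(D) and the Coulomb-matrix descriptor d. Only
# converged densities enter; the Grassmann logarithm is applied once per step
# and the stored Gamma is reused by every extrapolation that needs it.

#' Create an empty SCF history buffer
#'
#' @param capacity maximum number of retained entries (at least the largest
#'   history depth \code{q} any engine will request).
#' @return an environment of class \code{scf_history}.
#' @export
history_new <- function(capacity = 32L) {
  h <- new.env(parent = emptyenv())
  h$capacity <- as.integer(capacity)
  h$steps <- integer(0)
  h$gammas <- list()
  h$descriptors <- list()
  class(h) <- "scf_history"
  h
}

#' Append a converged step to a history buffer
#'
#' @param h \code{scf_history}.
#' @param step MD step index; must exceed all stored indices.
#' @param gamma tangent-space representative of the converged density.
#' @param descriptor Coulomb-matrix descriptor of the geometry.
#' @export
history_push <- function(h, step, gamma, descriptor) {
  stopifnot(inherits(h, "scf_history"))
  if (length(h$steps) && step <= max(h$steps))
    stop("history steps must be strictly increasing")
  h$steps <- c(h$steps, as.integer(step))
  h$gammas <- c(h$gammas, list(gamma))
  h$descriptors <- c(h$descriptors, list(descriptor))
  if (length(h$steps) > h$capacity) {
    keep <- seq.int(length(h$steps) - h$capacity + 1L, length(h$steps))
    h$steps <- h$steps[keep]
    h$gammas <- h$gammas[keep]
    h$descriptors <- h$descriptors[keep]
  }
  invisible(h)
}

#' Number of stored history entries
#' @param h \code{scf_history}.
#' @export
history_size <- function(h) length(h$steps)

#' Does the buffer hold q consecutive steps ending at n - 1?
#'
#' @param h \code{scf_history}.
#' @param n current step index (the step whose guess is being built).
#' @param q required history depth.
#' @return logical.
#' @export
history_ready <- function(h, n, q) {
  need <- seq.int(n - q, n - 1L)
  all(need %in% h$steps)
}

.history_gamma <- function(h, step) {
  i <- match(step, h$steps)
  if (is.na(i)) stop("no history entry for step ", step)
  h$gammas[[i]]
}

.history_descriptor <- function(h, step) {
  i <- match(step, h$steps)
  if (is.na(i)) stop("no history entry for step ", step)
  h$descriptors[[i]]
}
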