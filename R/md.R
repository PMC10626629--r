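# NVE Born-Oppenheimer dynamics with velocity Verlet and a pluggable SCF
# guess engine. Units: Bohr, fs, amu; energies logged in Hartree.

#' MD run configuration
#'
#' @param n_steps number of logged MD steps (equals the number of SCF solves).
#' @param dt time step in fs.
#' @param threshold SCF RMS convergence threshold.
#' @param temperature initial-velocity temperature (K).
#' @param seed velocity-sampling seed.
#' @param strategy guess engine: \code{"qtr"}, \code{"fully_tr"},
#'   \code{"gext"}, \code{"xlbo"}, \code{"previous"} or \code{"core"}.
#' @param q history depth; defaults per \code{\link{default_config}}.
#' @param epsilon regularization; defaults per \code{\link{default_config}}.
#' @param mixing SCF linear mixing.
#' @param purify_xlbo McWeeny-purify the XLBO guess before the SCF.
#' @param history_capacity retained (tangent, descriptor) snapshots; raise it
#'   to keep a whole short run for \code{\link{calibrate_parameters}}.
#' @return object of class \code{md_config}.
#' @export
md_config <- function(n_steps, dt = 0.5, threshold = 1e-5,
                      temperature = 300, seed = 1L, strategy = "qtr",
                      q = NULL, epsilon = NULL, mixing = 0.8,
                      purify_xlbo = TRUE, history_capacity = 64L) {
  stopifnot(dt > 0, n_steps >= 1)
  base <- default_config(threshold, strategy = "qtr")
  if (is.null(q)) q <- base$q
  if (is.null(epsilon)) epsilon <- if (strategy == "gext") 0.01 else base$epsilon
  cfg <- extrapolation_config(strategy, q = q, epsilon = epsilon,
                              purify_xlbo = purify_xlbo)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 threshold = threshold, temperature = temperature,
                 seed = as.integer(seed), engine = cfg, mixing = mixing,
                 history_capacity = as.integer(history_capacity)),
            class = "md_config")
}

#' Maxwell-Boltzmann initial velocities
#'
#' Per-component Gaussian velocities at the given temperature with the
#' centre-of-mass momentum removed; reproducible per seed and independent of
#' the caller's RNG stream.
#'
#' @param masses atomic masses (amu).
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @return N x 3 velocity matrix (Bohr/fs).
#' @export
init_velocities <- function(masses, temperature, seed) {
  stopifnot(temperature >= 0)
  n <- length(masses)
  v <- .with_seed(seed, {
    sd <- sqrt(.kB_internal * temperature / masses)
    matrix(stats::rnorm(3 * n, sd = rep(sd, 3)), n, 3)
  })
  p_com <- colSums(masses * v) / sum(masses)
  sweep(v, 2, p_com)
}

#' One velocity Verlet step
#'
#' Standard kick-drift-kick update; exactly time reversible for exact forces.
#'
#' @param positions N x 3 (Bohr).
#' @param velocities N x 3 (Bohr/fs).
#' @param masses amu.
#' @param forces_fn function(positions) returning N x 3 forces in
#'   Hartree/Bohr.
#' @param dt time step (fs).
#' @return list with updated \code{positions}, \code{velocities} and the
#'   \code{forces} at the new positions.
#' @export
velocity_verlet_step <- function(positions, velocities, masses, forces_fn,
                                 dt) {
  a <- .internal_per_hartree * forces_fn(positions) / masses
  v_half <- velocities + 0.5 * dt * a
  positions_new <- positions + dt * v_half
  a_new <- .internal_per_hartree * forces_fn(positions_new) / masses
  velocities_new <- v_half + 0.5 * dt * a_new
  list(positions = positions_new, velocities = velocities_new,
       forces = a_new * masses / .internal_per_hartree)
}

.kinetic_energy <- function(v, masses) {
  0.5 * sum(masses * v^2) / .internal_per_hartree
}

# Internal engine driver: owns history, reference frame, per-strategy state.
.engine_new <- function(cfg, capacity = 64L) {
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$history <- history_new(capacity)
  e$C0 <- NULL
  e$previous <- NULL
  e$xlbo <- if (cfg$strategy == "xlbo") xlbo_state_new() else NULL
  e$xlbo_next <- NULL          # pending purified/raw XLBO guess
  e$xlbo_count <- 0L           # updates seen; first 9 guesses are warm-up
  e$guess_store <- list()      # fully_tr: emitted guess tangents by step
  e
}

# Returns list(guess = density or NULL, cold_start = logical).
.engine_guess <- function(e, d_n, n) {
  cfg <- e$cfg
  if (is.null(e$previous))
    return(list(guess = NULL, cold_start = TRUE))
  cold <- function() list(guess = cold_start_guess(e$previous),
                          cold_start = TRUE)
  switch(cfg$strategy,
    core = list(guess = NULL, cold_start = TRUE),
    previous = list(guess = e$previous, cold_start = FALSE),
    xlbo = {
      if (is.null(e$xlbo_next)) cold()
      else list(guess = e$xlbo_next, cold_start = e$xlbo_count <= 9L)
    },
    gext = {
      g <- gext_guess(e$history, d_n, n, e$C0, q = cfg$q,
                      epsilon = cfg$epsilon)
      if (is.null(g)) cold() else list(guess = g, cold_start = FALSE)
    },
    qtr = {
      g <- qtr_guess(e$history, d_n, n, cfg, e$C0)
      if (is.null(g)) cold() else list(guess = g, cold_start = FALSE)
    },
    fully_tr = {
      sys <- build_ls_system(e$history, d_n, n, cfg)
      if (is.null(sys)) return(cold())
      alpha <- solve_tikhonov(sys$A, sys$b, epsilon = 0)
      G <- fully_tr_tangent(e$history, alpha, n, cfg, e$guess_store)
      e$guess_store[[as.character(n)]] <- G
      if (length(e$guess_store) > cfg$q + 4L)
        e$guess_store[[1L]] <- NULL
      list(guess = grassmann_exp(G, e$C0), cold_start = FALSE)
    })
}

# Record a converged density for step n. The (tangent, descriptor) history is
# maintained for every strategy so a finished run can seed the grid-search
# calibration of (q, epsilon).
.engine_update <- function(e, D, d_n, n) {
  cfg <- e$cfg
  e$previous <- D
  if (is.null(e$C0)) e$C0 <- frame_from_density(D)
  history_push(e$history, n, grassmann_log(D, e$C0), d_n)
  if (cfg$strategy == "xlbo") {
    st <- xlbo_step(e$xlbo, D)
    e$xlbo <- st$state
    e$xlbo_count <- e$xlbo_count + 1L
    e$xlbo_next <- if (cfg$purify_xlbo) mcweeny_purify(st$guess) else st$guess
  }
  invisible(e)
}

#' Run NVE Born-Oppenheimer dynamics on the toy model
#'
#' Per step: obtain a guess density from the engine (cold start while the
#' history warms up), converge the SCF, evaluate finite-difference forces,
#' advance with velocity Verlet, and append the converged tangent and
#' descriptor to the engine history. The run aborts cleanly on SCF failure,
#' returning the logs accumulated so far.
#'
#' @param g0 initial \code{molecular_geometry}.
#' @param masses atomic masses (amu).
#' @param spec \code{toy_model_spec}.
#' @param cfg \code{md_config}.
#' @param velocities optional initial velocities (Bohr/fs); sampled from
#'   \code{\link{init_velocities}} when \code{NULL}.
#' @return object of class \code{bomd_run}: \code{logs} data frame (columns
#'   step, time_fs, epot, ekin, etot, scf_iterations, converged, cold_start),
#'   \code{positions} (list of per-step position matrices),
#'   \code{guess_diagnostics} (per-step idempotency and trace residuals of
#'   the emitted guess densities), final \code{state}, the stored
#'   (tangent, descriptor) \code{history}, the \code{config}, and
#'   \code{aborted}.
#' @export
run_bomd <- function(g0, masses, spec, cfg, velocities = NULL) {
  stopifnot(inherits(cfg, "md_config"))
  n_steps <- cfg$n_steps
  dt <- cfg$dt
  R <- g0$positions
  v <- if (is.null(velocities))
    init_velocities(masses, cfg$temperature, cfg$seed) else velocities
  engine <- .engine_new(cfg$engine, capacity = cfg$history_capacity)
  epot_v <- ekin_v <- numeric(n_steps)
  iters_v <- integer(n_steps)
  cold_v <- logical(n_steps)
  gidem_v <- gtrace_v <- rep(NA_real_, n_steps)
  pos_list <- vector("list", n_steps)
  n_done <- 0L
  v_half <- NULL
  aborted <- FALSE
  g <- g0
  for (k in seq_len(n_steps) - 1L) {
    g$positions <- R
    d_n <- geometry_descriptor(g)
    gs <- .engine_guess(engine, d_n, k)
    if (!is.null(gs$guess)) {
      gidem_v[k + 1L] <- max(abs(gs$guess %*% gs$guess - gs$guess))
      gtrace_v[k + 1L] <- abs(sum(diag(gs$guess)) - spec$N)
    }
    scf <- tryCatch(
      scf_solve(g, spec, guess = gs$guess, threshold = cfg$threshold,
                mixing = cfg$mixing),
      error = function(err) err)
    if (inherits(scf, "error")) {
      warning(sprintf("run aborted at step %d: %s", k,
                      conditionMessage(scf)))
      aborted <- TRUE
      break
    }
    .engine_update(engine, scf$density, d_n, k)
    Fmat <- forces(g, spec, scf$density)
    a <- .internal_per_hartree * Fmat / masses
    if (!is.null(v_half)) v <- v_half + 0.5 * dt * a
    epot <- potential_energy(g, spec, scf)
    ekin <- .kinetic_energy(v, masses)
    if (!is.finite(epot) || !is.finite(ekin)) {
      warning(sprintf("run aborted at step %d: non-finite energy", k))
      aborted <- TRUE
      break
    }
    n_done <- k + 1L
    epot_v[n_done] <- epot
    ekin_v[n_done] <- ekin
    iters_v[n_done] <- scf$iterations
    cold_v[n_done] <- gs$cold_start
    pos_list[[n_done]] <- R
    if (k < n_steps - 1L) {
      v_half <- v + 0.5 * dt * a
      R <- R + dt * v_half
    }
  }
  idx <- seq_len(n_done)
  logs <- data.frame(
    step = idx - 1L, time_fs = (idx - 1L) * dt, epot = epot_v[idx],
    ekin = ekin_v[idx], etot = epot_v[idx] + ekin_v[idx],
    scf_iterations = iters_v[idx], converged = TRUE,
    cold_start = cold_v[idx])
  pos_list <- pos_list[idx]
  structure(list(logs = logs, positions = pos_list,
                 guess_diagnostics = data.frame(
                   step = idx - 1L, idempotency_error = gidem_v[idx],
                   trace_error = gtrace_v[idx], cold_start = cold_v[idx]),
                 state = list(positions = R, velocities = v,
                              masses = masses),
                 geometry = g0, spec = spec, config = cfg,
                 history = list(steps = engine$history$steps,
                                gammas = engine$history$gammas,
                                descriptors = engine$history$descriptors),
                 aborted = aborted),
            class = "bomd_run")
}

#' @export
print.bomd_run <- function(x, ...) {
  cat(sprintf(
    "bomd_run: %d steps (%s engine, threshold %.0e)%s\n",
    nrow(x$logs), x$config$engine$strategy, x$config$threshold,
    if (x$aborted) " [aborted]" else ""))
  if (nrow(x$logs) > 1) {
    el <- iteration_stats(x$logs, x$config$engine$q)
    cat(sprintf("  mean SCF iterations %.3f (sd %.3f), etot drift %.3e Ha/fs\n",
                el[1], el[2], ltd(x$logs$time_fs, x$logs$etot)))
  }
  invisible(x)
}

#' Calibrate history depth and regularization for a system
#'
#' Runs a short warm-up trajectory (previous-density guesses) under the
#' production settings, then replays the symmetric extrapolation over the
#' stored (tangent, descriptor) snapshots for every grid pair and picks the
#' error-minimizing \code{(q, epsilon)} — the per-system heuristic the
#' extrapolation method prescribes before production dynamics.
#'
#' @param g0 initial \code{molecular_geometry}.
#' @param masses atomic masses (amu).
#' @param spec \code{toy_model_spec}.
#' @param threshold production SCF threshold.
#' @param n_steps warm-up trajectory length (must exceed \code{max(q_grid)}).
#' @param seed velocity seed.
#' @param temperature initial temperature (K).
#' @param dt time step (fs).
#' @param q_grid,eps_grid search grids, see \code{\link{select_parameters}}.
#' @return list with \code{q}, \code{epsilon}, the error grid, and the
#'   warm-up \code{run}.
#' @export
calibrate_parameters <- function(g0, masses, spec, threshold = 1e-5,
                                 n_steps = 150L, seed = 1L,
                                 temperature = 300, dt = 0.5,
                                 q_grid = 3:20,
                                 eps_grid = c(0.001, 0.002, 0.005, 0.01,
                                              0.02, 0.05)) {
  cfg <- md_config(n_steps = n_steps, dt = dt, threshold = threshold,
                   temperature = temperature, seed = seed,
                   strategy = "previous",
                   history_capacity = n_steps + 1L)
  run <- run_bomd(g0, masses, spec, cfg)
  sel <- select_parameters(run$history$gammas, run$history$descriptors,
                           q_grid = q_grid, eps_grid = eps_grid)
  c(sel, list(run = run))
}

#' Retrace a completed run backwards
#'
#' Negates the final velocities, integrates the same number of steps with a
#' fresh engine of the same strategy, and reports the maximum position
#' deviation from the forward trajectory read in reverse. For exact
#' (tightly converged) forces the velocity Verlet integrator is time
#' reversible, so the retrace error isolates the guess-induced force bias.
#'
#' @param run completed \code{bomd_run}.
#' @return list with \code{max_deviation} (Bohr), the per-step
#'   \code{deviations}, and the reverse \code{run}.
#' @export
reverse_run <- function(run) {
  stopifnot(inherits(run, "bomd_run"), !run$aborted)
  g_end <- run$geometry
  g_end$positions <- run$state$positions
  cfg <- run$config
  back <- run_bomd(g_end, run$state$masses, run$spec, cfg,
                   velocities = -run$state$velocities)
  n <- min(length(back$positions), length(run$positions))
  dev <- vapply(seq_len(n), function(j) {
    max(abs(back$positions[[j]] -
            run$positions[[length(run$positions) - j + 1L]]))
  }, numeric(1))
  list(max_deviation = max(dev), deviations = dev, run = back)
}
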