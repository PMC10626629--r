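# Energy-stability and performance diagnostics: short-time fluctuation (STF),
# long-time drift (LTD), SCF iteration statistics and moving averages, plus
# CSV/text reporting.

#' Short-time fluctuation of a total-energy series
#'
#' Partitions the series into consecutive non-overlapping windows of the given
#' width (anchored at the first logged time; a trailing partial window is
#' dropped), takes the RMS deviation from the window mean inside each window,
#' and averages over the windows.
#'
#' @param times times (fs), strictly increasing.
#' @param energies total energies, same length and units as the run.
#' @param window window width (fs), default 50.
#' @return mean windowed RMS fluctuation (energy units).
#' @export
stf <- function(times, energies, window = 50) {
  stopifnot(length(times) == length(energies), length(times) >= 2,
            all(diff(times) > 0))
  span <- times[length(times)] - times[1]
  dt_med <- stats::median(diff(times))
  n_win <- floor((span + dt_med / 2) / window)
  if (n_win < 1)
    stop("energy series shorter than one window")
  bin <- floor((times - times[1]) / window)
  keep <- bin < n_win
  rms <- tapply(energies[keep], bin[keep],
                function(e) sqrt(mean((e - mean(e))^2)))
  mean(rms)
}

#' Long-time drift of a total-energy series
#'
#' Slope of the ordinary least-squares regression line of total energy
#' against time over the full series.
#'
#' @param times times (fs).
#' @param energies total energies.
#' @return drift in energy units per time unit.
#' @export
ltd <- function(times, energies) {
  stopifnot(length(times) == length(energies))
  if (length(times) < 2) stop("need at least two points for a drift slope")
  unname(stats::coef(stats::lm(energies ~ times))[2])
}

#' SCF iteration statistics of a run
#'
#' Mean and population standard deviation of the per-step SCF iteration
#' counts, discarding the first \code{q} steps and any step served by a
#' cold-start guess (history warm-up).
#'
#' @param logs step-log data frame with columns \code{step},
#'   \code{scf_iterations} and \code{cold_start}.
#' @param q number of leading steps to discard.
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
iteration_stats <- function(logs, q) {
  eligible <- logs$step >= q & !logs$cold_start
  if (!any(eligible)) stop("no eligible steps after discarding warm-up")
  x <- logs$scf_iterations[eligible]
  m <- mean(x)
  c(mean = m, sd = sqrt(mean((x - m)^2)))
}

#' Centered moving average with shrinking edge windows
#'
#' @param values numeric vector.
#' @param window nominal window length (>= 1); at the edges the window
#'   shrinks so the output has the same length as the input.
#' @return smoothed vector.
#' @export
moving_average <- function(values, window = 25L) {
  stopifnot(window >= 1)
  n <- length(values)
  left <- (as.integer(window) - 1L) %/% 2L
  right <- as.integer(window) - 1L - left
  vapply(seq_len(n), function(i) {
    mean(values[max(1L, i - left):min(n, i + right)])
  }, numeric(1))
}

#' Stability report of a single run
#'
#' @param run \code{bomd_run} (or a step-log data frame).
#' @param q warm-up steps to discard in the iteration statistics; defaults to
#'   the run's history depth.
#' @param window STF window (fs).
#' @return object of class \code{stability_report}: \code{stf}, \code{ltd},
#'   \code{n_windows}, \code{mean_iterations}, \code{std_iterations}.
#' @export
stability_report <- function(run, q = NULL, window = 50) {
  logs <- if (inherits(run, "bomd_run")) run$logs else run
  if (is.null(q)) {
    q <- if (inherits(run, "bomd_run")) run$config$engine$q else 5L
  }
  it <- iteration_stats(logs, q)
  span <- logs$time_fs[nrow(logs)] - logs$time_fs[1]
  structure(list(
    stf = stf(logs$time_fs, logs$etot, window),
    ltd = ltd(logs$time_fs, logs$etot),
    n_windows = max(1L, floor(span / window)),
    mean_iterations = unname(it["mean"]),
    std_iterations = unname(it["sd"])),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability_report: STF %.4e, LTD %.4e per fs (%d windows), iterations %.2f +/- %.2f\n",
    x$stf, x$ltd, x$n_windows, x$mean_iterations, x$std_iterations))
  invisible(x)
}

#' Side-by-side comparison of guess strategies
#'
#' One row per run with STF, LTD and iteration statistics. Runs with
#' different step counts are compared on their common prefix (with a
#' warning).
#'
#' @param runs named list of \code{bomd_run} objects (names label the rows).
#' @param q warm-up discard; default from each run's configuration.
#' @param window STF window (fs).
#' @return data frame of class \code{stability_table}.
#' @export
compare_report <- function(runs, q = NULL, window = 50) {
  stopifnot(length(runs) >= 1)
  if (is.null(names(runs)))
    names(runs) <- vapply(runs, function(r) r$config$engine$strategy, "")
  n_steps <- vapply(runs, function(r) nrow(r$logs), integer(1))
  n_common <- min(n_steps)
  if (length(unique(n_steps)) > 1)
    warning("runs have different step counts; comparing the common prefix of ",
            n_common, " steps")
  rows <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    logs <- r$logs[seq_len(n_common), , drop = FALSE]
    qq <- if (is.null(q)) r$config$engine$q else q
    rep_ <- stability_report(logs, q = qq, window = window)
    data.frame(strategy = nm, stf = rep_$stf, ltd = rep_$ltd,
               mean_iterations = rep_$mean_iterations,
               std_iterations = rep_$std_iterations,
               n_steps = n_common)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' @export
print.stability_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("%-10s %12s %14s %10s %8s %8s\n",
              "strategy", "STF", "LTD/fs", "k_mean", "k_sd", "steps"))
  for (i in seq_len(nrow(df)))
    cat(sprintf("%-10s %12.4e %14.4e %10.3f %8.3f %8d\n",
                df$strategy[i], df$stf[i], df$ltd[i],
                df$mean_iterations[i], df$std_iterations[i], df$n_steps[i]))
  invisible(x)
}

#' Write a step log as CSV
#'
#' Columns: step, time_fs, epot, ekin, etot, scf_iterations, converged,
#' cold_start.
#'
#' @param run \code{bomd_run} or step-log data frame.
#' @param path output file.
#' @export
write_step_log <- function(run, path) {
  logs <- if (inherits(run, "bomd_run")) run$logs else run
  out <- logs
  for (cn in names(out))
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step log written by \code{\link{write_step_log}}
#'
#' @param path CSV file.
#' @return step-log data frame.
#' @export
read_step_log <- function(path) {
  utils::read.csv(path)
}

#' Write a trajectory as extended XYZ
#'
#' One frame per logged step; the comment line carries step index, time and
#' total energy.
#'
#' @param run \code{bomd_run}.
#' @param path output file.
#' @export
write_trajectory_xyz <- function(run, path) {
  g <- run$geometry
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(run$positions)) {
    xyz <- run$positions[[k]] / .bohr_per_angstrom
    writeLines(sprintf("%d", nrow(xyz)), con)
    writeLines(sprintf("step=%d time_fs=%.4f etot=%.12f",
                       run$logs$step[k], run$logs$time_fs[k],
                       run$logs$etot[k]), con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       g$elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Round-trip a JSON run configuration
#'
#' Reads a JSON configuration of the form
#' \code{{"strategy": "...", "q": ..., "epsilon": ..., "purify_xlbo": ...,
#' "seed": ..., "n_steps": ..., "dt": ..., "threshold": ...,
#' "temperature": ...}} and returns the matching \code{md_config}; missing
#' fields take the package defaults.
#'
#' @param path JSON file.
#' @return \code{md_config}.
#' @export
read_md_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  md_config(
    n_steps = if (is.null(j$n_steps)) 100L else j$n_steps,
    dt = if (is.null(j$dt)) 0.5 else j$dt,
    threshold = if (is.null(j$threshold)) 1e-5 else j$threshold,
    temperature = if (is.null(j$temperature)) 300 else j$temperature,
    seed = if (is.null(j$seed)) 1L else j$seed,
    strategy = if (is.null(j$strategy)) "qtr" else j$strategy,
    q = j$q, epsilon = j$epsilon,
    purify_xlbo = if (is.null(j$purify_xlbo)) TRUE else j$purify_xlbo)
}

#' Echo an MD configuration to JSON
#'
#' @param cfg \code{md_config}.
#' @param path output file.
#' @export
write_md_config <- function(cfg, path) {
  jsonlite::write_json(
    list(strategy = cfg$engine$strategy, q = cfg$engine$q,
         epsilon = cfg$engine$epsilon, purify_xlbo = cfg$engine$purify_xlbo,
         seed = cfg$seed, n_steps = cfg$n_steps, dt = cfg$dt,
         threshold = cfg$threshold, temperature = cfg$temperature),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
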