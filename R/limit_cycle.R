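# Limit-cycle observables: stiff integration, peak-based period extraction
# and period curves. Time is in the system's native unit (minutes for the
# NF-kB model).

#' Integrate an ODE system
#'
#' Stiff-capable integration with `deSolve::lsoda` at tight tolerances
#' (defaults `rtol 1e-8`, `atol 1e-12`). When the system carries a compiled
#' backend the C right-hand side is used. Output is sampled densely enough
#' for sub-grid peak refinement.
#'
#' @param sys an [ode_system()].
#' @param init initial state; defaults to zeros.
#' @param t_end integration horizon (system time units); `0` returns the
#'   initial state only.
#' @param n_out number of output samples (default gives step
#'   `t_end/4000`).
#' @param dt output sampling step; overrides `n_out`.
#' @param rtol,atol integrator tolerances.
#' @return A tibble with column `time` and one column per state.
#' @export
simulate <- function(sys, init = NULL, t_end, n_out = 4000, dt = NULL,
                     rtol = 1e-8, atol = 1e-12) {
  init <- init %||% setNames(numeric(sys$dim), sys$state_names)
  stopifnot(length(init) == sys$dim, t_end >= 0)
  if (t_end == 0) {
    out <- tibble(time = 0)
    out[sys$state_names] <- as.list(as.numeric(init))
    return(out)
  }
  times <- if (!is.null(dt)) seq(0, t_end, by = dt) else {
    seq(0, t_end, length.out = max(2L, n_out + 1L))
  }
  y0 <- setNames(as.numeric(init), sys$state_names)
  raw <- if (!is.null(sys$compiled)) {
    deSolve::lsoda(y0, times, func = sys$compiled$func,
                   parms = sys$compiled$parms(sys$pars),
                   dllname = sys$compiled$dllname,
                   initfunc = sys$compiled$initfunc,
                   rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    deSolve::lsoda(y0, times,
                   func = function(t, y, p) list(sys$rhs(y, p)),
                   parms = sys$pars, rtol = rtol, atol = atol,
                   maxsteps = 50000)
  }
  diagn <- attr(raw, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(sprintf("simulate: integrator failed (istate %d) at t ~ %.4g",
                  diagn[1], raw[nrow(raw), 1]),
          class = "nfkbosc_integrator_error")
  }
  out <- as_tibble(as.data.frame(raw))
  names(out)[1] <- "time"
  out
}

# Quadratically refined local maxima of x(t) on a uniform grid.
# Returns a data.frame with refined times and heights.
find_peaks <- function(t, x, minima = FALSE) {
  if (minima) x <- -x
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(), value = numeric()))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(i)) return(data.frame(time = numeric(), value = numeric()))
  a <- x[i - 1L]; b <- x[i]; cc <- x[i + 1L]
  denom <- a - 2 * b + cc
  shift <- ifelse(abs(denom) > 0, 0.5 * (a - cc) / denom, 0)
  dt <- t[2] - t[1]
  tp <- t[i] + shift * dt
  vp <- b - 0.25 * (a - cc) * shift
  if (minima) vp <- -vp
  data.frame(time = tp, value = vp)
}

#' Extract the oscillation period from a simulated time series
#'
#' Discards a transient, finds refined peaks of the chosen species, and
#' reports the mean inter-peak interval. The result is flagged `converged`
#' only when successive inter-peak intervals agree to 0.1%, and
#' `sustained` only when the peak-to-trough amplitude is steady (ratio of
#' successive amplitudes within `[0.999, 1.001]` over the last 5 cycles) —
#' slowly damped oscillations near the bifurcation can masquerade as
#' sustained otherwise. Fewer than 3 post-transient peaks yields a
#' non-oscillatory result (period `NA`), not an error.
#'
#' @param sim a [simulate()] result.
#' @param species observable column (default nuclear NF-kB for the NF-kB
#'   model; otherwise the first state).
#' @param transient initial stretch to discard (time units).
#' @return A one-row tibble of class `limit_cycle_summary`: `period`,
#'   `converged`, `sustained`, `n_peaks`, and `<species>_max`/`_min`
#'   envelope columns for every state column.
#' @export
extract_period <- function(sim, species = NULL, transient = 2000) {
  state_cols <- setdiff(names(sim), "time")
  species <- species %||% if ("NFkBn" %in% state_cols) "NFkBn" else state_cols[1]
  stopifnot(species %in% state_cols)
  keep <- sim$time >= transient
  tt <- sim$time[keep]
  xx <- sim[[species]][keep]

  env <- as.list(setNames(rep(NA_real_, 2 * length(state_cols)),
                          c(paste0(state_cols, "_max"),
                            paste0(state_cols, "_min"))))
  base <- function(period, conv, sust, n) {
    out <- tibble(period = period, converged = conv, sustained = sust,
                  n_peaks = n)
    out[names(env)] <- env
    class(out) <- c("limit_cycle_summary", class(out))
    out
  }
  if (length(tt) < 10) return(base(NA_real_, FALSE, FALSE, 0L))

  peaks <- find_peaks(tt, xx)
  troughs <- find_peaks(tt, xx, minima = TRUE)
  # ignore numerically flat ripples around an equilibrium
  if (nrow(peaks) >= 1 && nrow(troughs) >= 1) {
    span <- max(peaks$value) - min(troughs$value)
    flat <- span < 1e-9 * max(abs(xx), 1e-12)
    if (flat) return(base(NA_real_, FALSE, FALSE, 0L))
  }
  if (nrow(peaks) < 3) return(base(NA_real_, FALSE, FALSE, nrow(peaks)))

  intervals <- diff(peaks$time)
  period <- mean(intervals)
  conv <- length(intervals) >= 2 &&
    max(abs(intervals - period)) / period < 1e-3

  # amplitude steadiness over the final 5 cycles
  sust <- FALSE
  n5 <- min(nrow(peaks) - 1L, nrow(troughs), 5L)
  if (n5 >= 2) {
    pk <- tail(peaks$value, n5 + 1L)
    tr <- tail(troughs$value, n5)
    amp <- head(pk, n5) - tr
    ratios <- amp[-1] / amp[-length(amp)]
    sust <- all(ratios > 0.999 & ratios < 1.001)
  }

  # per-species envelope over the final full cycle
  t_last <- tail(peaks$time, 2)
  win <- sim$time >= t_last[1] & sim$time <= t_last[2]
  for (sp in state_cols) {
    env[[paste0(sp, "_max")]] <- max(sim[[sp]][win])
    env[[paste0(sp, "_min")]] <- min(sim[[sp]][win])
  }
  base(period, conv, sust, nrow(peaks))
}

#' Period of the sustained oscillation of an ODE system
#'
#' Convenience wrapper: integrate past the transient, extract the period,
#' and extend the horizon (up to `t_max`) until the convergence criterion
#' holds. Returns the [extract_period()] summary.
#'
#' @param sys an [ode_system()].
#' @param init initial state (defaults to zeros).
#' @param species observable for peak detection.
#' @param transient discarded initial stretch (time units).
#' @param window initial measurement window after the transient.
#' @param t_max hard cap on the total horizon.
#' @param dt output sampling step.
#' @param rtol,atol integrator tolerances.
#' @return A `limit_cycle_summary` tibble (one row).
#' @export
oscillation_period <- function(sys, init = NULL, species = NULL,
                               transient = 2000, window = 2000,
                               t_max = 20000, dt = 0.5,
                               rtol = 1e-8, atol = 1e-12) {
  t_end <- transient + window
  repeat {
    sim <- simulate(sys, init = init, t_end = t_end, dt = dt,
                    rtol = rtol, atol = atol)
    res <- extract_period(sim, species = species, transient = transient)
    if ((res$converged && res$n_peaks >= 6) || t_end >= t_max) return(res)
    t_end <- min(2 * t_end, t_max)
  }
}

#' Period as a function of a parameter
#'
#' Runs [oscillation_period()] on a grid of parameter values.
#' Non-oscillatory grid points are flagged (period `NA`, `oscillatory =
#' FALSE`), never dropped.
#'
#' @param sys an [ode_system()].
#' @param par_name parameter to vary.
#' @param grid numeric vector of parameter values.
#' @param ... passed to [oscillation_period()].
#' @return A tibble with `param_value`, `period`, `oscillatory`,
#'   `converged`, `sustained` and the envelope columns.
#' @export
period_curve <- function(sys, par_name, grid, ...) {
  rows <- lapply(grid, function(v) {
    res <- oscillation_period(set_par(sys, par_name, v), ...)
    dplyr::bind_cols(tibble(param_value = v,
                            oscillatory = !is.na(res$period)), res)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "par_name") <- par_name
  class(out) <- c("period_curve", class(out))
  out
}
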