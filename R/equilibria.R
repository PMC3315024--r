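# Equilibria, stability, one-parameter continuation and Hopf detection.
#
# Eigenvalue conventions: the "leading complex pair" of an equilibrium is
# the complex-conjugate eigenvalue pair with the largest real part; a Hopf
# bifurcation is a parameter value where that real part crosses zero while
# the imaginary part stays bounded away from zero. Real-eigenvalue
# crossings (folds) are excluded from Hopf refinement.

.IM_TOL <- 1e-12      # |Im| above this counts as a complex eigenvalue
.HYP_TOL <- 1e-8      # |Re| below this counts as non-hyperbolic

#' Newton solve for an equilibrium
#'
#' Damped Newton iteration on the right-hand side of `sys` from `guess`.
#' Non-convergence is reported, not raised: callers fall back to long-time
#' integration for a fresh guess. With `integrate_fallback = TRUE` that
#' fallback (integration for `t_settle` time units, then Newton again) is
#' applied automatically.
#'
#' @param sys an [ode_system()].
#' @param guess starting state vector.
#' @param tol residual tolerance (max-norm of the right-hand side).
#' @param max_iter maximum Newton iterations.
#' @param integrate_fallback integrate towards the attractor if Newton
#'   fails from `guess`.
#' @param t_settle integration horizon for the fallback.
#' @return An object of class `equilibrium`: a list with `state`,
#'   `eigenvalues`, `stability`, `residual`, `converged`, `iterations`.
#' @export
find_equilibrium <- function(sys, guess, tol = 1e-11, max_iter = 50,
                             integrate_fallback = FALSE, t_settle = 5e4) {
  res <- newton_solve(sys, guess, tol = tol, max_iter = max_iter)
  if (!res$converged && integrate_fallback) {
    sim <- simulate(sys, init = guess, t_end = t_settle,
                    n_out = 200, rtol = 1e-8, atol = 1e-12)
    endpoint <- as.numeric(sim[nrow(sim), sys$state_names])
    res <- newton_solve(sys, endpoint, tol = tol, max_iter = max_iter)
  }
  J <- system_jacobian(sys, res$state)
  ev <- eigen(J, only.values = TRUE)$values
  structure(
    list(state = setNames(res$state, sys$state_names),
         eigenvalues = ev,
         stability = classify_stability(ev),
         residual = res$residual,
         converged = res$converged,
         iterations = res$iterations),
    class = "equilibrium"
  )
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium: %s, residual %.2e%s>\n", x$stability,
              x$residual, if (x$converged) "" else ", NOT converged"))
  print(round(x$state, 6))
  invisible(x)
}

newton_solve <- function(sys, y, tol = 1e-11, max_iter = 50) {
  y <- as.numeric(y)
  f <- sys$rhs(y, sys$pars)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) {
      return(list(state = y, residual = max(abs(f)), converged = TRUE,
                  iterations = it - 1L))
    }
    J <- system_jacobian(sys, y)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {                      # backtracking on the residual norm
      y_new <- y - lambda * step
      f_new <- sys$rhs(y_new, sys$pars)
      if (all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f)) || lambda < 1 / 64)) break
      lambda <- lambda / 2
    }
    y <- y_new
    f <- f_new
  }
  list(state = y, residual = max(abs(f)), converged = max(abs(f)) < tol,
       iterations = max_iter)
}

#' Linear stability class from eigenvalues
#'
#' `stable-focus` when all real parts are negative and some eigenvalue has
#' a non-zero imaginary part (damped oscillatory approach), `stable-node`
#' when all real parts are negative and all eigenvalues are real,
#' `unstable` when some real part is positive, and `non-hyperbolic` when
#' the largest |Re| among the leading eigenvalues is below `tol`.
#'
#' @param eigenvalues complex eigenvalue vector.
#' @param tol non-hyperbolicity tolerance on |Re|.
#' @return One of `"stable-node"`, `"stable-focus"`, `"unstable"`,
#'   `"non-hyperbolic"`.
#' @export
classify_stability <- function(eigenvalues, tol = .HYP_TOL) {
  re <- Re(eigenvalues)
  if (max(abs(re)) < tol || abs(max(re)) < tol) return("non-hyperbolic")
  if (max(re) > 0) return("unstable")
  if (any(abs(Im(eigenvalues)) > .IM_TOL)) "stable-focus" else "stable-node"
}

# real part / frequency of the leading complex pair (NA when none)
leading_complex <- function(ev) {
  cplx <- ev[abs(Im(ev)) > .IM_TOL]
  if (!length(cplx)) return(c(re = NA_real_, im = NA_real_))
  i <- which.max(Re(cplx))
  c(re = Re(cplx[i]), im = abs(Im(cplx[i])))
}

#' Continue an equilibrium branch in one parameter
#'
#' Natural-parameter continuation with adaptive step control: the step is
#' halved when Newton needs more than `easy_iter` iterations or when the
#' leading complex pair changes stability within a step (so stability
#' changes are bracketed tightly), and grown by 1.3 after easy steps. If
#' Newton fails even at the minimum step, a pseudo-arclength corrector is
#' tried so that folds can be traversed; if that also fails the branch is
#' truncated with a message.
#'
#' @param sys an [ode_system()].
#' @param par_name name of the continuation parameter.
#' @param range numeric `c(from, to)`; continuation runs from `from` to
#'   `to` (either direction).
#' @param guess equilibrium state at `from` (or a good starting guess).
#' @param step0 initial step (default 1/100 of the range width).
#' @param min_step smallest step accepted (default `step0/4096`).
#' @param refine_step step below which stability changes are no longer
#'   re-bracketed by halving (default `step0/16`).
#' @param max_points safety cap on branch length.
#' @return A tibble of class `bifurcation_branch`: one row per equilibrium
#'   with the parameter value, state columns, `max_re_eig` and
#'   `freq_im_eig` of the leading complex pair, and `stability`.
#'   Attributes `par_name`, `sys` and `truncated` are attached.
#' @export
continue_branch <- function(sys, par_name, range, guess,
                            step0 = NULL, min_step = NULL,
                            refine_step = NULL, max_points = 5000) {
  from <- range[1]; to <- range[2]
  width <- abs(to - from)
  stopifnot(width > 0)
  dir <- sign(to - from)
  step0 <- step0 %||% (width / 100)
  min_step <- min_step %||% (step0 / 4096)
  refine_step <- refine_step %||% (step0 / 16)

  sys <- set_par(sys, par_name, from)
  eq <- find_equilibrium(sys, guess)
  if (!eq$converged) {
    abort("continue_branch: no equilibrium at the start of the range")
  }

  rows <- vector("list", 0L)
  push <- function(par, eqobj) {
    lc <- leading_complex(eqobj$eigenvalues)
    rows[[length(rows) + 1L]] <<- c(
      list(param_value = par),
      as.list(eqobj$state),
      list(max_re_eig = unname(lc["re"]), freq_im_eig = unname(lc["im"]),
           stability = eqobj$stability)
    )
  }
  push(from, eq)

  par <- from
  y <- as.numeric(eq$state)
  y_prev <- NULL; par_prev <- NULL
  h <- step0
  ds <- step0 / 4
  truncated <- FALSE
  arc_mode <- FALSE     # once a fold is rounded, stay on arclength steps
  prev_sign <- sign(leading_complex(eq$eigenvalues)["re"])
  par_lo <- min(from, to); par_hi <- max(from, to)
  tol_end <- 1e-14 * max(1, abs(to))

  record <- function(par_new, state, residual, iterations) {
    sys <<- set_par(sys, par_name, par_new)
    J <- system_jacobian(sys, state)
    ev <- eigen(J, only.values = TRUE)$values
    eqobj <- structure(list(state = setNames(state, sys$state_names),
                            eigenvalues = ev,
                            stability = classify_stability(ev),
                            residual = residual, converged = TRUE,
                            iterations = iterations),
                       class = "equilibrium")
    push(par_new, eqobj)
    ev
  }

  while (length(rows) < max_points) {
    if (!arc_mode && !(dir * (to - par) > tol_end)) break
    if (arc_mode && (par < par_lo - tol_end || par > par_hi + tol_end)) break

    if (!arc_mode) {
      h <- min(h, abs(to - par))
      h_try <- h
      accepted <- FALSE
      while (!accepted) {
        par_new <- par + dir * h_try
        # secant predictor when two previous points exist
        y0 <- if (!is.null(y_prev) && !is.null(par_prev) &&
                  abs(par - par_prev) > 0) {
          y + (y - y_prev) * (par_new - par) / (par - par_prev)
        } else y
        sys <- set_par(sys, par_name, par_new)
        ns <- newton_solve(sys, y0)
        if (ns$converged) {
          ev <- record(par_new, ns$state, ns$residual, ns$iterations)
          lc <- leading_complex(ev)
          new_sign <- sign(lc["re"])
          flips <- !is.na(new_sign) && !is.na(prev_sign) &&
            new_sign != prev_sign
          if (flips && h_try > refine_step) {
            rows[[length(rows)]] <- NULL   # too coarse: retry tighter
            h_try <- h_try / 2
            next
          }
          y_prev <- y; par_prev <- par
          y <- ns$state; par <- par_new
          prev_sign <- if (is.na(new_sign)) prev_sign else new_sign
          h <- if (ns$iterations <= 5) min(h_try * 1.3, step0 * 4) else h_try
          accepted <- TRUE
        } else if (h_try > min_step) {
          h_try <- max(h_try / 2, min_step)
        } else {
          arc_mode <- TRUE   # fold suspected: switch to pseudo-arclength
          accepted <- TRUE
        }
      }
    } else {
      arc <- arclength_step(sys, par_name, y, par, y_prev, par_prev,
                            ds = ds)
      while (is.null(arc) && ds > min_step) {
        ds <- ds / 2
        arc <- arclength_step(sys, par_name, y, par, y_prev, par_prev,
                              ds = ds)
      }
      if (is.null(arc)) {
        inform(sprintf(
          "continue_branch: truncated at %s = %.6g (Newton failure beyond minimum step)",
          par_name, par))
        truncated <- TRUE
        break
      }
      record(arc$par, arc$y, arc$residual, arc$iterations)
      y_prev <- y; par_prev <- par
      y <- arc$y; par <- arc$par
      if (arc$iterations <= 5) ds <- min(ds * 1.3, step0)
    }
  }

  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  attr(out, "par_name") <- par_name
  attr(out, "sys") <- sys
  attr(out, "truncated") <- truncated
  class(out) <- c("bifurcation_branch", class(out))
  out
}

# One pseudo-arclength predictor-corrector step on the extended system
# [f(y, par); tangent . (u - u_pred)] = 0. Returns NULL on failure.
arclength_step <- function(sys, par_name, y, par, y_prev, par_prev, ds,
                           max_iter = 30, tol = 1e-11) {
  n <- length(y)
  tang <- if (!is.null(y_prev)) {
    t0 <- c(y - y_prev, par - par_prev)
    nrm <- sqrt(sum(t0^2))
    if (nrm == 0) return(NULL)
    t0 / nrm
  } else c(numeric(n), 1)
  u <- c(y, par) + ds * tang
  u_pred <- u
  for (it in seq_len(max_iter)) {
    sys <- set_par(sys, par_name, u[n + 1])
    f <- sys$rhs(u[1:n], sys$pars)
    g <- sum(tang * (u - u_pred))
    if (max(abs(c(f, g))) < tol) {
      return(list(y = u[1:n], par = u[n + 1], residual = max(abs(f)),
                  iterations = it))
    }
    J <- system_jacobian(sys, u[1:n])
    # d f / d par by central differences
    hp <- 1e-7 * max(abs(u[n + 1]), 1)
    sys_p <- set_par(sys, par_name, u[n + 1] + hp)
    sys_m <- set_par(sys, par_name, u[n + 1] - hp)
    dfdp <- (sys_p$rhs(u[1:n], sys_p$pars) - sys_m$rhs(u[1:n], sys_m$pars)) /
      (2 * hp)
    A <- rbind(cbind(J, dfdp), tang)
    delta <- tryCatch(solve(A, c(f, g)), error = function(e) NULL)
    if (is.null(delta)) return(NULL)
    u <- u - delta
  }
  NULL
}

#' Detect and refine Hopf points along a branch
#'
#' Every sign change of the leading complex pair's real part between
#' consecutive branch points is refined by bisection (tolerance `1e-10` on
#' the parameter; the refined |Re| is verified against `1e-8`). Crossings
#' whose imaginary part vanishes during refinement are excluded as folds,
#' with a message.
#'
#' @param branch a [continue_branch()] result.
#' @param sys the system (defaults to the one stored on the branch).
#' @param par_name continuation parameter (defaults to the stored one).
#' @return A tibble of class `hopf_set` with one row per Hopf point:
#'   `param_name`, `param_value`, `omega` (angular frequency, per time
#'   unit), `period` (`2*pi/omega`), `n_critical` (eigenvalues with
#'   |Re| < 1e-6), `criticality` (`NA` until classified) and a `state`
#'   list-column holding the equilibrium.
#' @export
detect_hopf <- function(branch, sys = NULL, par_name = NULL) {
  sys <- sys %||% attr(branch, "sys")
  par_name <- par_name %||% attr(branch, "par_name")
  stopifnot(nrow(branch) >= 2)
  re <- branch$max_re_eig
  im <- branch$freq_im_eig
  pv <- branch$param_value
  state_mat <- as.matrix(branch[, sys$state_names])

  hits <- which(!is.na(re[-1]) & !is.na(re[-length(re)]) &
                  sign(re[-1]) * sign(re[-length(re)]) < 0 &
                  im[-1] > .IM_TOL & im[-length(im)] > .IM_TOL)
  out <- vector("list", 0L)
  for (i in hits) {
    ref <- refine_hopf(sys, par_name, pv[i], pv[i + 1],
                       state_mat[i, ], sign(re[i]))
    if (is.null(ref)) {
      inform(sprintf(
        "detect_hopf: crossing in (%g, %g) lost its imaginary pair during refinement; excluded (fold, not Hopf)",
        pv[i], pv[i + 1]))
      next
    }
    out[[length(out) + 1L]] <- tibble(
      param_name = par_name,
      param_value = ref$par,
      omega = ref$omega,
      period = 2 * pi / ref$omega,
      n_critical = ref$n_critical,
      criticality = NA_character_,
      state = list(setNames(ref$y, sys$state_names))
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble(
    param_name = character(), param_value = numeric(), omega = numeric(),
    period = numeric(), n_critical = integer(), criticality = character(),
    state = list()
  )
  res <- dplyr::arrange(res, .data$param_value)
  class(res) <- c("hopf_set", class(res))
  attr(res, "sys") <- sys
  res
}

# bisection refinement of one crossing; returns NULL when the pair turns real
refine_hopf <- function(sys, par_name, lo, hi, y_lo, sign_lo,
                        par_tol = 1e-10, re_tol = .HYP_TOL, max_iter = 80) {
  eval_at <- function(par, yg) {
    sys <- set_par(sys, par_name, par)
    ns <- newton_solve(sys, yg)
    if (!ns$converged) return(NULL)
    ev <- eigen(system_jacobian(sys, ns$state), only.values = TRUE)$values
    lc <- leading_complex(ev)
    list(y = ns$state, re = lc["re"], im = lc["im"], ev = ev)
  }
  y <- y_lo
  r_lo <- eval_at(lo, y)
  if (is.null(r_lo)) return(NULL)
  tol <- par_tol * max(1, abs(hi))
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- eval_at(mid, y)
    if (is.null(r)) return(NULL)
    if (is.na(r$im) || r$im <= .IM_TOL) return(NULL)  # became real: fold
    y <- r$y
    if (sign(r$re) == sign_lo) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  final <- eval_at((lo + hi) / 2, y)
  if (is.null(final) || is.na(final$im) || final$im <= .IM_TOL) return(NULL)
  if (abs(final$re) > re_tol) {
    warn(sprintf("refine_hopf: |Re| = %.3e above tolerance %.0e at %s = %.8g",
                 abs(final$re), re_tol, par_name, (lo + hi) / 2))
  }
  list(par = (lo + hi) / 2, y = final$y, omega = unname(final$im),
       n_critical = sum(abs(Re(final$ev)) < 1e-6))
}

#' Classify Hopf criticality by amplitude probe
#'
#' Integrates the system at parameter offsets `delta` and `4 * delta` past
#' the crossing, on the side where the equilibrium is unstable, discards
#' the transient, and measures the stable oscillation amplitude around the
#' equilibrium. The bifurcation is called supercritical when both probes
#' settle on small-amplitude cycles whose amplitudes scale like the square
#' root of the offset (ratio near 2), subcritical when trajectories escape
#' to a distant attractor or blow up, and undetermined otherwise.
#'
#' @param sys an [ode_system()].
#' @param hopf one row of a [detect_hopf()] result (or the whole tibble,
#'   in which case each row is classified).
#' @param par_name continuation parameter (defaults to the stored name).
#' @param delta probe offset; default `1e-3 * max(1, |param_value|)`.
#' @param t_factor probe horizon in units of the linear growth time
#'   `1/Re(lambda)` at the probe offset.
#' @return The `hopf` tibble with `criticality` filled in.
#' @export
classify_criticality <- function(sys, hopf, par_name = NULL, delta = NULL,
                                 t_factor = 15) {
  par_name <- par_name %||% hopf$param_name[1]
  out <- hopf
  for (i in seq_len(nrow(hopf))) {
    out$criticality[i] <- criticality_probe(
      sys, par_name, hopf$param_value[i], hopf$state[[i]],
      hopf$omega[i], delta = delta, t_factor = t_factor)
  }
  out
}

criticality_probe <- function(sys, par_name, par_star, eq_state, omega,
                              delta = NULL, t_factor = 15) {
  delta <- delta %||% (1e-3 * max(1, abs(par_star)))
  # which side is unstable?
  re_at <- function(par, yg) {
    sys <- set_par(sys, par_name, par)
    ns <- newton_solve(sys, yg)
    if (!ns$converged) return(NULL)
    ev <- eigen(system_jacobian(sys, ns$state), only.values = TRUE)$values
    list(re = leading_complex(ev)["re"], y = ns$state)
  }
  rp <- re_at(par_star + delta, as.numeric(eq_state))
  rm <- re_at(par_star - delta, as.numeric(eq_state))
  if (is.null(rp) || is.null(rm)) return("undetermined")
  side <- if (!is.na(rp$re) && rp$re > 0) 1 else if (!is.na(rm$re) && rm$re > 0) -1 else NA
  if (is.na(side)) return("undetermined")

  amp_at <- function(off) {
    r <- re_at(par_star + side * off, as.numeric(eq_state))
    if (is.null(r) || is.na(r$re) || r$re <= 0) return(NA_real_)
    sysO <- set_par(sys, par_name, par_star + side * off)
    eq <- r$y
    scale <- max(abs(eq), 1)
    y0 <- eq + 1e-4 * scale
    t_end <- min(t_factor / r$re, 1e8)
    # diverging probes (subcritical side) hit integrator limits by design
    sim <- tryCatch(
      suppressWarnings(simulate(sysO, init = y0, t_end = t_end,
                                n_out = 4000, rtol = 1e-8, atol = 1e-12)),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)   # blow-up: no small attractor
    Y <- as.matrix(sim[, sysO$state_names])
    rads <- sqrt(rowSums((Y - matrix(eq, nrow(Y), length(eq),
                                     byrow = TRUE))^2))
    if (any(!is.finite(rads)) || max(rads) > 100 * scale) return(Inf)
    tail_r <- rads[seq(floor(0.75 * length(rads)), length(rads))]
    mean(tail_r)
  }
  a1 <- amp_at(delta)
  a2 <- amp_at(4 * delta)
  if (any(is.na(c(a1, a2)))) return("undetermined")
  if (is.infinite(a1) || is.infinite(a2)) return("subcritical")
  if (a1 <= 0) return("undetermined")
  ratio <- a2 / a1
  if (ratio > 1.35 && ratio < 3.0) "supercritical" else "undetermined"
}
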