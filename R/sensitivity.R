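# Slope-based sensitivity scores: the normalised mean slope of the Hopf
# location (or of the oscillation period) across a +-theta window around
# each parameter's default value.

#' Shape-preserving curve interpolation
#'
#' Piecewise cubic Hermite interpolation (pchip) through `(mu, value)`
#' pairs: the interpolant passes through every knot, preserves local
#' monotonicity and does not overshoot. With two points it degenerates to
#' the straight line between them.
#'
#' @param points a data frame whose first two columns are `mu` and the
#'   interpolated value, `mu` strictly monotone.
#' @return A function of `mu` with attributes `domain` (range of the
#'   knots) and `knots`.
#' @export
interpolate_curve <- function(points) {
  mu <- points[[1]]
  val <- points[[2]]
  if (length(mu) < 2) abort("interpolate_curve: need at least 2 points")
  if (anyDuplicated(mu)) abort("interpolate_curve: duplicate mu values")
  o <- order(mu)
  mu <- mu[o]; val <- val[o]
  f <- if (length(mu) == 2) {
    # pchip needs three knots; two points define the segment exactly
    function(x) approx(mu, val, x, rule = 2)$y
  } else {
    function(x) pracma::pchip(mu, val, x)
  }
  attr(f, "domain") <- range(mu)
  attr(f, "knots") <- data.frame(mu = mu, value = val)
  f
}

#' Slope sensitivity score
#'
#' Samples `m = 2l + 1` uniformly spaced points of `curve` on the window
#' `[mu0 (1 - theta), mu0 (1 + theta)]` and returns the average of the
#' successive finite-difference slopes, normalised by `mu0 / reference`:
#'
#' `SS = (1 / 2l) * sum_i (v[i+1] - v[i]) / (mu[i+1] - mu[i]) * mu0 / reference`
#'
#' On uniform samples the sum telescopes, so the score equals the chord
#' slope across the window times `mu0 / reference`; the score's sign is
#' the sign of the mean slope.
#'
#' @param curve a function of `mu` (e.g. from [interpolate_curve()]) or a
#'   two-column data frame of `(mu, value)` points to interpolate first.
#' @param mu0 unperturbed parameter value (window centre).
#' @param theta fractional half-width of the window (default 0.1).
#' @param m number of samples, odd, >= 3 (default 21).
#' @param reference normalising value (> 0): the critical stimulation
#'   intensity for Hopf-location scores, the default-parameter period for
#'   period scores.
#' @return A one-row tibble of class `sensitivity_score` with `mu0`,
#'   `theta`, `l`, `m`, `reference`, `score`.
#' @export
sensitivity_score <- function(curve, mu0, theta = 0.1, m = 21, reference) {
  if (m %% 2 == 0 || m < 3) abort("sensitivity_score: m must be odd and >= 3")
  if (reference <= 0) abort("sensitivity_score: reference must be > 0")
  if (is.data.frame(curve)) curve <- interpolate_curve(curve)
  lo <- mu0 * (1 - theta); hi <- mu0 * (1 + theta)
  dom <- attr(curve, "domain")
  if (!is.null(dom)) {
    if (lo < dom[1] - 1e-12 * abs(dom[1])) {
      abort(sprintf(
        "sensitivity_score: window lower edge %.6g leaves the curve domain [%.6g, %.6g]",
        lo, dom[1], dom[2]))
    }
    if (hi > dom[2] + 1e-12 * abs(dom[2])) {
      abort(sprintf(
        "sensitivity_score: window upper edge %.6g leaves the curve domain [%.6g, %.6g]",
        hi, dom[1], dom[2]))
    }
  }
  l <- (m - 1L) / 2L
  mus <- seq(lo, hi, length.out = m)
  vals <- curve(mus)
  if (any(!is.finite(vals))) {
    abort("sensitivity_score: curve evaluated to non-finite values")
  }
  slopes <- diff(vals) / diff(mus)
  score <- sum(slopes) / (2 * l) * mu0 / reference
  out <- tibble(mu0 = mu0, theta = theta, l = l, m = m,
                reference = reference, score = score)
  class(out) <- c("sensitivity_score", class(out))
  out
}

#' Hopf location as a function of one parameter
#'
#' Tracks the Hopf point that is continuous with the default-parameter
#' bifurcation (at `TR = tr_star`) while `par_name` varies across
#' `window`, marching outward from the default value and re-bracketing
#' each crossing around the previous location (when a slice holds several
#' Hopf points this picks the one nearest the tracked branch).
#'
#' @param params an [nfkb_params()] object.
#' @param par_name parameter to vary (not `"TR"`).
#' @param window numeric `c(lo, hi)` containing the default value.
#' @param n_points number of curve points across the window (odd
#'   recommended so the default value is a knot).
#' @param tr_star,state Hopf location and equilibrium state at the default
#'   parameters; computed via [nfkb_hopf_slice()] when omitted.
#' @return A tibble `(mu, TR_star, omega)` of class `hopf_location_curve`.
#' @export
hopf_location_curve <- function(params, par_name, window = NULL,
                                n_points = 11, tr_star = NULL,
                                state = NULL) {
  stopifnot(par_name != "TR")
  mu0 <- params[[par_name]]
  window <- window %||% (mu0 * c(0.9, 1.1))
  stopifnot(window[1] < mu0, window[2] > mu0)
  if (is.null(tr_star) || is.null(state)) {
    sl <- nfkb_hopf_slice(params)
    if (!nrow(sl)) abort("hopf_location_curve: no Hopf point at defaults")
    i <- which.max(sl$param_value)     # high-dose branch
    tr_star <- sl$param_value[i]
    state <- sl$state[[i]]
  }
  sys <- nfkb_system(params)

  track <- function(mus) {
    tr_prev <- tr_star; y_prev <- as.numeric(state)
    out <- vector("list", length(mus))
    for (i in seq_along(mus)) {
      s <- set_par(sys, par_name, mus[i])
      hp <- track_one_hopf(s, "TR", tr_prev, y_prev)
      if (is.null(hp)) {
        abort(sprintf(
          "hopf_location_curve: lost the Hopf branch at %s = %.6g",
          par_name, mus[i]))
      }
      out[[i]] <- tibble(mu = mus[i], TR_star = hp$par, omega = hp$omega)
      tr_prev <- hp$par; y_prev <- hp$y
    }
    dplyr::bind_rows(out)
  }

  half <- (n_points - 1) %/% 2
  up <- seq(mu0, window[2], length.out = half + 1L)[-1]
  dn <- seq(mu0, window[1], length.out = n_points - half)[-1]
  res <- dplyr::bind_rows(
    tibble(mu = mu0, TR_star = tr_star,
           omega = NA_real_),
    track(up), track(dn))
  res <- dplyr::arrange(res, .data$mu)
  # fill the centre frequency from its neighbours' refined values
  if (any(is.na(res$omega)) && nrow(res) > 2) {
    res$omega[is.na(res$omega)] <-
      approx(res$mu[!is.na(res$omega)], res$omega[!is.na(res$omega)],
             res$mu[is.na(res$omega)], rule = 2)$y
  }
  class(res) <- c("hopf_location_curve", class(res))
  res
}

# locate the eigenvalue crossing nearest tr_prev: expand a bracket around
# it, then bisect with refine_hopf
track_one_hopf <- function(sys, slice_par, tr_prev, y_prev,
                           width0 = 0.08, max_expand = 8) {
  re_at <- function(tr, yg) {
    s <- set_par(sys, slice_par, tr)
    ns <- newton_solve(s, yg)
    if (!ns$converged) return(NULL)
    ev <- eigen(system_jacobian(s, ns$state), only.values = TRUE)$values
    lc <- leading_complex(ev)
    list(re = lc["re"], y = ns$state)
  }
  w <- width0 * max(abs(tr_prev), 1e-3)
  for (k in seq_len(max_expand)) {
    lo <- max(tr_prev - w, 1e-9)
    hi <- tr_prev + w
    rlo <- re_at(lo, y_prev)
    rhi <- re_at(hi, y_prev)
    if (!is.null(rlo) && !is.null(rhi) &&
        !is.na(rlo$re) && !is.na(rhi$re) &&
        sign(rlo$re) * sign(rhi$re) < 0) {
      ref <- refine_hopf(sys, slice_par, lo, hi, rlo$y, sign(rlo$re))
      if (!is.null(ref)) return(ref)
    }
    w <- w * 2
  }
  NULL
}

.sens_params <- function() setdiff(.param_order, "TR")

#' Hopf-location sensitivity scores for all parameters
#'
#' For each model parameter (all 28 except TR) the Hopf-location curve
#' over the `+-theta` window is computed with [hopf_location_curve()],
#' interpolated (pchip), sampled at `m` uniform points and scored with
#' [sensitivity_score()], normalised by the default critical intensity.
#' A parameter whose curve cannot be tracked yields a flagged row (score
#' `NA`), not an error.
#'
#' @param params an [nfkb_params()] object.
#' @param theta fractional window half-width (default 0.1).
#' @param m Eq. samples (odd, default 21).
#' @param n_curve Hopf-curve knots per window (default 11).
#' @param names subset of parameter names (default: all 28).
#' @return A tibble of class `sensitivity_table`: `param_num`,
#'   `param_num_alt`, `param_name`, `description`, `mu0`, `score`, `ok`,
#'   `note`; attribute `reference` holds the default critical intensity,
#'   and `high_sensitivity(x)` filters `|score| >= 0.5`.
#' @export
hb_sensitivity_all <- function(params = nfkb_params(), theta = 0.1, m = 21,
                               n_curve = 11, names = NULL) {
  names <- names %||% .sens_params()
  tab <- param_table()
  sl <- nfkb_hopf_slice(params)
  if (!nrow(sl)) abort("hb_sensitivity_all: no Hopf point at defaults")
  i0 <- which.max(sl$param_value)
  tr_star <- sl$param_value[i0]
  state0 <- sl$state[[i0]]

  rows <- lapply(names, function(nm) {
    mu0 <- params[[nm]]
    row <- tab[tab$name == nm, ]
    res <- tryCatch({
      crv <- hopf_location_curve(params, nm,
                                 window = mu0 * c(1 - theta, 1 + theta),
                                 n_points = n_curve, tr_star = tr_star,
                                 state = state0)
      sc <- sensitivity_score(crv[, c("mu", "TR_star")], mu0 = mu0,
                              theta = theta, m = m, reference = tr_star)
      list(score = sc$score, ok = TRUE, note = NA_character_)
    }, error = function(e) {
      list(score = NA_real_, ok = FALSE, note = conditionMessage(e))
    })
    tibble(param_num = row$num, param_num_alt = row$num_alt,
           param_name = nm, description = row$description, mu0 = mu0,
           score = res$score, ok = res$ok, note = res$note)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reference") <- tr_star
  attr(out, "mode") <- "hb"
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' Period sensitivity scores for all parameters
#'
#' With the stimulation fixed at `TR = 1`, the sustained-oscillation
#' period is measured (by integration and peak extraction) at `m` sampled
#' values of each parameter across its `+-theta` window, and the slope
#' score is formed exactly as for the Hopf location with the
#' default-parameter period `P0` as the normalising reference.
#' Non-oscillatory sample points flag the row.
#'
#' @inheritParams hb_sensitivity_all
#' @param transient,window,t_max,dt period-measurement controls
#'   ([oscillation_period()]), in minutes.
#' @return A `sensitivity_table` tibble; attribute `reference` holds `P0`
#'   (minutes).
#' @export
period_sensitivity_all <- function(params = nfkb_params(), theta = 0.1,
                                   m = 21, names = NULL, transient = 2000,
                                   window = 2000, t_max = 8000, dt = 0.5) {
  names <- names %||% .sens_params()
  tab <- param_table()
  params$TR <- 1
  base_sys <- nfkb_system(params)
  init <- nfkb_initial_state(params)

  period_at <- function(sys) {
    res <- oscillation_period(sys, init = init, species = "NFkBn",
                              transient = transient, window = window,
                              t_max = t_max, dt = dt)
    if (is.na(res$period)) NA_real_ else res$period
  }
  P0 <- period_at(base_sys)
  if (is.na(P0)) abort("period_sensitivity_all: no oscillation at defaults")

  rows <- lapply(names, function(nm) {
    mu0 <- params[[nm]]
    row <- tab[tab$name == nm, ]
    mus <- seq(mu0 * (1 - theta), mu0 * (1 + theta), length.out = m)
    pers <- vapply(mus, function(v) {
      period_at(set_par(base_sys, nm, v))
    }, numeric(1))
    if (any(is.na(pers))) {
      return(tibble(param_num = row$num, param_num_alt = row$num_alt,
                    param_name = nm, description = row$description,
                    mu0 = mu0, score = NA_real_, ok = FALSE,
                    note = sprintf("%d non-oscillatory sample point(s)",
                                   sum(is.na(pers)))))
    }
    l <- (m - 1L) / 2L
    score <- sum(diff(pers) / diff(mus)) / (2 * l) * mu0 / P0
    tibble(param_num = row$num, param_num_alt = row$num_alt,
           param_name = nm, description = row$description, mu0 = mu0,
           score = score, ok = TRUE, note = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reference") <- P0
  attr(out, "mode") <- "period"
  class(out) <- c("sensitivity_table", class(out))
  out
}

#' High-sensitivity subset
#'
#' Filters a [hb_sensitivity_all()] / [period_sensitivity_all()] table to
#' the parameters with `|score| >= threshold` (default 0.5, the published
#' cut between the high- and low-sensitivity groups), ordered by
#' decreasing |score|.
#'
#' @param scores a `sensitivity_table`.
#' @param threshold absolute-score cutoff.
#' @return The filtered, reordered tibble.
#' @export
high_sensitivity <- function(scores, threshold = 0.5) {
  out <- scores[!is.na(scores$score) & abs(scores$score) >= threshold, ]
  out[order(-abs(out$score)), ]
}
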