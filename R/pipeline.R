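# End-to-end runs reproducing the published figures' data, with optional
# CSV export. These are the entry points the command-line wrapper calls.

#' Equilibrium branch of the NF-kB model in TR
#'
#' Finds the resting equilibrium at the lower end of `tr_range` (long-time
#' integration from the resting initial condition, then Newton) and
#' continues it across the range.
#'
#' @param params an [nfkb_params()] object.
#' @param tr_range continuation window for the stimulation intensity.
#' @param ... passed to [continue_branch()].
#' @return A `bifurcation_branch` tibble.
#' @export
nfkb_branch <- function(params = nfkb_params(), tr_range = c(1e-3, 1), ...) {
  sys <- nfkb_system(params)
  sys <- set_par(sys, "TR", tr_range[1])
  eq <- find_equilibrium(sys, nfkb_initial_state(params),
                         integrate_fallback = TRUE)
  if (!eq$converged) abort("nfkb_branch: no equilibrium at range start")
  continue_branch(sys, "TR", tr_range, guess = eq$state, ...)
}

#' One-parameter bifurcation run
#'
#' Regenerates the data of the one-parameter bifurcation diagram in the
#' stimulation intensity: the equilibrium branch with stability labels,
#' refined Hopf points (optionally classified), and the limit-cycle
#' period/envelope over the oscillatory window.
#'
#' @param params an [nfkb_params()] object.
#' @param tr_range continuation window, default `c(1e-3, 1)`.
#' @param n_periods period-curve grid points past the last Hopf point
#'   (0 skips the period curve).
#' @param classify run the amplitude-probe criticality classification on
#'   each Hopf point (integration-heavy).
#' @param out_dir optional directory; writes `branch.csv`, `hopf.csv`,
#'   `period.csv`.
#' @param ... passed to [continue_branch()].
#' @return A list of class `nfkb_one_param` with elements `branch`
#'   (`bifurcation_branch`), `hopf` (`hopf_set`) and `periods`
#'   (`period_curve` or `NULL`).
#' @export
run_one_param <- function(params = nfkb_params(), tr_range = c(1e-3, 1),
                          n_periods = 8, classify = FALSE, out_dir = NULL,
                          ...) {
  if (diff(tr_range) <= 0) abort("run_one_param: empty TR range")
  branch <- nfkb_branch(params, tr_range, ...)
  hopf <- detect_hopf(branch)
  sys <- nfkb_system(params)
  if (classify && nrow(hopf)) hopf <- classify_criticality(sys, hopf)

  periods <- NULL
  if (n_periods > 0 && nrow(hopf)) {
    hb <- max(hopf$param_value)
    if (hb < tr_range[2]) {
      grid <- seq(hb + 0.01 * (tr_range[2] - hb), tr_range[2],
                  length.out = n_periods)
      periods <- period_curve(sys, "TR", grid,
                              init = nfkb_initial_state(params),
                              species = "NFkBn")
    }
  }

  out <- structure(list(branch = branch, hopf = hopf, periods = periods,
                        params = params),
                   class = "nfkb_one_param")
  if (!is.null(out_dir)) write_one_param(out, out_dir)
  out
}

#' @export
print.nfkb_one_param <- function(x, ...) {
  cat(sprintf("<nfkb_one_param: %d branch points, %d Hopf point(s)%s>\n",
              nrow(x$branch), nrow(x$hopf),
              if (!is.null(x$periods)) {
                sprintf(", period curve (%d pts)", nrow(x$periods))
              } else ""))
  if (nrow(x$hopf)) {
    print(dplyr::select(as_tibble(x$hopf), -"state"))
  }
  invisible(x)
}

write_one_param <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(res$branch),
            file.path(out_dir, "branch.csv"), row.names = FALSE)
  hopf <- as_tibble(res$hopf)
  hopf$state <- NULL
  write.csv(as.data.frame(hopf), file.path(out_dir, "hopf.csv"),
            row.names = FALSE)
  if (!is.null(res$periods)) {
    per <- as.data.frame(res$periods)
    names(per)[names(per) == "period"] <- "period_min"
    write.csv(per, file.path(out_dir, "period.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Two-parameter bifurcation run
#'
#' Traces the Hopf curve in the (TR, second parameter) plane over the
#' published range (or a given one) and optionally writes
#' `hopf_curve.csv` with columns `second_param,mu,TR,branch_label`.
#'
#' @param params an [nfkb_params()] object.
#' @param second_param second parameter name.
#' @param range window for the second parameter; defaults to the
#'   published survey range.
#' @param out_dir optional output directory.
#' @param ... passed to [trace_hopf_curve()].
#' @return A `hopf_curve` tibble.
#' @export
run_two_param <- function(params = nfkb_params(), second_param,
                          range = NULL, out_dir = NULL, ...) {
  tab <- param_table()
  if (!second_param %in% tab$name) {
    close <- tab$name[order(utils::adist(second_param, tab$name))][1:5]
    abort(paste0("unknown parameter '", second_param,
                 "'; did you mean one of: ", paste(close, collapse = ", ")))
  }
  if (is.null(range)) {
    row <- tab[tab$name == second_param, ]
    range <- c(max(row$lo, 1e-9), row$hi)
  }
  curve <- trace_hopf_curve(params, second_param, range, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(second_param = curve$second_param, mu = curve$mu,
                     TR = curve$TR, branch_label = curve$branch)
    write.csv(df, file.path(out_dir, "hopf_curve.csv"), row.names = FALSE)
  }
  curve
}

#' Single-Hopf range survey run
#'
#' Computes the percentage-of-range with single-Hopf topology for the
#' requested parameters and optionally writes `survey.csv`.
#'
#' @inheritParams survey_table
#' @param out_dir optional output directory.
#' @return The [survey_table()] tibble.
#' @export
run_survey <- function(params = nfkb_params(), names = NULL, n_grid = 201,
                       out_dir = NULL, ...) {
  res <- survey_table(params, names = names, n_grid = n_grid, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(as.data.frame(res), file.path(out_dir, "survey.csv"),
              row.names = FALSE)
  }
  res
}

#' Sensitivity-score run
#'
#' Hopf-location (`mode = "hb"`) or period (`mode = "period"`) sensitivity
#' scores for all parameters; optionally writes a CSV with columns
#' `param_num,param_name,description,score`.
#'
#' @param params an [nfkb_params()] object.
#' @param mode `"hb"` or `"period"`.
#' @param theta fractional window (default 0.1).
#' @param m samples per window (odd, default 21).
#' @param out_dir optional output directory.
#' @param ... passed to the underlying scorer.
#' @return A `sensitivity_table` tibble.
#' @export
run_sensitivity <- function(params = nfkb_params(),
                            mode = c("hb", "period"), theta = 0.1, m = 21,
                            out_dir = NULL, ...) {
  mode <- match.arg(mode)
  if (m %% 2 == 0 || m < 3) abort("run_sensitivity: m must be odd and >= 3")
  res <- if (mode == "hb") {
    hb_sensitivity_all(params, theta = theta, m = m, ...)
  } else {
    period_sensitivity_all(params, theta = theta, m = m, ...)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(param_num = res$param_num_alt,
                     param_name = res$param_name,
                     description = res$description, score = res$score)
    write.csv(df, file.path(out_dir, paste0("sensitivity_", mode, ".csv")),
              row.names = FALSE)
  }
  res
}

#' Fold of a Hopf curve in the second parameter
#'
#' Locates the value of `second_param` at which the slope of the Hopf
#' curve `TR*(mu)` reverses (i.e. the minimum of the tracked high-dose
#' Hopf location), by golden-section minimisation of the tracked branch.
#'
#' @param params an [nfkb_params()] object.
#' @param second_param parameter name.
#' @param window search window `c(lo, hi)` for the second parameter.
#' @param tr_guess,state_guess Hopf location and equilibrium state at a
#'   point inside the window (computed at `window` midpoint when absent).
#' @param tol minimisation tolerance on `mu`.
#' @return A one-row tibble `(mu, TR)` at the fold.
#' @export
hopf_fold <- function(params, second_param, window, tr_guess = NULL,
                      state_guess = NULL, tol = 1e-5) {
  sys <- nfkb_system(params)
  if (is.null(tr_guess) || is.null(state_guess)) {
    mu_mid <- sqrt(prod(window))
    sl <- nfkb_hopf_slice(params, second_param, mu_mid)
    if (!nrow(sl)) abort("hopf_fold: no Hopf point at the window midpoint")
    i <- which.max(sl$param_value)
    tr_guess <- sl$param_value[i]
    state_guess <- sl$state[[i]]
  }
  last <- list(tr = tr_guess, y = as.numeric(state_guess))
  tr_at <- function(mu) {
    s <- set_par(sys, second_param, mu)
    hp <- track_one_hopf(s, "TR", last$tr, last$y)
    if (is.null(hp)) return(NA_real_)
    last <<- list(tr = hp$par, y = hp$y)
    hp$par
  }
  opt <- stats::optimize(function(mu) {
    v <- tr_at(mu)
    if (is.na(v)) 1e6 else v
  }, interval = window, tol = tol)
  tibble(mu = opt$minimum, TR = opt$objective)
}

#' Boundary of the Hopf-carrying region in a second parameter
#'
#' Bisection on `second_param` for the smallest value whose TR slice still
#' carries at least one Hopf point (the low-`mu` end of the Hopf curve).
#'
#' @param params an [nfkb_params()] object.
#' @param second_param parameter name.
#' @param window bracket `c(lo, hi)` with no Hopf at `lo` and at least
#'   one at `hi`.
#' @param tol bisection tolerance on `mu`.
#' @param tr_range TR window per slice.
#' @param ... slice options.
#' @return The boundary value of `second_param`.
#' @export
hopf_boundary <- function(params, second_param, window, tol = 1e-6,
                          tr_range = c(1e-5, 1), ...) {
  sys <- nfkb_system(params)
  n_at <- function(mu, guess) {
    s <- set_par(sys, second_param, mu)
    sl <- tryCatch(hopf_slice(s, "TR", range = tr_range, guess = guess,
                              refine = FALSE, ...),
                   error = function(e) NULL)
    if (is.null(sl)) list(n = 0L, g = guess) else {
      list(n = nrow(sl), g = attr(sl, "end_state"))
    }
  }
  lo <- window[1]; hi <- window[2]
  g <- NULL
  rlo <- n_at(lo, g)
  rhi <- n_at(hi, rlo$g)
  if (rlo$n > 0 || rhi$n == 0) {
    abort("hopf_boundary: window must bracket the boundary (no Hopf at lo, Hopf at hi)")
  }
  g <- rhi$g
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- n_at(mid, g)
    if (r$n > 0) { hi <- mid; g <- r$g } else lo <- mid
  }
  (lo + hi) / 2
}
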