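# Two-parameter Hopf structure: slices in the stimulation intensity for
# each value of a second parameter, curve assembly, and the
# percentage-of-range survey of one-Hopf topology.

# TR grid for a slice: logarithmically spaced below `split` (low-dose
# islands live at very small TR; linear grids miss them), linear above.
slice_grid <- function(range, n_log = 45, n_lin = 60, split = 0.05) {
  lo <- range[1]; hi <- range[2]
  stopifnot(lo > 0, hi > lo)
  if (hi <= split) return(exp(seq(log(lo), log(hi), length.out = n_log)))
  if (lo >= split) return(seq(lo, hi, length.out = n_lin))
  c(exp(seq(log(lo), log(split), length.out = n_log)),
    seq(split, hi, length.out = n_lin)[-1])
}

#' All Hopf points of a one-parameter slice
#'
#' Walks the equilibrium branch across a (log + linear) grid of the slice
#' parameter, counts sign changes of the leading complex pair, and
#' (optionally) refines each crossing by bisection. The number of Hopf
#' points in the slice is its topology signature for the range survey.
#'
#' @param sys an [ode_system()].
#' @param slice_par the parameter swept within the slice (default `"TR"`).
#' @param range slice parameter window, default `c(1e-5, 1)`.
#' @param guess equilibrium state (or good guess) at `range[1]`; defaults
#'   to zeros with Newton + integration fallback.
#' @param refine refine crossings by bisection (`TRUE`) or only count and
#'   bracket them (`FALSE`, used by the survey).
#' @param n_log,n_lin,split grid layout, see Details.
#' @return A `hopf_set` tibble (as [detect_hopf()]); when
#'   `refine = FALSE`, columns `param_value`/`omega` hold bracket
#'   midpoints and grid frequencies. Attribute `n_hopf` carries the count,
#'   attribute `end_state` the branch state at `range[1]` for reuse by
#'   neighbouring slices.
#' @export
hopf_slice <- function(sys, slice_par = "TR", range = c(1e-5, 1),
                       guess = NULL, refine = TRUE,
                       n_log = 45, n_lin = 60, split = 0.05) {
  grid <- slice_grid(range, n_log = n_log, n_lin = n_lin, split = split)
  sys <- set_par(sys, slice_par, grid[1])
  guess <- guess %||% setNames(numeric(sys$dim), sys$state_names)
  eq0 <- find_equilibrium(sys, guess,
                          integrate_fallback = !is.null(sys$compiled))
  if (!eq0$converged) {
    abort(sprintf("hopf_slice: no equilibrium at %s = %g", slice_par,
                  grid[1]))
  }
  y <- as.numeric(eq0$state)
  start_state <- y
  prev <- NULL
  crossings <- list()
  for (g in grid) {
    sys <- set_par(sys, slice_par, g)
    ns <- newton_solve(sys, y)
    if (!ns$converged) next
    y <- ns$state
    ev <- eigen(system_jacobian(sys, y), only.values = TRUE)$values
    lc <- leading_complex(ev)
    cur <- list(par = g, y = y, re = lc["re"], im = lc["im"])
    if (!is.null(prev) && !is.na(prev$re) && !is.na(cur$re) &&
        prev$im > .IM_TOL && cur$im > .IM_TOL &&
        sign(prev$re) * sign(cur$re) < 0) {
      crossings[[length(crossings) + 1L]] <- list(prev = prev, cur = cur)
    }
    prev <- cur
  }

  rows <- lapply(crossings, function(cr) {
    if (refine) {
      ref <- refine_hopf(sys, slice_par, cr$prev$par, cr$cur$par,
                         cr$prev$y, sign(cr$prev$re))
      if (is.null(ref)) return(NULL)
      tibble(param_name = slice_par, param_value = ref$par,
             omega = ref$omega, period = 2 * pi / ref$omega,
             n_critical = ref$n_critical, criticality = NA_character_,
             state = list(setNames(ref$y, sys$state_names)))
    } else {
      mid <- (cr$prev$par + cr$cur$par) / 2
      om <- unname((cr$prev$im + cr$cur$im) / 2)
      tibble(param_name = slice_par, param_value = mid, omega = om,
             period = 2 * pi / om, n_critical = NA_integer_,
             criticality = NA_character_,
             state = list(setNames(cr$prev$y, sys$state_names)))
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    param_name = character(), param_value = numeric(), omega = numeric(),
    period = numeric(), n_critical = integer(), criticality = character(),
    state = list())
  out <- dplyr::arrange(out, .data$param_value)
  class(out) <- c("hopf_set", class(out))
  attr(out, "n_hopf") <- nrow(out)
  attr(out, "end_state") <- start_state
  attr(out, "sys") <- sys
  out
}

#' Hopf points of the NF-kB model in TR for one parameter setting
#'
#' Sets `second_param` to `value` (when given) and returns all Hopf points
#' in the stimulation intensity over `tr_range`.
#'
#' @param params an [nfkb_params()] object.
#' @param second_param optional parameter name to override.
#' @param value value for `second_param`.
#' @param tr_range TR window, default `c(1e-5, 1)`.
#' @param ... passed to [hopf_slice()].
#' @return A `hopf_set` tibble.
#' @examples
#' \donttest{
#' nfkb_hopf_slice(nfkb_params())                    # one Hopf near 0.366
#' nfkb_hopf_slice(nfkb_params(), "totalNFkB", 0.15) # three Hopf points
#' }
#' @export
nfkb_hopf_slice <- function(params, second_param = NULL, value = NULL,
                            tr_range = c(1e-5, 1), ...) {
  if (!is.null(second_param)) {
    stopifnot(!is.null(value), value > 0)
    over <- setNames(list(value), second_param)
    params <- do.call(nfkb_params, c(unclass(params)[setdiff(.param_order,
                                                             second_param)],
                                     over))
  }
  hopf_slice(nfkb_system(params), slice_par = "TR", range = tr_range, ...)
}

#' Trace a Hopf curve in the (TR, second parameter) plane
#'
#' Assembles the Hopf locus from adaptively refined one-parameter slices:
#' wherever the Hopf count changes between neighbouring slices the spacing
#' is halved, down to `min_rel_spacing` of the range, so fold and island
#' boundaries are bracketed. Points are chained across slices by proximity
#' in TR, and the chain carrying the highest-TR (high-dose) Hopf point is
#' labelled `main`; disconnected chains are labelled `island`.
#'
#' @param params an [nfkb_params()] object.
#' @param second_param name of the second parameter.
#' @param range survey window for the second parameter.
#' @param n_slices initial number of uniform slices.
#' @param min_rel_spacing refinement floor as a fraction of the range.
#' @param tr_range TR window per slice.
#' @param ... slice grid options passed to [hopf_slice()].
#' @return A tibble of class `hopf_curve` with columns `second_param`,
#'   `mu`, `TR`, `omega`, `period`, `branch`, plus per-slice counts in
#'   attribute `slices`.
#' @export
trace_hopf_curve <- function(params, second_param, range, n_slices = 41,
                             min_rel_spacing = 1e-4,
                             tr_range = c(1e-5, 1), ...) {
  stopifnot(range[1] > 0, range[2] > range[1])
  sys <- nfkb_system(params)
  mus <- seq(range[1], range[2], length.out = n_slices)
  cache <- new.env(parent = emptyenv())

  slice_at <- function(mu, guess) {
    key <- format(mu, digits = 15)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- set_par(sys, second_param, mu)
    sl <- tryCatch(
      hopf_slice(s, "TR", range = tr_range, guess = guess, refine = TRUE,
                 ...),
      error = function(e) NULL)
    cache[[key]] <- sl
    sl
  }

  # initial pass, reusing each slice's start state as the next guess
  guess <- NULL
  slices <- list()
  for (mu in mus) {
    sl <- slice_at(mu, guess)
    if (!is.null(sl)) guess <- attr(sl, "end_state")
    slices[[length(slices) + 1L]] <- list(mu = mu, slice = sl)
  }

  # adaptive refinement where the count changes
  min_gap <- min_rel_spacing * diff(range)
  repeat {
    mus_now <- vapply(slices, `[[`, numeric(1), "mu")
    counts <- vapply(slices, function(s) {
      if (is.null(s$slice)) NA_integer_ else nrow(s$slice)
    }, integer(1))
    ins <- which(abs(diff(counts)) > 0 & diff(mus_now) > min_gap)
    if (!length(ins)) break
    for (i in ins) {
      mu_mid <- (mus_now[i] + mus_now[i + 1]) / 2
      g <- if (!is.null(slices[[i]]$slice)) {
        attr(slices[[i]]$slice, "end_state")
      }
      sl <- slice_at(mu_mid, g)
      slices[[length(slices) + 1L]] <- list(mu = mu_mid, slice = sl)
    }
    ord <- order(vapply(slices, `[[`, numeric(1), "mu"))
    slices <- slices[ord]
  }

  pts <- dplyr::bind_rows(lapply(slices, function(s) {
    if (is.null(s$slice) || !nrow(s$slice)) return(NULL)
    tibble(mu = s$mu, TR = s$slice$param_value, omega = s$slice$omega,
           period = s$slice$period)
  }))
  if (!nrow(pts)) {
    out <- tibble(second_param = character(), mu = numeric(),
                  TR = numeric(), omega = numeric(), period = numeric(),
                  branch = character())
    class(out) <- c("hopf_curve", class(out))
    return(out)
  }

  pts <- label_branches(pts)
  out <- tibble(second_param = second_param, mu = pts$mu, TR = pts$TR,
                omega = pts$omega, period = pts$period, branch = pts$branch)
  out <- dplyr::arrange(out, .data$branch, .data$mu, .data$TR)
  attr(out, "slices") <- tibble(
    mu = vapply(slices, `[[`, numeric(1), "mu"),
    n_hopf = vapply(slices, function(s) {
      if (is.null(s$slice)) NA_integer_ else nrow(s$slice)
    }, integer(1)))
  class(out) <- c("hopf_curve", class(out))
  out
}

# chain Hopf points across slices by TR proximity; the chain containing
# the global highest-TR point is the high-dose ("main") branch
label_branches <- function(pts) {
  pts <- pts[order(pts$mu, pts$TR), ]
  pts$chain <- NA_integer_
  chains_last <- list()   # chain id -> last TR seen
  next_id <- 1L
  for (mu in unique(pts$mu)) {
    idx <- which(pts$mu == mu)
    used <- integer(0)
    for (i in idx) {
      best <- NA_integer_; bestd <- Inf
      for (cid in setdiff(seq_along(chains_last), used)) {
        d <- abs(log(pts$TR[i]) - log(chains_last[[cid]]))
        if (!is.na(d) && d < bestd) { bestd <- d; best <- cid }
      }
      if (!is.na(best) && bestd < log(4)) {   # within 4x in TR
        pts$chain[i] <- best
        chains_last[[best]] <- pts$TR[i]
        used <- c(used, best)
      } else {
        pts$chain[i] <- next_id
        chains_last[[next_id]] <- pts$TR[i]
        used <- c(used, next_id)
        next_id <- next_id + 1L
      }
    }
  }
  main_chain <- pts$chain[which.max(pts$TR)]
  pts$branch <- ifelse(pts$chain == main_chain, "main", "island")
  pts
}

#' Fraction of a parameter range with single-Hopf topology
#'
#' For `n_grid` uniform values of `second_param` across `range`, counts
#' the Hopf points of the TR slice and reports the percentage of the range
#' (trapezoidal measure of the indicator) on which the one-parameter
#' diagram has exactly one Hopf point — the published per-parameter
#' robustness summary.
#'
#' @param params an [nfkb_params()] object.
#' @param second_param parameter name.
#' @param range numeric `c(lo, hi)`; defaults to the published survey
#'   range from [param_table()]. A degenerate range (`lo == hi`) scores a
#'   single slice.
#' @param n_grid number of grid points (>= 50 for survey use; smaller
#'   values are allowed for spot checks).
#' @param tr_range TR window per slice.
#' @param ... slice grid options passed to [hopf_slice()].
#' @return A tibble of class `range_survey` with one row: `name`,
#'   `range_lo`, `range_hi`, `n_grid`, `pct_one_hb`; per-point counts in
#'   attribute `counts`.
#' @export
survey_range <- function(params, second_param, range = NULL, n_grid = 201,
                         tr_range = c(1e-5, 1), ...) {
  tab <- param_table()
  if (is.null(range)) {
    row <- tab[tab$name == second_param, ]
    if (!nrow(row)) abort(paste0("no published range for ", second_param))
    range <- c(row$lo, row$hi)
  }
  sys <- nfkb_system(params)
  mus <- if (range[2] > range[1]) {
    if (range[1] <= 0) {
      # open interval at an unphysical endpoint: sample strictly inside,
      # one grid spacing away from zero
      seq(range[2] / n_grid, range[2], length.out = n_grid)
    } else {
      seq(range[1], range[2], length.out = n_grid)
    }
  } else range[1]

  counts <- rep(NA_integer_, length(mus))
  guess <- NULL
  for (i in seq_along(mus)) {
    s <- set_par(sys, second_param, mus[i])
    sl <- tryCatch(
      hopf_slice(s, "TR", range = tr_range, guess = guess, refine = FALSE,
                 ...),
      error = function(e) NULL)
    if (!is.null(sl)) {
      counts[i] <- nrow(sl)
      guess <- attr(sl, "end_state")
    }
  }
  ind <- as.numeric(counts == 1L)
  ind[is.na(ind)] <- 0
  pct <- if (length(mus) == 1L) 100 * ind else {
    w <- rep(1, length(mus)); w[c(1, length(mus))] <- 0.5
    100 * sum(w * ind) / sum(w)
  }
  out <- tibble(name = second_param, range_lo = range[1],
                range_hi = range[2], n_grid = length(mus),
                pct_one_hb = pct)
  attr(out, "counts") <- tibble(mu = mus, n_hopf = counts)
  class(out) <- c("range_survey", class(out))
  out
}

#' Survey all published parameter ranges
#'
#' Runs [survey_range()] for each requested parameter over its published
#' range and collects the single-Hopf percentages in the layout of the
#' published table.
#'
#' @param params an [nfkb_params()] object.
#' @param names parameters to survey (default: all except TR).
#' @param n_grid grid points per parameter.
#' @param ... passed to [survey_range()].
#' @return A tibble with `param_num`, `param_name`, `range_lo`,
#'   `range_hi`, `pct_one_hb`.
#' @export
survey_table <- function(params, names = NULL, n_grid = 201, ...) {
  tab <- param_table()
  names <- names %||% setdiff(tab$name, "TR")
  rows <- lapply(names, function(nm) {
    sv <- survey_range(params, nm, n_grid = n_grid, ...)
    tibble(param_num = tab$num[tab$name == nm], param_name = nm,
           range_lo = sv$range_lo, range_hi = sv$range_hi,
           pct_one_hb = sv$pct_one_hb)
  })
  dplyr::bind_rows(rows)
}
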