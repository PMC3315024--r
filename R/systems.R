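# ode_system: the light container the continuation and limit-cycle
# machinery operates on. It couples a right-hand side f(y, pars), an
# (optional) analytic Jacobian J(y, pars), a named parameter list, and an
# optional compiled-backend description used for long integrations.

#' Construct an ODE system
#'
#' Bundles a right-hand side, an optional analytic Jacobian, parameters and
#' metadata into the object all continuation, Hopf-detection and limit-cycle
#' functions consume. When `jac` is `NULL`, Jacobians are computed by
#' central finite differences.
#'
#' @param rhs function `(y, pars) -> dy` returning the derivative vector.
#' @param pars named list of parameters.
#' @param state_names character vector naming the state components.
#' @param jac optional function `(y, pars) -> matrix`.
#' @param compiled optional list describing a compiled deSolve backend:
#'   `dllname`, `func`, `initfunc`, and `parms(pars)` returning the numeric
#'   parameter vector in the order the C code expects.
#' @param name short label used in printing.
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(rhs, pars, state_names, jac = NULL, compiled = NULL,
                       name = "ode_system") {
  stopifnot(is.function(rhs), is.list(pars), is.character(state_names))
  structure(
    list(rhs = rhs, jac = jac, pars = pars, state_names = state_names,
         dim = length(state_names), compiled = compiled, name = name),
    class = "ode_system"
  )
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("<ode_system: %s, %d states, %d parameters%s>\n", x$name,
              x$dim, length(x$pars),
              if (!is.null(x$compiled)) ", compiled backend" else ""))
  invisible(x)
}

#' Set a parameter of an ODE system
#'
#' @param sys an [ode_system()].
#' @param name parameter name.
#' @param value new value.
#' @return The modified system.
#' @export
set_par <- function(sys, name, value) {
  if (!name %in% names(sys$pars)) {
    abort(paste0("unknown parameter '", name, "'; available: ",
                 paste(names(sys$pars), collapse = ", ")))
  }
  sys$pars[[name]] <- value
  sys
}

system_jacobian <- function(sys, y, pars = sys$pars) {
  if (!is.null(sys$jac)) return(sys$jac(y, pars))
  fd_jacobian(function(z) sys$rhs(z, pars), y)
}

# central finite differences, step scaled per component
fd_jacobian <- function(f, y, eps = 1e-7) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- eps * max(abs(y[j]), 1)
    yp <- y; ym <- y
    yp[j] <- yp[j] + hj
    ym[j] <- ym[j] - hj
    J[, j] <- (f(yp) - f(ym)) / (2 * hj)
  }
  J
}

#' The NF-kB model as an ODE system
#'
#' Wraps the reduced 11-variable model (or the full 14-variable one) into
#' an [ode_system()] with analytic Jacobian and compiled integration
#' backend. Time unit: minutes.
#'
#' @param params an [nfkb_params()] object.
#' @param full use the full 14-species model (no analytic Jacobian).
#' @return An `ode_system`.
#' @examples
#' sys <- nfkb_system(nfkb_params(TR = 0.2))
#' @export
nfkb_system <- function(params = nfkb_params(), full = FALSE) {
  stopifnot(inherits(params, "nfkb_params"))
  parms_vec <- function(pars) unlist(pars)[.param_order]
  if (full) {
    return(ode_system(
      rhs = function(y, pars) nfkb_rhs_full(y, pars),
      pars = params,
      state_names = nfkb_species_full(),
      compiled = list(dllname = "nfkbosc", func = "nfkb_derivs_full",
                      initfunc = "nfkb_initmod", parms = parms_vec),
      name = "NF-kB (full, 14 species)"
    ))
  }
  ode_system(
    rhs = function(y, pars) nfkb_rhs(y, pars),
    jac = function(y, pars) nfkb_jacobian(y, pars),
    pars = params,
    state_names = nfkb_species(),
    compiled = list(dllname = "nfkbosc", func = "nfkb_derivs",
                    initfunc = "nfkb_initmod", parms = parms_vec),
    name = "NF-kB (reduced, 11 species)"
  )
}

# ---------------------------------------------------------------------------
# Oracle fixtures: small systems whose Hopf structure is known analytically.
# They are the correctness gate for the numerical machinery.

#' Hopf normal-form fixture
#'
#' The planar system `x' = alpha*x - omega*y + s*x*(x^2+y^2)`,
#' `y' = omega*x + alpha*y + s*y*(x^2+y^2)`. It has an equilibrium at the
#' origin for every `alpha`, a Hopf bifurcation exactly at `alpha = 0` with
#' angular frequency `omega`, and the bifurcation is supercritical for
#' `s = -1` (stable cycle of radius `sqrt(alpha)` and period `2*pi/omega`
#' for `alpha > 0`) and subcritical for `s = +1`.
#'
#' @param omega angular frequency, `> 0`.
#' @param s cubic coefficient sign: `-1` supercritical, `+1` subcritical.
#' @param alpha initial value of the bifurcation parameter.
#' @return An `ode_system` with attribute `known` listing the exact facts.
#' @export
make_hopf_normal_form <- function(omega, s = -1, alpha = -0.5) {
  stopifnot(omega > 0, s %in% c(-1, 1))
  rhs <- function(y, pars) {
    r2 <- y[1]^2 + y[2]^2
    c(pars$alpha * y[1] - pars$omega * y[2] + pars$s * y[1] * r2,
      pars$omega * y[1] + pars$alpha * y[2] + pars$s * y[2] * r2)
  }
  jac <- function(y, pars) {
    x1 <- y[1]; x2 <- y[2]; s <- pars$s
    r2 <- x1^2 + x2^2
    matrix(c(pars$alpha + s * (r2 + 2 * x1^2),
             -pars$omega + s * 2 * x1 * x2,
             pars$omega + s * 2 * x1 * x2,
             pars$alpha + s * (r2 + 2 * x2^2)),
           2, 2, byrow = TRUE)
  }
  sys <- ode_system(rhs, list(alpha = alpha, omega = omega, s = s),
                    c("x", "y"), jac = jac, name = "Hopf normal form")
  attr(sys, "known") <- list(
    hopf_par = "alpha", hopf_at = 0, omega = omega,
    criticality = if (s == -1) "supercritical" else "subcritical",
    cycle_radius = function(alpha) sqrt(max(alpha, 0)),
    period = 2 * pi / omega
  )
  sys
}

#' Brusselator fixture
#'
#' The Brusselator `x' = a - (b+1)x + x^2 y`, `y' = bx - x^2 y` with
#' equilibrium `(a, b/a)` for all parameter values and a supercritical Hopf
#' bifurcation at `b = 1 + a^2`, where the Jacobian trace vanishes; the
#' critical frequency is `omega = a`.
#'
#' @param a positive parameter.
#' @param b initial value of the bifurcation parameter.
#' @return An `ode_system` with attribute `known`.
#' @export
make_brusselator <- function(a, b = 1) {
  stopifnot(a > 0)
  rhs <- function(y, pars) {
    c(pars$a - (pars$b + 1) * y[1] + y[1]^2 * y[2],
      pars$b * y[1] - y[1]^2 * y[2])
  }
  jac <- function(y, pars) {
    matrix(c(-(pars$b + 1) + 2 * y[1] * y[2], pars$b - 2 * y[1] * y[2],
             y[1]^2, -y[1]^2), 2, 2)
  }
  sys <- ode_system(rhs, list(a = a, b = b), c("x", "y"), jac = jac,
                    name = "Brusselator")
  attr(sys, "known") <- list(
    hopf_par = "b", hopf_at = 1 + a^2, omega = a,
    criticality = "supercritical",
    equilibrium = function(pars) c(pars$a, pars$b / pars$a)
  )
  sys
}

#' Normal-form family with prescribed Hopf locus
#'
#' A two-parameter family built on the supercritical normal form whose Hopf
#' point in the slice parameter `TR` sits exactly at `TR = mu`: the linear
#' growth rate is `alpha = TR - mu`. Used to exercise the two-parameter
#' slicing machinery against an exactly known Hopf curve.
#'
#' @param omega angular frequency of the fixture.
#' @return An `ode_system` with parameters `TR` and `mu`.
#' @export
make_hopf_locus_family <- function(omega = 1) {
  rhs <- function(y, pars) {
    a <- pars$TR - pars$mu
    r2 <- y[1]^2 + y[2]^2
    c(a * y[1] - pars$omega * y[2] - y[1] * r2,
      pars$omega * y[1] + a * y[2] - y[2] * r2)
  }
  jac <- function(y, pars) {
    a <- pars$TR - pars$mu
    x1 <- y[1]; x2 <- y[2]
    r2 <- x1^2 + x2^2
    matrix(c(a - (r2 + 2 * x1^2), -pars$omega - 2 * x1 * x2,
             pars$omega - 2 * x1 * x2, a - (r2 + 2 * x2^2)),
           2, 2, byrow = TRUE)
  }
  sys <- ode_system(rhs, list(TR = 0.1, mu = 0.5, omega = omega),
                    c("x", "y"), jac = jac, name = "Hopf locus family")
  attr(sys, "known") <- list(hopf_par = "TR", hopf_at = function(mu) mu,
                             omega = omega, criticality = "supercritical")
  sys
}

#' Randomly perturbed parameter sets
#'
#' Multiplies every parameter except `TR` by an independent uniform factor
#' in `[1 - fraction, 1 + fraction]`. Deterministic for a fixed `seed`;
#' the global random-number state is left untouched.
#'
#' @param params an [nfkb_params()] object.
#' @param fraction perturbation half-width, in `(0, 1)`; `0` returns the
#'   input unchanged.
#' @param seed integer seed.
#' @return A perturbed `nfkb_params` object with attribute `seed`.
#' @export
perturb_parameters <- function(params, fraction, seed) {
  stopifnot(inherits(params, "nfkb_params"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(params)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  nm <- setdiff(.param_order, "TR")
  fac <- stats::runif(length(nm), 1 - fraction, 1 + fraction)
  out <- params
  for (i in seq_along(nm)) out[[nm[i]]] <- out[[nm[i]]] * fac[i]
  out <- do.call(nfkb_params, unclass(out))
  attr(out, "seed") <- as.integer(seed)
  out
}
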