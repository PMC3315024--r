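# Reduced 11-ODE NF-kB model: right-hand sides, Hill terms, conservation
# bookkeeping and the analytic Jacobian.
#
# Unit conventions, fixed throughout the package:
#  * concentrations are cytoplasmic-equivalent uM for every species, nuclear
#    ones included; the actual nuclear concentration of a nuclear species is
#    kv times its state value, and that actual concentration is what drives
#    NF-kB-dependent transcription;
#  * both conservation laws are plain sums of the state values;
#  * rate constants are stored per second (as published) and the dynamics
#    are expressed per minute by a uniform factor of 60 in the derivatives,
#    so all times, eigenvalues and periods downstream are in minutes.

#' Species names
#'
#' `nfkb_species()` returns the 11 dynamical species of the reduced model;
#' `nfkb_species_full()` the 14 species of the full model (adding inactive
#' IKK, the cytoplasmic IkBa-NF-kB complex and free phosphorylated IkBa,
#' which the reduction eliminates).
#'
#' @return Character vector of species names.
#' @export
nfkb_species <- function() {
  c("IKKn", "IKK", "IkBa", "IkBan", "NFkB", "NFkBn", "IkBaNFkBn",
    "pIkBaNFkB", "A20", "A20t", "IkBat")
}

#' @rdname nfkb_species
#' @export
nfkb_species_full <- function() {
  c(nfkb_species(), "IKKi", "IkBaNFkB", "pIkBa")
}

.SECONDS_PER_MIN <- 60

#' Hill regulatory functions
#'
#' `hill_activation` is the increasing Hill function
#' `beta * x^h / (k^h + x^h)` used for NF-kB-driven transcription of the
#' IkBa and A20 genes; it is half-maximal at `x = k` and saturates at
#' `beta`. `hill_inhibition` is the decreasing form `beta / (k + x)` used
#' for the A20 block of IKK recycling.
#'
#' @param x input concentration (uM), `x >= 0`; vectorised.
#' @param beta maximal rate (activation) or numerator constant (inhibition).
#' @param k half-maximal concentration (uM), `k > 0`.
#' @param h Hill coefficient, `h > 0`.
#' @return Numeric vector of rates (activation) or dimensionless factors
#'   (inhibition, when `beta = k`).
#' @examples
#' hill_activation(0.065, beta = 1, k = 0.065, h = 2)  # half-maximal
#' hill_inhibition(0, beta = 0.0018, k = 0.0018)       # unstimulated: 1
#' @export
hill_activation <- function(x, beta, k, h) {
  if (any(Re(x) < 0)) abort("hill_activation: x must be >= 0")
  if (any(beta <= 0) || any(k <= 0) || any(h <= 0)) {
    abort("hill_activation: beta, k, h must be > 0")
  }
  xh <- x^h
  beta * xh / (k^h + xh)
}

#' @rdname hill_activation
#' @export
hill_inhibition <- function(x, beta, k) {
  if (any(Re(x) < 0)) abort("hill_inhibition: x must be >= 0")
  if (any(Re(k + x) == 0)) abort("hill_inhibition: k + x must be non-zero")
  beta / (k + x)
}

#' Reduced-model right-hand side
#'
#' Time derivative (uM per minute) of the 11 retained species. The two
#' eliminated species are reconstructed from the conservation laws:
#' inactive IKK as `totalIKK - IKKn - IKK` and the cytoplasmic
#' IkBa-NF-kB complex as `totalNFkB` minus all other NF-kB-containing
#' species. Accepts complex `state` so that derivatives can be checked by
#' complex-step differentiation.
#'
#' @param state numeric (or complex) vector of length 11, ordered as
#'   [nfkb_species()].
#' @param params an [nfkb_params()] object.
#' @return Vector of 11 derivatives (uM/min).
#' @export
nfkb_rhs <- function(state, params) {
  p <- params
  IKKn <- state[1L]; IKK <- state[2L]; IkBa <- state[3L]; IkBan <- state[4L]
  NFkB <- state[5L]; NFkBn <- state[6L]; Cn <- state[7L]; Pc <- state[8L]
  A20 <- state[9L]; A20t <- state[10L]; IkBat <- state[11L]

  IKKi <- p$totalIKK - IKKn - IKK
  Cc <- p$totalNFkB - NFkB - NFkBn - Cn - Pc

  xn <- p$kv * NFkBn                       # actual nuclear NF-kB (uM)
  hillTx <- xn^p$h / (p$k^p$h + xn^p$h)
  inh <- p$kbA20 / (p$kbA20 + p$TR * A20)  # A20 block, active under TNFa

  d <- c(
    p$kp * IKKi * inh - p$TR * p$ka * IKKn,
    p$TR * p$ka * IKKn - p$ki * IKK,
    p$ktria * IkBat - p$ka1 * IkBa * NFkB + p$kd1 * Cc - p$kc2 * IKK * IkBa -
      p$kdegf * IkBa - p$ki2 * IkBa + p$kv * p$ke2 * IkBan,
    p$ki2 * IkBa - p$kv * p$ke2 * IkBan - p$kv * p$ka1 * IkBan * NFkBn +
      p$kd1 * Cn - p$kdegf * IkBan,
    -p$ka1 * IkBa * NFkB + (p$kd1 + p$kdegc) * Cc + p$kdegpin * Pc -
      p$ki1 * NFkB + p$kv * p$ke1f * NFkBn,
    p$ki1 * NFkB - p$kv * p$ke1f * NFkBn - p$kv * p$ka1 * IkBan * NFkBn +
      p$kd1 * Cn,
    p$kv * p$ka1 * IkBan * NFkBn - p$kd1 * Cn - p$kv * p$ke1c * Cn,
    p$kc3 * IKK * Cc - p$kdegpin * Pc,
    p$ktra * A20t - p$kda * A20,
    p$kitra * hillTx - p$kdegta * A20t,
    p$kitria * hillTx - p$kdegtia * IkBat
  )
  .SECONDS_PER_MIN * d
}

#' Reduced-model Jacobian
#'
#' Analytic 11 x 11 Jacobian of [nfkb_rhs()] with respect to the state,
#' in per-minute units. Entries are closed-form derivatives including the
#' chain contributions of the two conservation-law eliminations.
#'
#' @inheritParams nfkb_rhs
#' @return 11 x 11 numeric matrix (units 1/min).
#' @export
nfkb_jacobian <- function(state, params) {
  p <- params
  IKKn <- state[1L]; IKK <- state[2L]; IkBa <- state[3L]; IkBan <- state[4L]
  NFkB <- state[5L]; NFkBn <- state[6L]; Cn <- state[7L]; Pc <- state[8L]
  A20 <- state[9L]

  IKKi <- p$totalIKK - IKKn - IKK
  Cc <- p$totalNFkB - NFkB - NFkBn - Cn - Pc

  den <- p$kbA20 + p$TR * A20
  inh <- p$kbA20 / den
  dinh_dA20 <- -p$kbA20 * p$TR / den^2

  xn <- p$kv * NFkBn
  # d(hill)/d(NFkBn); zero at the origin for h > 1
  dhill <- if (xn == 0 && p$h > 1) {
    0
  } else if (xn == 0 && p$h == 1) {
    p$kv / p$k
  } else {
    p$kv * p$h * xn^(p$h - 1) * p$k^p$h / (p$k^p$h + xn^p$h)^2
  }

  kd <- p$kd1 + p$kdegc
  J <- matrix(0, 11L, 11L)

  # IKKn' = kp*IKKi*inh - TR*ka*IKKn   (IKKi = totalIKK - IKKn - IKK)
  J[1L, 1L] <- -p$kp * inh - p$TR * p$ka
  J[1L, 2L] <- -p$kp * inh
  J[1L, 9L] <- p$kp * IKKi * dinh_dA20
  # IKK' = TR*ka*IKKn - ki*IKK
  J[2L, 1L] <- p$TR * p$ka
  J[2L, 2L] <- -p$ki
  # IkBa'
  J[3L, 2L] <- -p$kc2 * IkBa
  J[3L, 3L] <- -p$ka1 * NFkB - p$kc2 * IKK - p$kdegf - p$ki2
  J[3L, 4L] <- p$kv * p$ke2
  J[3L, 5L] <- -p$ka1 * IkBa - p$kd1
  J[3L, 6L] <- -p$kd1
  J[3L, 7L] <- -p$kd1
  J[3L, 8L] <- -p$kd1
  J[3L, 11L] <- p$ktria
  # IkBan'
  J[4L, 3L] <- p$ki2
  J[4L, 4L] <- -p$kv * p$ke2 - p$kv * p$ka1 * NFkBn - p$kdegf
  J[4L, 6L] <- -p$kv * p$ka1 * IkBan
  J[4L, 7L] <- p$kd1
  # NFkB'
  J[5L, 3L] <- -p$ka1 * NFkB
  J[5L, 5L] <- -p$ka1 * IkBa - kd - p$ki1
  J[5L, 6L] <- -kd + p$kv * p$ke1f
  J[5L, 7L] <- -kd
  J[5L, 8L] <- -kd + p$kdegpin
  # NFkBn'
  J[6L, 4L] <- -p$kv * p$ka1 * NFkBn
  J[6L, 5L] <- p$ki1
  J[6L, 6L] <- -p$kv * p$ke1f - p$kv * p$ka1 * IkBan
  J[6L, 7L] <- p$kd1
  # IkBaNFkBn'
  J[7L, 4L] <- p$kv * p$ka1 * NFkBn
  J[7L, 6L] <- p$kv * p$ka1 * IkBan
  J[7L, 7L] <- -p$kd1 - p$kv * p$ke1c
  # pIkBaNFkB' = kc3*IKK*Cc - kdegpin*Pc
  J[8L, 2L] <- p$kc3 * Cc
  J[8L, 5L] <- -p$kc3 * IKK
  J[8L, 6L] <- -p$kc3 * IKK
  J[8L, 7L] <- -p$kc3 * IKK
  J[8L, 8L] <- -p$kc3 * IKK - p$kdegpin
  # A20' / mRNAs
  J[9L, 9L] <- -p$kda
  J[9L, 10L] <- p$ktra
  J[10L, 6L] <- p$kitra * dhill
  J[10L, 10L] <- -p$kdegta
  J[11L, 6L] <- p$kitria * dhill
  J[11L, 11L] <- -p$kdegtia

  .SECONDS_PER_MIN * J
}

#' Full 14-species right-hand side
#'
#' The model before reduction: inactive IKK, the cytoplasmic IkBa-NF-kB
#' complex and free phosphorylated IkBa are carried explicitly. Used as an
#' independent cross-check that the reduction is exact.
#'
#' @param state numeric vector of length 14, ordered as
#'   [nfkb_species_full()].
#' @inheritParams nfkb_rhs
#' @return Vector of 14 derivatives (uM/min).
#' @export
nfkb_rhs_full <- function(state, params) {
  p <- params
  IKKn <- state[1L]; IKK <- state[2L]; IkBa <- state[3L]; IkBan <- state[4L]
  NFkB <- state[5L]; NFkBn <- state[6L]; Cn <- state[7L]; Pc <- state[8L]
  A20 <- state[9L]; A20t <- state[10L]; IkBat <- state[11L]
  IKKi <- state[12L]; Cc <- state[13L]; pIkBa <- state[14L]

  xn <- p$kv * NFkBn
  hillTx <- xn^p$h / (p$k^p$h + xn^p$h)
  inh <- p$kbA20 / (p$kbA20 + p$TR * A20)

  d <- c(
    p$kp * IKKi * inh - p$TR * p$ka * IKKn,
    p$TR * p$ka * IKKn - p$ki * IKK,
    p$ktria * IkBat - p$ka1 * IkBa * NFkB + p$kd1 * Cc - p$kc2 * IKK * IkBa -
      p$kdegf * IkBa - p$ki2 * IkBa + p$kv * p$ke2 * IkBan,
    p$ki2 * IkBa - p$kv * p$ke2 * IkBan - p$kv * p$ka1 * IkBan * NFkBn +
      p$kd1 * Cn - p$kdegf * IkBan,
    -p$ka1 * IkBa * NFkB + (p$kd1 + p$kdegc) * Cc + p$kdegpin * Pc -
      p$ki1 * NFkB + p$kv * p$ke1f * NFkBn,
    p$ki1 * NFkB - p$kv * p$ke1f * NFkBn - p$kv * p$ka1 * IkBan * NFkBn +
      p$kd1 * Cn,
    p$kv * p$ka1 * IkBan * NFkBn - p$kd1 * Cn - p$kv * p$ke1c * Cn,
    p$kc3 * IKK * Cc - p$kdegpin * Pc,
    p$ktra * A20t - p$kda * A20,
    p$kitra * hillTx - p$kdegta * A20t,
    p$kitria * hillTx - p$kdegtia * IkBat,
    p$ki * IKK - p$kp * IKKi * inh,
    p$ka1 * IkBa * NFkB - p$kd1 * Cc - p$kc3 * IKK * Cc - p$kdegc * Cc +
      p$kv * p$ke1c * Cn,
    p$kc2 * IKK * IkBa - p$kdegpin * pIkBa
  )
  .SECONDS_PER_MIN * d
}

#' Conservation laws
#'
#' Evaluates the two conserved quantities on a full 14-species state:
#' total IKK (neutral + active + inactive) and total NF-kB (free NF-kB plus
#' every NF-kB-containing complex, cytoplasmic and nuclear alike, all in
#' cytoplasmic-equivalent uM).
#'
#' @param state full state vector of length 14.
#' @return Named numeric vector with `totalIKK` and `totalNFkB`.
#' @export
conservation_totals <- function(state) {
  c(totalIKK = unname(state[1L] + state[2L] + state[12L]),
    totalNFkB = unname(state[5L] + state[6L] + state[7L] + state[8L] +
                         state[13L]))
}

#' Map between reduced and full states
#'
#' `reconstruct_full_state` rebuilds the 14-species state from a reduced
#' state using the conservation laws (free phosphorylated IkBa, which does
#' not feed back on the rest of the system, is set to `pIkBa`);
#' `reduce_state` drops the eliminated species.
#'
#' @param state reduced state (length 11) or full state (length 14).
#' @param params an [nfkb_params()] object.
#' @param pIkBa value for the decoupled phospho-IkBa pool (default 0).
#' @return Numeric state vector of length 14 (or 11).
#' @export
reconstruct_full_state <- function(state, params, pIkBa = 0) {
  IKKi <- params$totalIKK - state[1L] - state[2L]
  Cc <- params$totalNFkB - state[5L] - state[6L] - state[7L] - state[8L]
  out <- c(state[1:11], IKKi, Cc, pIkBa)
  names(out) <- nfkb_species_full()
  out
}

#' @rdname reconstruct_full_state
#' @export
reduce_state <- function(state) {
  out <- state[1:11]
  names(out) <- nfkb_species()
  out
}

#' Physical-domain check
#'
#' A reduced state is physical when all 11 components and both eliminated
#' species (reconstructed from the conservation laws) are non-negative.
#'
#' @inheritParams nfkb_rhs
#' @param tol tolerance below zero still accepted (integrator noise).
#' @return Logical scalar.
#' @export
in_physical_domain <- function(state, params, tol = 1e-9) {
  full <- reconstruct_full_state(state, params)
  all(full >= -tol)
}

#' Resting initial condition
#'
#' The initial condition used throughout: all NF-kB bound in the
#' cytoplasmic IkBa-NF-kB complex (concentration `totalNFkB`) and all IKK
#' neutral (concentration `totalIKK`); every other species zero. In the
#' reduced coordinates the complex is the eliminated species, so the
#' reduced vector is zero except for `IKKn`.
#'
#' @param params an [nfkb_params()] object.
#' @param full return the 14-species state instead of the reduced one.
#' @return Named state vector.
#' @export
nfkb_initial_state <- function(params, full = FALSE) {
  red <- setNames(numeric(11L), nfkb_species())
  red["IKKn"] <- params$totalIKK
  if (!full) return(red)
  reconstruct_full_state(red, params)
}
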