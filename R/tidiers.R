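# broom-style tidiers for the fitted/derived objects.

#' @method tidy equilibrium
#' @export
tidy.equilibrium <- function(x, ...) {
  tibble(species = names(x$state), value = unname(x$state))
}

#' @method glance equilibrium
#' @export
glance.equilibrium <- function(x, ...) {
  lc <- leading_complex(x$eigenvalues)
  tibble(stability = x$stability, residual = x$residual,
         converged = x$converged, max_re_eig = unname(lc["re"]),
         freq_im_eig = unname(lc["im"]))
}

#' @method tidy bifurcation_branch
#' @export
tidy.bifurcation_branch <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "par_name") <- NULL
  attr(out, "sys") <- NULL
  attr(out, "truncated") <- NULL
  out
}

#' @method glance bifurcation_branch
#' @export
glance.bifurcation_branch <- function(x, ...) {
  tibble(par_name = attr(x, "par_name"), n_points = nrow(x),
         par_min = min(x$param_value), par_max = max(x$param_value),
         n_stability_changes = sum(diff(as.integer(
           factor(x$stability))) != 0),
         truncated = isTRUE(attr(x, "truncated")))
}

#' @method tidy hopf_set
#' @export
tidy.hopf_set <- function(x, ...) {
  out <- as_tibble(x)
  out$state <- NULL
  out
}

#' @method glance hopf_set
#' @export
glance.hopf_set <- function(x, ...) {
  tibble(n_hopf = nrow(x),
         par_min = if (nrow(x)) min(x$param_value) else NA_real_,
         par_max = if (nrow(x)) max(x$param_value) else NA_real_)
}

#' @method tidy sensitivity_table
#' @export
tidy.sensitivity_table <- function(x, ...) as_tibble(x)

#' @method glance sensitivity_table
#' @export
glance.sensitivity_table <- function(x, ...) {
  tibble(mode = attr(x, "mode"), reference = attr(x, "reference"),
         n = nrow(x), n_ok = sum(x$ok),
         n_high = sum(!is.na(x$score) & abs(x$score) >= 0.5))
}

#' @method tidy nfkb_one_param
#' @export
tidy.nfkb_one_param <- function(x, ...) tidy(x$hopf)

#' @method glance nfkb_one_param
#' @export
glance.nfkb_one_param <- function(x, ...) {
  dplyr::bind_cols(glance(x$branch), tibble(n_hopf = nrow(x$hopf)))
}
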