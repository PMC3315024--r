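# Model parameters: the 26 reaction rates plus the stimulation intensity TR
# and the two conserved totals. Values are stored exactly as published
# (per-second rate constants, concentrations in uM); all dynamics functions
# convert uniformly to a minutes time base (see nfkb_rhs).

.param_order <- c(
  "TR", "totalIKK", "totalNFkB", "kv", "kp", "ka", "ki", "kda", "kbA20",
  "kc2", "kc3", "kdegpin", "ka1", "kd1", "kdegf", "kdegc", "ki1", "ke1f",
  "ke1c", "ki2", "ke2", "h", "k", "kitria", "ktria", "kdegtia", "kitra",
  "ktra", "kdegta"
)

.param_defaults <- c(
  TR = 1.0, totalIKK = 0.08, totalNFkB = 0.08, kv = 3.3,
  kp = 0.0006, ka = 0.004, ki = 0.003, kda = 0.0045, kbA20 = 0.0018,
  kc2 = 0.074, kc3 = 0.37, kdegpin = 0.1, ka1 = 0.5, kd1 = 0.0005,
  kdegf = 0.0005, kdegc = 0.000022, ki1 = 0.0026, ke1f = 52e-6,
  ke1c = 0.01, ki2 = 0.00067, ke2 = 3.35e-4, h = 2, k = 0.065,
  kitria = 1.4e-7, ktria = 0.5, kdegtia = 0.0003, kitra = 1.4e-7,
  ktra = 0.5, kdegta = 0.00048
)

# Published survey ranges and parameter numbering. `num` follows the main
# parameter table; `num_alt` follows the numbering used alongside the
# sensitivity scores (identical up to ke2, one higher from h on).
.param_ranges <- data.frame(
  num = 1:29,
  name = c("TR", "totalIKK", "totalNFkB", "kv", "kp", "ka", "ki", "kda",
           "kbA20", "kc2", "kc3", "kdegpin", "ka1", "kd1", "kdegf", "kdegc",
           "ki1", "ke1f", "ke1c", "ki2", "ke2", "h", "k", "kitria", "ktria",
           "kdegtia", "kitra", "ktra", "kdegta"),
  lo = c(0, 0.001943, 0.032147, 1.7658, 1.00e-05, 0.00010279, 0.0007336,
         9.48e-05, 6.81e-06, 0.00028691, 0.0029809, 0, 0.10325, 0.0002,
         0.0004, 0, 0.00155, 0, 4.48e-05, 6.84e-05, 0, 0.68071, 0.055,
         7.06e-08, 0.20438, 4.98e-06, 5.13e-08, 0.18323, 3.30e-05),
  hi = c(1, 0.21102, 0.1, 5.7363, 0.0015968, 2.9586, 0.11817, 0.021019,
         0.0093601, 0.46452, 1.07, 0.736, 1.629, 0.01128, 0.0014042,
         0.00019312, 0.047406, 0.00021787, 0.38702, 0.0015916, 0.016038,
         2.4335, 0.11369, 1.68e-07, 0.6, 0.00059088, 2.63e-06, 11.436,
         0.0020154),
  description = c(
    "TNFa stimulation intensity (0 = none, 1 = saturating)",
    "Total IKK kinase (conserved)",
    "Total NF-kB (conserved)",
    "Cytoplasmic to nuclear volume ratio",
    "IKK recycling (inactive to neutral)",
    "IKK activation by TNFa signal",
    "Spontaneous IKK inactivation",
    "Constitutive A20 degradation",
    "A20 inhibition of IKK recycling (half-effect concentration)",
    "IKK-mediated phosphorylation of free IkBa",
    "IKK-mediated phosphorylation of the IkBa-NF-kB complex",
    "Degradation of phosphorylated IkBa species",
    "IkBa-NF-kB association",
    "IkBa-NF-kB dissociation",
    "Constitutive degradation of free IkBa",
    "Constitutive degradation of the IkBa-NF-kB complex",
    "NF-kB nuclear import",
    "Free NF-kB nuclear export",
    "IkBa-NF-kB complex nuclear export",
    "IkBa nuclear import",
    "IkBa nuclear export",
    "Hill coefficient of NF-kB-driven transcription",
    "Nuclear NF-kB concentration at half-maximal transcription",
    "Inducible IkBa mRNA synthesis (maximal rate)",
    "IkBa translation rate",
    "IkBa mRNA degradation",
    "Inducible A20 mRNA synthesis (maximal rate)",
    "A20 translation rate",
    "A20 mRNA degradation"
  ),
  stringsAsFactors = FALSE
)
.param_ranges$num_alt <- .param_ranges$num + (.param_ranges$num >= 22)
.param_ranges$default <- unname(.param_defaults[.param_ranges$name])

# accepted aliases in config files
.param_aliases <- c(totIKK = "totalIKK", totNFkB = "totalNFkB", tr = "TR")

#' Model parameter set
#'
#' Constructs the parameter set of the two-feedback NF-kB signalling model:
#' the 26 reaction rate constants, the Hill pair (`h`, `k`), the
#' cytoplasmic:nuclear volume ratio `kv`, the two conserved totals
#' (`totalNFkB`, `totalIKK`, in uM) and the dimensionless TNFa stimulation
#' intensity `TR`. Defaults are the published model values; rate constants
#' are per second, concentrations in uM.
#'
#' @param ... named overrides of individual parameters, e.g.
#'   `nfkb_params(totalNFkB = 0.15)`.
#' @return A named list of class `nfkb_params`.
#' @examples
#' p <- nfkb_params()
#' p$TR
#' nfkb_params(TR = 0.5, totalNFkB = 0.15)$totalNFkB
#' @export
nfkb_params <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  p <- as.list(.param_defaults)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", "),
                   "; valid names: ", paste(.param_order, collapse = ", ")))
    }
    p[names(over)] <- lapply(over, as.numeric)
  }
  validate_params(p)
  structure(p, class = "nfkb_params")
}

validate_params <- function(p) {
  stopifnot(setequal(names(p), .param_order))
  vals <- unlist(p)
  if (any(!is.finite(vals))) abort("all parameters must be finite")
  if (p$TR < 0) abort("TR must be >= 0")
  pos <- setdiff(.param_order, "TR")
  neg <- pos[unlist(p[pos]) <= 0]
  if (length(neg)) {
    abort(paste0("parameter(s) must be strictly positive: ",
                 paste(neg, collapse = ", ")))
  }
  invisible(p)
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("<nfkb_params>\n")
  v <- unlist(x)[.param_order]
  changed <- abs(v - .param_defaults[.param_order]) >
    1e-15 * pmax(abs(.param_defaults[.param_order]), 1e-300)
  for (i in seq_along(v)) {
    cat(sprintf("  %-10s %-12g%s\n", names(v)[i], v[i],
                if (changed[i]) "  (changed)" else ""))
  }
  invisible(x)
}

#' Published parameter table with survey ranges
#'
#' The model parameters with their published survey ranges, default values
#' and both numbering schemes (`num` as in the parameter table, `num_alt`
#' as used with the sensitivity scores).
#'
#' @return A tibble with columns `num`, `num_alt`, `name`, `description`,
#'   `default`, `lo`, `hi`.
#' @export
param_table <- function() {
  as_tibble(.param_ranges[, c("num", "num_alt", "name", "description",
                              "default", "lo", "hi")])
}

#' Read and write parameter configurations
#'
#' Parameter sets round-trip through flat key-value JSON or YAML files.
#' Keys are the parameter names; `totIKK` and `totNFkB` are accepted as
#' aliases on input.
#'
#' @param params an `nfkb_params` object.
#' @param path file path; format inferred from the extension
#'   (`.json`, `.yaml`/`.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `read_params` returns an `nfkb_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path, format = NULL) {
  stopifnot(inherits(params, "nfkb_params"))
  format <- format %||% guess_format(path)
  x <- as.list(unlist(params)[.param_order])
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  x <- if (format == "json") jsonlite::read_json(path) else yaml::read_yaml(path)
  nm <- names(x)
  hit <- nm %in% names(.param_aliases)
  nm[hit] <- .param_aliases[nm[hit]]
  names(x) <- nm
  do.call(nfkb_params, x)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = "json",
    yaml = "yaml",
    yml = "yaml",
    abort(paste0("cannot infer config format from extension '.", ext,
                 "'; pass format = \"json\" or \"yaml\""))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
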