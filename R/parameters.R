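#' Calibrated model parameters
#'
#' Returns the full calibrated parameter set of the model in CGS units
#' (cm, s, g, cells). Rates are per second, concentrations in g/cm^3,
#' diffusivities in cm^2/s. The 400 um tissue strip is stored as
#' `L_domain = 0.04` cm. `T_max` is a simulation cap (the model is run to
#' numerical equilibrium, not to a biologically prescribed horizon) and is
#' therefore a configuration field rather than part of the calibration.
#'
#' Fields:
#' * `beta_n`, `theta` — cell motility (cm^2/s) and rate of spontaneous
#'   phenotypic change (1/s); both act as diffusivities, in space and in
#'   trait space respectively.
#' * `beta_o`, `beta_g`, `beta_l` — substrate diffusivities;
#'   `lambda_o`, `lambda_g`, `lambda_l` — natural decay rates.
#' * `gamma_o`, `alpha_o` — maximal rate and Michaelis constant of
#'   proliferation via oxidative phosphorylation; `gamma_g`, `alpha_g` —
#'   same for glycolysis.
#' * `eta_o`, `eta_l` — selection gradients (curvature of the quadratic
#'   fitness penalty around the fittest trait) for oxygen- and
#'   lactate-driven selection.
#' * `kappa` — crowding death coefficient (cm^3/s per cell); the local
#'   carrying capacity scales as proliferation rate / `kappa`.
#' * `zeta_o`, `zeta_g`, `zeta_l` — conversion factors (g per cell) for
#'   substrate consumption/production.
#' * `O_m`, `O_M` — oxygen thresholds separating hypoxic, moderately
#'   oxygenated and normoxic habitats; `L_m`, `L_M` — lactate thresholds
#'   separating mildly, moderately and highly acidic habitats.
#' * `S_bar_o`, `S_bar_g` — vessel-side Dirichlet values for oxygen and
#'   glucose; `S_under_o`, `S_under_g` — far-field Dirichlet values;
#'   `S_under_l` — vessel-side lactate value (lactate has zero-flux at the
#'   far end).
#'
#' @return An object of class `"eet_params"` (named list of scalars).
#' @export
#' @examples
#' p <- default_parameters()
#' p$gamma_o       # 3.65e-7 / s
#' validate_parameters(p)  # character(0)
default_parameters <- function() {
  p <- list(
    # cells
    beta_n  = 1e-13,
    theta   = 1e-13,
    # substrates: diffusion and decay
    beta_o  = 1.46e-5,
    beta_g  = 1.10e-6,
    beta_l  = 1.9e-6,
    lambda_o = 1.2e-3,
    lambda_g = 2.33e-5,
    lambda_l = 5e-2,
    # metabolism
    gamma_o = 3.65e-7,
    alpha_o = 6.4e-9,
    gamma_g = 3.42e-7,
    alpha_g = 9e-6,
    # selection and crowding
    eta_o   = 3.65e-2,
    eta_l   = 1e-2,
    kappa   = 2e-10,
    # conversion factors
    zeta_o  = 1e-8,
    zeta_g  = 1e-8,
    zeta_l  = 1e-8,
    # habitat thresholds
    O_m     = 8.2e-9,
    O_M     = 4.3e-7,
    L_m     = 2e-5,
    L_M     = 7.15e-5,
    # boundary values
    S_bar_o   = 2.08e-6,
    S_bar_g   = 1.35e-4,
    S_under_o = 2e-10,
    S_under_g = 1.35e-6,
    S_under_l = 1e-8,
    # geometry and horizon
    L_domain = 0.04,
    T_max    = 1e9
  )
  class(p) <- "eet_params"
  p
}

#' Validate a parameter set
#'
#' Checks positivity of every field and the biological ordering constraints
#' that make the habitat classification and boundary calibration coherent:
#' `O_M > O_m`, `L_M > L_m`, `S_bar_o > O_M` (the vessel is normoxic),
#' `S_under_o < O_m` (the far field is hypoxic), `S_under_l < L_m` (the
#' vessel side is mildly acidic), and `S_under_o < S_bar_o`,
#' `S_under_g < S_bar_g`.
#'
#' Reporting, not raising: returns a character vector of violation
#' descriptions, empty when the set is valid.
#'
#' @param params An `"eet_params"` object or compatible named list.
#' @return Character vector of violations (possibly empty).
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  fields <- setdiff(names(default_parameters()), character(0))
  for (f in fields) {
    val <- params[[f]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      v <- c(v, sprintf("%s: missing or non-finite", f))
    } else if (val <= 0) {
      v <- c(v, sprintf("%s: must be strictly positive (got %g)", f, val))
    }
  }
  chk <- function(cond, msg) if (isTRUE(cond)) character(0) else msg
  num <- function(f) {
    val <- params[[f]]
    if (is.numeric(val) && length(val) == 1L && is.finite(val)) val else NA_real_
  }
  ord <- function(a, b, msg) {
    x <- num(a); y <- num(b)
    if (is.na(x) || is.na(y)) return(character(0))  # already reported above
    chk(x < y, sprintf("%s/%s: require %s < %s (got %g >= %g)", a, b, a, b, x, y))
  }
  v <- c(v,
    ord("O_m", "O_M", NULL),
    ord("L_m", "L_M", NULL),
    ord("O_M", "S_bar_o", NULL),
    ord("S_under_o", "O_m", NULL),
    ord("S_under_l", "L_m", NULL),
    ord("S_under_o", "S_bar_o", NULL),
    ord("S_under_g", "S_bar_g", NULL)
  )
  v
}

# Solver/experiment option keys accepted in configuration documents,
# with their defaults. Numeric unless listed in .eet_config_string_keys.
.eet_config_option_defaults <- function() {
  list(
    nx = 200, ny = 41,
    dt = NA_real_,                 # NA => automatic stable step
    abiotic_mode = "quasi-stationary",
    stability_safety = 0.9,
    equilibrium_tol = 1e-12,
    max_steps = 100000,
    record_every = 1,
    preset = "baseline",
    seed = NA_real_                # placeholder: the model is deterministic
  )
}
.eet_config_string_keys <- c("abiotic_mode", "preset")

#' Load a flat key-value configuration
#'
#' Parses a flat TOML-style document (`key = value` lines, `#` comments).
#' Keys are either model-parameter fields (see [default_parameters()]) or
#' solver/experiment options (`nx`, `ny`, `dt`, `abiotic_mode`,
#' `stability_safety`, `equilibrium_tol`, `max_steps`, `record_every`,
#' `preset`, `seed`). Missing keys fall back to defaults; unknown keys are
#' rejected; the resulting parameter set must validate.
#'
#' @param text Character scalar (whole document) or vector of lines.
#'   Ignored when `path` is given.
#' @param path Optional file to read.
#' @param overrides Optional named list applied after the document
#'   (the programmatic equivalent of `--set key=value`).
#' @return List with elements `params` (an `"eet_params"`) and `options`
#'   (solver/experiment options).
#' @export
#' @examples
#' cfg <- load_config("eta_l = 3.65e-3")
#' cfg$params$eta_o / cfg$params$eta_l   # ratio 10
load_config <- function(text = NULL, path = NULL, overrides = NULL) {
  if (!is.null(path)) text <- readLines(path, warn = FALSE)
  if (is.null(text)) text <- character(0)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop(sprintf("configuration parse failure at line: '%s'", ln), call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  for (k in names(overrides)) kv[[k]] <- overrides[[k]]

  params <- default_parameters()
  options <- .eet_config_option_defaults()
  for (k in names(kv)) {
    val <- kv[[k]]
    if (k %in% names(params)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop(sprintf("configuration key '%s': numeric value expected, got '%s'",
                     k, as.character(val)), call. = FALSE)
      params[[k]] <- num
    } else if (k %in% names(options)) {
      if (k %in% .eet_config_string_keys) {
        options[[k]] <- gsub("\"|'", "", as.character(val))
      } else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num) && !identical(tolower(as.character(val)), "auto"))
          stop(sprintf("configuration key '%s': numeric value expected, got '%s'",
                       k, as.character(val)), call. = FALSE)
        options[[k]] <- if (is.na(num)) NA_real_ else num
      }
    } else {
      stop(sprintf("unknown configuration key '%s'", k), call. = FALSE)
    }
  }
  viol <- validate_parameters(params)
  if (length(viol) > 0)
    stop(sprintf("configuration validation failure: %s",
                 paste(viol, collapse = "; ")), call. = FALSE)
  list(params = params, options = options)
}

#' Serialise parameters (and options) to a flat configuration document
#'
#' Inverse of [load_config()]: `load_config(serialise_config(p))` restores
#' `p` bit-identically (values are written with full double precision).
#'
#' @param params An `"eet_params"` object.
#' @param options Optional solver/experiment option list.
#' @return Character vector of `key = value` lines.
#' @export
serialise_config <- function(params, options = NULL) {
  fmt <- function(x) {
    if (is.character(x)) x else sprintf("%.17g", x)
  }
  lines <- vapply(names(params), function(k) {
    sprintf("%s = %s", k, fmt(params[[k]]))
  }, character(1))
  if (!is.null(options)) {
    opt <- options[!vapply(options, function(x) is.numeric(x) && is.na(x), logical(1))]
    lines <- c(lines, vapply(names(opt), function(k) {
      sprintf("%s = %s", k, fmt(opt[[k]]))
    }, character(1)))
  }
  unname(lines)
}

#' @export
print.eet_params <- function(x, ...) {
  cat("Model parameters (CGS units):\n")
  for (k in names(x)) cat(sprintf("  %-10s = %g\n", k, x[[k]]))
  invisible(x)
}
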