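#' Parameters of the generalized sleep model
#'
#' Bundle the full parameter vector of the opportunity-cost sleep model into a
#' validated `model_params` object. Units follow the model's conventions:
#' `q` counts (10-minute) periods per day, the homeostatic decay constants
#' `nu_W`/`nu_S` are e-folding times in hours (converted to per-period decay
#' factors by [decay_factor()]), and `xi` is the opportunity-cost scale
#' normalized to 1 for captive animals.
#'
#' @param q Integer, periods per day (>= 2).
#' @param kappa Curvature of the circadian penalty (> 0); 2 is quadratic.
#' @param eta Curvature of foraging production (> 0).
#' @param gamma Curvature of foraging utility (0 < gamma <= 1).
#' @param rho Autoregressive persistence of the environmental state, quoted
#'   per hour (0 <= rho < 1); see [rho_per_period()].
#' @param nu_W,nu_S Homeostatic decay constants while awake / asleep, hours.
#' @param mu_W,mu_S Waking and sleeping asymptotes of the homeostat
#'   (`mu_W > mu_S`).
#' @param lam Wake-sleep switching cost, utility units (>= 0).
#' @param chi Weight on the circadian penalty (>= 0).
#' @param xi Opportunity-cost scale (>= 0); 1 for captive animals.
#' @param sigma Standard deviation of environmental innovations (>= 0).
#'
#' @return An object of class `model_params` (a named list of the thirteen
#'   fields above).
#' @seealso [preset()], [validate_params()], [apply_scenario()]
#' @export
#' @examples
#' p <- preset("elephant_wild")
#' p$xi
#' validate_params(p)
model_params <- function(q = 144, kappa = 2, eta = 1, gamma = 0.8, rho = 0.9,
                         nu_W = 8, nu_S = 8, mu_W = 1, mu_S = -0.9056,
                         lam = 0.2, chi = 10, xi = 1, sigma = 0) {
  p <- list(q = as.integer(q), kappa = as.numeric(kappa),
            eta = as.numeric(eta), gamma = as.numeric(gamma),
            rho = as.numeric(rho), nu_W = as.numeric(nu_W),
            nu_S = as.numeric(nu_S), mu_W = as.numeric(mu_W),
            mu_S = as.numeric(mu_S), lam = as.numeric(lam),
            chi = as.numeric(chi), xi = as.numeric(xi),
            sigma = as.numeric(sigma))
  class(p) <- "model_params"
  bad <- validate_params(p)
  if (length(bad))
    stop("invalid model parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  p
}

.param_fields <- c("q", "kappa", "eta", "gamma", "rho", "nu_W", "nu_S",
                   "mu_W", "mu_S", "lam", "chi", "xi", "sigma")

#' Check model-parameter invariants
#'
#' Reports (rather than raises) violations of the model's parameter
#' constraints, one human-readable message per violated rule.
#'
#' @param p A `model_params` object or a named list with the same fields.
#' @return Character vector of violations; empty when all invariants hold.
#' @export
validate_params <- function(p) {
  out <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) out <<- c(out, msg)
  chk(is.numeric(p$q) && length(p$q) == 1 && p$q == round(p$q) && p$q >= 2,
      "q must be an integer >= 2")
  chk(p$mu_W > p$mu_S, "mu_W > mu_S violated")
  chk(p$nu_W > 0, "nu_W must be > 0")
  chk(p$nu_S > 0, "nu_S must be > 0")
  chk(p$kappa > 0, "kappa must be > 0")
  chk(p$gamma > 0 && p$gamma <= 1, "gamma must satisfy 0 < gamma <= 1")
  chk(p$eta > 0, "eta must be > 0")
  chk(p$xi >= 0, "xi must be >= 0")
  chk(p$lam >= 0, "lam must be >= 0")
  chk(p$chi >= 0, "chi must be >= 0")
  chk(p$sigma >= 0, "sigma must be >= 0")
  chk(p$rho >= 0 && p$rho < 1, "rho must satisfy 0 <= rho < 1")
  out
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  vals <- vapply(.param_fields, function(f) format(x[[f]]), character(1))
  cat(paste0("  ", format(.param_fields), " = ", vals, collapse = "\n"), "\n")
  invisible(x)
}

#' Species parameter presets
#'
#' Load one of the four packaged parameter sets: elephants and three-toed
#' sloths, each in captivity (`xi` normalized to 1) and in the wild (`xi` and
#' `sigma` calibrated to observed daily sleep moments). Presets are shipped as
#' flat JSON files under `extdata/presets/` so new species files can be
#' derived from them; see [read_params()].
#'
#' @param name One of `"elephant_captive"`, `"elephant_wild"`,
#'   `"sloth_captive"`, `"sloth_wild"`.
#' @return A `model_params` object.
#' @export
#' @examples
#' preset("sloth_captive")$mu_W
preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "sleepcost")
  if (identical(path, ""))
    stop("unknown preset: '", name, "' (available: ",
         paste(preset_names(), collapse = ", "), ")", call. = FALSE)
  read_params(path)
}

#' @rdname preset
#' @export
preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "sleepcost")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Read and write parameter files
#'
#' Parameter files are flat JSON key-value documents whose keys are exactly
#' the `model_params` field names. Unknown keys are an error, which catches
#' typos in parameter names; missing keys fall back to nothing -- all thirteen
#' fields must be present.
#'
#' @param path File path.
#' @param p A `model_params` object (for `write_params`).
#' @return `read_params` returns a `model_params`; `write_params` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .param_fields)
  if (length(unknown))
    stop("unknown parameter name(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(.param_fields, names(raw))
  if (length(missing))
    stop("missing parameter(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(model_params, raw[.param_fields])
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  jsonlite::write_json(p[.param_fields], path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Sensitivity scenarios
#'
#' The five scenario labels used in the sensitivity analysis. `A` is the
#' benchmark (no overrides); `B` halves the homeostatic decay constants to
#' 4 h; `C` doubles the circadian weight to 20; `D` lowers the switching cost
#' to 0.02; `E` removes diminishing foraging utility (`gamma` = 1).
#'
#' @param label One of `"A"` to `"E"`.
#' @return A `scenario_spec`: list with `label`, `description`, `overrides`.
#' @export
#' @examples
#' apply_scenario(preset("elephant_wild"), scenario_spec("B"))$nu_W
scenario_spec <- function(label) {
  tab <- list(
    A = list(description = "benchmark", overrides = list()),
    B = list(description = "lower half-lives",
             overrides = list(nu_W = 4, nu_S = 4)),
    C = list(description = "higher sleep weight", overrides = list(chi = 20)),
    D = list(description = "lower switching cost",
             overrides = list(lam = 0.02)),
    E = list(description = "no diminishing utility",
             overrides = list(gamma = 1))
  )
  if (!label %in% names(tab))
    stop("unknown scenario label: '", label, "'", call. = FALSE)
  out <- c(list(label = label), tab[[label]])
  class(out) <- "scenario_spec"
  out
}

#' Apply a sensitivity scenario to a parameter set
#'
#' Returns a copy of `p` with exactly the scenario's overrides applied and
#' every other field unchanged. Idempotent: applying a scenario twice equals
#' applying it once.
#'
#' @param p A `model_params` object.
#' @param scenario A `scenario_spec` or a scenario label (`"A"`..`"E"`).
#' @return A `model_params` object.
#' @export
apply_scenario <- function(p, scenario) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(p, "model_params"), inherits(scenario, "scenario_spec"))
  do.call(model_params, modifyList(unclass(p)[.param_fields],
                                   scenario$overrides))
}

#' Observed daily sleep moments used for calibration
#'
#' The observed mean and standard deviation of daily sleep hours per species
#' and setting, as collected from the field and captivity studies the model
#' is fitted to. Shipped as `extdata/observed_moments.json`.
#'
#' @return A data frame with columns `species`, `setting`, `mean_hours`,
#'   `sd_hours`.
#' @export
observed_moments <- function() {
  path <- system.file("extdata", "observed_moments.json",
                      package = "sleepcost")
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(out)
}
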