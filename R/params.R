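#' Default species and scenario parameterization
#'
#' Returns the default life-history, recruitment, fishery, and predation
#' constants for the two modeled stocks — lingcod (*Ophiodon elongatus*,
#' sex-structured) and yelloweye rockfish (*Sebastes ruberrimus*,
#' sex-aggregated) — together with the global scenario constants: the four
#' prey-specialization levels gamma, the default bycatch proportionality b,
#' and the fishing-rate grid explored for the predator.
#'
#' All values are fixed constants of the analysis (stock-assessment and
#' diet-study estimates); they are the single source of truth used by every
#' other module. Rates are instantaneous and annual (yr^-1), lengths in cm,
#' weights in kg.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{lingcod}{`species_params` list for the predator.}
#'     \item{yelloweye}{`species_params` list for the prey.}
#'     \item{gamma_scenarios}{named numeric: none 0, generalist 0.001,
#'       intermediate 0.014, specialist 0.05.}
#'     \item{b}{default bycatch proportionality, 0.05.}
#'     \item{F_grid}{41 evenly spaced fishing rates on \[0, 0.4\].}
#'   }
#' @export
#' @examples
#' p <- default_parameters()
#' p$yelloweye$M
#' p$gamma_scenarios
default_parameters <- function() {
  lingcod <- species_params(
    name = "lingcod",
    sex_structured = TRUE,
    M = c(F = 0.18, M = 0.32),
    h = 0.8,
    R0 = 4848,
    k = c(F = 0.191, M = 0.214),
    Linf = c(F = 100.9, M = 86.3),
    a_w = c(F = 3.308e-6, M = 2.179e-6),
    b_w = c(F = 3.248, M = 3.36),
    L_min = 56,
    plus_age = 20,
    mat_a50 = c(F = 4, M = 2),
    mat_slope = c(F = 0.5, M = 0.5),
    rho = 0.23,
    sigma = 0.5,
    a_c = c(F = 3.31, M = 3.01),
    b_c = c(F = 0.71, M = 0.77),
    Y5 = 0.05,
    Y95 = 0.29,
    delta = 0.3
  )
  yelloweye <- species_params(
    name = "yelloweye",
    sex_structured = FALSE,
    M = 0.044,
    h = 0.718,
    R0 = 220,
    k = 0.049,
    Linf = 63.9,
    a_w = 7.313e-6,
    b_w = 3.242,
    L_min = 25,
    plus_age = 65,
    mat_a50 = 17.5,
    mat_slope = 0.5,
    rho = 0.23,
    sigma = 0.5
  )
  list(
    lingcod = lingcod,
    yelloweye = yelloweye,
    gamma_scenarios = c(none = 0, generalist = 0.001,
                        intermediate = 0.014, specialist = 0.05),
    b = 0.05,
    F_grid = seq(0, 0.4, length.out = 41)
  )
}

#' Construct and validate a species parameter set
#'
#' Builds the per-species constant block used throughout the package. For a
#' sex-structured species every sex-varying field must be a length-2 named
#' vector (`F`, `M`); for a sex-aggregated species scalars are expected.
#' Consumption allometry (`a_c`, `b_c`), the diet-spectra quantile slopes
#' (`Y5`, `Y95`) and handling time `delta` are predator-only fields and may be
#' `NULL` for the prey.
#'
#' @param name species label.
#' @param sex_structured logical; track the two sexes separately?
#' @param M instantaneous natural mortality (yr^-1), per sex if structured.
#' @param h Beverton-Holt steepness, 0.2 < h <= 1.
#' @param R0 recruitment at unfished equilibrium (numbers of age-1 fish).
#' @param k von Bertalanffy growth coefficient (yr^-1).
#' @param Linf asymptotic length (cm).
#' @param a_w,b_w mass-length power-law intercept (kg cm^-b_w) and exponent.
#' @param L_min minimum length caught by the fishery (cm).
#' @param plus_age terminal (plus-group) age class.
#' @param mat_a50 age at 50% maturity (yr).
#' @param mat_slope logistic maturity slope (yr^-1).
#' @param rho lag-1 autocorrelation of recruitment deviations, |rho| < 1.
#' @param sigma SD of recruitment deviations (log scale), > 0.
#' @param a_c,b_c annual consumption allometry (kg yr^-1 at 1 kg; exponent);
#'   predator only.
#' @param Y5,Y95 5th/95th quantile slopes of the predator diet size spectra
#'   (prey length as a fraction of predator length); predator only.
#' @param delta handling time of the type-II functional response (yr per unit
#'   intake); predator only.
#' @return A validated list of class `species_params`.
#' @export
species_params <- function(name, sex_structured, M, h, R0, k, Linf,
                           a_w, b_w, L_min, plus_age, mat_a50, mat_slope,
                           rho, sigma,
                           a_c = NULL, b_c = NULL, Y5 = NULL, Y95 = NULL,
                           delta = NULL) {
  p <- list(
    name = name, sex_structured = isTRUE(sex_structured),
    M = M, h = h, R0 = R0, k = k, Linf = Linf, a_w = a_w, b_w = b_w,
    L_min = L_min, plus_age = as.integer(plus_age),
    mat_a50 = mat_a50, mat_slope = mat_slope, rho = rho, sigma = sigma,
    a_c = a_c, b_c = b_c, Y5 = Y5, Y95 = Y95, delta = delta
  )
  class(p) <- "species_params"
  validate_species_params(p)
  p
}

#' Validate a species parameter set
#'
#' Checks the admissibility invariants: positive rates, 0.2 < h <= 1,
#' |rho| < 1, sigma > 0, plus-group age >= 2, and L_min < Linf.
#'
#' @param p a `species_params` list.
#' @return `p`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_species_params <- function(p) {
  nsex <- if (p$sex_structured) 2L else 1L
  chk_len <- function(field) {
    if (length(p[[field]]) != nsex)
      stop(sprintf("'%s' must have length %d for %s", field, nsex, p$name))
  }
  for (f in c("M", "k", "Linf", "a_w", "b_w", "mat_a50", "mat_slope"))
    chk_len(f)
  pos <- function(field) {
    if (any(!is.finite(p[[field]])) || any(p[[field]] <= 0))
      stop(sprintf("'%s' must be positive and finite (%s)", field, p$name))
  }
  for (f in c("M", "k", "Linf", "a_w", "b_w", "L_min", "mat_slope", "R0"))
    pos(f)
  if (!(p$h > 0.2 && p$h <= 1))
    stop("steepness 'h' must satisfy 0.2 < h <= 1")
  if (abs(p$rho) >= 1) stop("|rho| must be < 1")
  if (p$sigma <= 0) stop("'sigma' must be > 0")
  if (p$plus_age < 2) stop("'plus_age' must be >= 2")
  if (any(p$L_min >= p$Linf)) stop("'L_min' must be below 'Linf'")
  if (!is.null(p$Y5) && !is.null(p$Y95) && p$Y5 >= p$Y95)
    stop("'Y5' must be below 'Y95'")
  if (!is.null(p$delta) && p$delta < 0) stop("'delta' must be >= 0")
  invisible(p)
}

#' Default uniform bounds for the global sensitivity analysis
#'
#' The GSA perturbs the poorly known predation and recruitment parameters.
#' Bounds are plus/minus 50% of each default value, truncated to admissible
#' ranges; prey specialization gamma, being the scenario axis rather than a
#' single default, spans its admissible range \[0, 0.1\].
#'
#' @return Named list of `c(lo, hi)` bounds for `gamma`, `delta`, `q_scale`,
#'   `sigma`, `rho_L`, `rho_Y`, `Y95`.
#' @export
default_gsa_bounds <- function() {
  list(
    gamma   = c(0, 0.1),
    delta   = c(0.15, 0.45),
    q_scale = c(0.5, 1.5),
    sigma   = c(0.25, 0.75),
    rho_L   = c(0.115, 0.345),
    rho_Y   = c(0.115, 0.345),
    Y95     = c(0.145, 0.435)
  )
}

#' Draw Monte-Carlo parameter sets for the global sensitivity analysis
#'
#' Each draw samples every parameter independently and uniformly within its
#' bounds, giving `n` unique model parameterizations.
#'
#' @param n number of draws (>= 1).
#' @param bounds named list of `c(lo, hi)` numeric bounds; see
#'   [default_gsa_bounds()].
#' @param seed optional integer seed for reproducibility.
#' @return A data.frame with one column per parameter, `n` rows, and a
#'   `draw` index column.
#' @export
#' @examples
#' s <- sample_gsa_parameters(5, seed = 1)
#' range(s$gamma)
sample_gsa_parameters <- function(n, bounds = default_gsa_bounds(),
                                  seed = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  known <- names(default_gsa_bounds())
  if (is.null(names(bounds)) || !all(names(bounds) %in% known))
    stop("unknown parameter name in 'bounds'; expected subset of: ",
         paste(known, collapse = ", "))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop(sprintf("bounds for '%s' must be finite with lo < hi", nm))
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(bounds, function(b) stats::runif(n, b[1], b[2]))
  out <- as.data.frame(draws)
  out$draw <- seq_len(n)
  out
}
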