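#' @useDynLib mckm, .registration = TRUE
#' @importFrom stats nlminb qnorm runif rnorm median coef setNames aggregate sd var
#' @importFrom utils read.csv write.csv modifyList
NULL

#' Canonical order of the 13 kinetic parameters
#'
#' Parameter names in the canonical order used throughout the package:
#' \code{mu_max} (maximum specific growth rate, h^-1), \code{k_d} (death rate
#' constant, h^-1), \code{K_glc} (glucose half-saturation, g/L),
#' \code{Y_X_glc} (biomass yield on glucose, 1e9 cells/g), \code{Y_X_gln},
#' \code{Y_X_glu}, \code{Y_X_amm} (biomass yields on glutamine / glutamate /
#' ammonium, 1e9 cells/mmol), \code{Y_lac_glc} (lactate yield on glucose,
#' g/g), \code{Y_gln_glu} (glutamine yield on glutamate, mol/mol),
#' \code{Y_P_X} (mAb yield on biomass, g/1e9 cells), \code{Y_X_lac} (biomass
#' yield on lactate, 1e9 cells/g), \code{m_glc} (glucose maintenance,
#' g/(1e9 cells)/h), and \code{KD_amm} (ammonium death half-saturation, mM).
#' @export
mckm_parameter_names <- c(
  "mu_max", "k_d", "K_glc", "Y_X_glc", "Y_X_gln", "Y_X_glu", "Y_lac_glc",
  "Y_X_amm", "Y_gln_glu", "Y_P_X", "Y_X_lac", "m_glc", "KD_amm"
)

#' Names of the eight model states
#'
#' Viable cell concentration \code{Xv} (1e9 cells/L), product titre \code{P}
#' (g/L), glucose \code{glc} (g/L), glutamate \code{glu} (mM), glutamine
#' \code{gln} (mM), ammonium \code{amm} (mM), lactate \code{lac} (g/L), and
#' the estimated specific growth rate \code{mu_est} (h^-1), carried as an
#' additional state acting as a mechanistic constraint during regression.
#' @export
mckm_state_names <- c("Xv", "P", "glc", "glu", "gln", "amm", "lac", "mu_est")

# names of the eight yield-type parameters and their (numerator, denominator)
# species for mass-balance initial guesses
.yield_pairs <- list(
  Y_X_glc   = c("Xv",  "glc"),
  Y_X_gln   = c("Xv",  "gln"),
  Y_X_glu   = c("Xv",  "glu"),
  Y_lac_glc = c("lac", "glc"),
  Y_X_amm   = c("Xv",  "amm"),
  Y_gln_glu = c("gln", "glu"),
  Y_X_lac   = c("Xv",  "lac"),
  Y_P_X     = c("P",   "Xv")
)

#' Construct a kinetic parameter vector
#'
#' Builds and validates the named 13-entry parameter vector of the model.
#' All entries must be non-negative; the stoichiometric caps
#' \code{Y_lac_glc <= 2} and \code{Y_gln_glu <= 1} are enforced.
#'
#' @param ... Either a single named numeric vector/list of length 13, or the
#'   13 parameters as named arguments.
#' @return A named numeric vector of class \code{kinetic_parameters}.
#' @export
kinetic_parameters <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args))) {
    x <- unlist(args[[1]])
  } else {
    x <- unlist(args)
  }
  if (is.null(names(x)) && length(x) == 13L) names(x) <- mckm_parameter_names
  missing <- setdiff(mckm_parameter_names, names(x))
  if (length(missing))
    stop("missing kinetic parameters: ", paste(missing, collapse = ", "))
  x <- x[mckm_parameter_names]
  if (anyNA(x) || any(!is.finite(x)))
    stop("kinetic parameters must be finite")
  if (any(x < 0))
    stop("kinetic parameters must be non-negative")
  if (x[["Y_lac_glc"]] > 2)
    stop("Y_lac_glc exceeds its stoichiometric cap of 2 g/g")
  if (x[["Y_gln_glu"]] > 1)
    stop("Y_gln_glu exceeds its stoichiometric cap of 1 mol/mol")
  structure(x, class = "kinetic_parameters")
}

#' Default regression bounds and initial guesses
#'
#' The shipped lower bounds, upper bounds, and default initial guesses for
#' the 13 kinetic parameters. \code{mu_max} and \code{K_glc} carry fallback
#' initial guesses (the geometric midpoints of their ranges) because their
#' working initial guesses are computed per run by the Monod pre-regression
#' (\code{\link{preregress_monod}}); the yield entries may likewise be
#' overridden per run by \code{\link{estimate_yield_ig_bounds}}.
#'
#' @param lb,ub,ig Optional named numeric vectors overriding individual
#'   entries of the defaults.
#' @return A list of class \code{parameter_bounds} with named 13-vectors
#'   \code{lb}, \code{ub}, \code{ig}.
#' @export
parameter_bounds <- function(lb = NULL, ub = NULL, ig = NULL) {
  d_lb <- c(mu_max = 0.01, k_d = 1e-4, K_glc = 0.1, Y_X_glc = 0.1,
            Y_X_gln = 0.1, Y_X_glu = 0.001, Y_lac_glc = 0.1, Y_X_amm = 0.1,
            Y_gln_glu = 0.001, Y_P_X = 1e-4, Y_X_lac = 0.01, m_glc = 0,
            KD_amm = 0)
  d_ub <- c(mu_max = 0.1, k_d = 0.1, K_glc = 10, Y_X_glc = 10,
            Y_X_gln = 10, Y_X_glu = 20, Y_lac_glc = 2, Y_X_amm = 20,
            Y_gln_glu = 1, Y_P_X = 1, Y_X_lac = 5, m_glc = 1,
            KD_amm = 100)
  d_ig <- c(mu_max = sqrt(0.01 * 0.1), k_d = 0.016, K_glc = 1,
            Y_X_glc = 1, Y_X_gln = 0.974, Y_X_glu = 1, Y_lac_glc = 0.615,
            Y_X_amm = 0.67, Y_gln_glu = 0.7, Y_P_X = 0.2, Y_X_lac = 2.7,
            m_glc = 0.006192, KD_amm = 5)
  ov <- function(d, x) { if (!is.null(x)) d[names(x)] <- x; d }
  out <- list(lb = ov(d_lb, lb), ub = ov(d_ub, ub), ig = ov(d_ig, ig))
  if (any(out$lb > out$ig) || any(out$ig > out$ub))
    stop("parameter bounds must satisfy lb <= ig <= ub elementwise")
  structure(out, class = "parameter_bounds")
}

#' Model constants
#'
#' Fixed quantities of a simulated culture that are not regressed:
#' the lactate-switch glucose threshold \code{alpha_glc} (g/L, the glucose
#' concentration below which lactate consumption is activated), the feed
#' concentrations \code{glc_F_in} (g/L) and \code{glu_F_in} (mM), and the
#' initial working volume \code{V0} (L). The shipped defaults are synthetic
#' stand-ins sized for a 15 mL minibioreactor with concentrated feeds; the
#' threshold default of 0.5 g/L is a plausible depletion-scale value and
#' should be overridden when a data-derived value is available.
#'
#' @param alpha_glc Lactate-switch glucose threshold, g/L.
#' @param glc_F_in Glucose concentration of the bolus feed, g/L.
#' @param glu_F_in Glutamate concentration of the bolus feed, mM.
#' @param V0 Initial working volume, L.
#' @return A list of class \code{model_constants}.
#' @export
model_constants <- function(alpha_glc = 0.5, glc_F_in = 100, glu_F_in = 50,
                            V0 = 0.015) {
  if (!is.numeric(alpha_glc) || alpha_glc <= 0) stop("alpha_glc must be > 0")
  if (!is.numeric(V0) || V0 <= 0) stop("V0 must be > 0")
  structure(list(alpha_glc = alpha_glc, glc_F_in = glc_F_in,
                 glu_F_in = glu_F_in, V0 = V0),
            class = "model_constants")
}

#' Construct a culture state
#'
#' @param Xv,P,glc,glu,gln,amm,lac Concentrations (units as in
#'   \code{\link{mckm_state_names}}); all must be non-negative.
#' @param mu_est Estimated growth rate, h^-1. If \code{NULL}, it is
#'   initialized consistently as the Monod growth rate at the given glucose
#'   concentration once a parameter vector is known (see
#'   \code{\link{simulate_fedbatch}}).
#' @return Named numeric vector of class \code{culture_state}.
#' @export
culture_state <- function(Xv, P = 0, glc, glu, gln, amm, lac,
                          mu_est = NA_real_) {
  x <- c(Xv = Xv, P = P, glc = glc, glu = glu, gln = gln, amm = amm,
         lac = lac, mu_est = mu_est)
  conc <- x[setdiff(mckm_state_names, "mu_est")]
  if (anyNA(conc) || any(conc < 0))
    stop("all concentrations must be present and non-negative")
  structure(x, class = "culture_state")
}

#' Molecular weights for unit conversion
#'
#' Helpers for users whose glucose or lactate assays report molar units.
#' The package works in gram units for glucose, lactate, and product
#' (g/L) and in mM for glutamine, glutamate, and ammonium.
#'
#' @param mM Concentration in mmol/L.
#' @return Concentration in g/L.
#' @export
glc_mM_to_gL <- function(mM) mM * 180.16 / 1000

#' @rdname glc_mM_to_gL
#' @export
lac_mM_to_gL <- function(mM) mM * 90.08 / 1000

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (13):\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

# clip a named vector into [lb, ub]
.clip_bounds <- function(x, bounds) {
  pmin(pmax(x, bounds$lb[names(x)]), bounds$ub[names(x)])
}
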