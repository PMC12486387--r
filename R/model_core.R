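#' Monod growth rate on glucose
#'
#' mu = mu_max * glc / (K_glc + glc). Glucose is the only growth-limiting
#' substrate of the model; the returned rate is bounded in [0, mu_max].
#'
#' @param theta Kinetic parameter vector (see \code{\link{kinetic_parameters}}).
#' @param glc Glucose concentration, g/L (non-negative).
#' @return Specific growth rate, h^-1.
#' @export
growth_rate <- function(theta, glc) {
  if (any(glc < 0)) stop("glucose concentration must be non-negative")
  theta[["mu_max"]] * glc / (theta[["K_glc"]] + glc)
}

#' Ammonium-driven death rate
#'
#' mu_d = k_d * amm / (KD_amm + amm), a Monod-type function of ammonium
#' alone; bounded in [0, k_d].
#'
#' @param theta Kinetic parameter vector.
#' @param amm Ammonium concentration, mM (non-negative).
#' @return Specific death rate, h^-1.
#' @export
death_rate <- function(theta, amm) {
  if (any(amm < 0)) stop("ammonium concentration must be non-negative")
  ifelse(amm > 0, theta[["k_d"]] * amm / (theta[["KD_amm"]] + amm), 0)
}

#' Specific (per-cell) metabolic rates
#'
#' Evaluates all specific rates of the model at one state: growth-associated
#' production of product and ammonium, Luedeking-Piret glucose consumption
#' with maintenance, glutamate/glutamine consumption, and the glucose-gated
#' lactate switch. All q's are per-cell rates; the ODEs multiply by Xv once.
#'
#' The lactate branch: production q_lac = +Y_lac_glc * q_glc while glucose is
#' at or above the threshold \code{alpha_glc}, consumption
#' q_lac = -mu / Y_X_lac once glucose falls below it. Setting
#' \code{lactate_switch_as_printed = TRUE} flips the inequality (production
#' below the threshold), for strict comparison against the alternative
#' reading of the switch.
#'
#' @param theta Kinetic parameter vector.
#' @param state Named state vector (see \code{\link{culture_state}}).
#' @param constants \code{\link{model_constants}}.
#' @param lactate_switch_as_printed Logical; flip the switch inequality.
#' @return Named list with \code{q_P}, \code{q_glc}, \code{q_glu},
#'   \code{q_gln}, \code{q_amm}, \code{q_lac}, \code{mu}, \code{mu_d}.
#' @export
specific_rates <- function(theta, state, constants,
                           lactate_switch_as_printed = FALSE) {
  yields <- c("Y_X_glc", "Y_X_gln", "Y_X_glu", "Y_X_amm", "Y_X_lac", "Y_P_X")
  if (any(theta[yields] == 0))
    stop("invalid parameters: zero yield would divide by zero")
  glc <- max(state[["glc"]], 0)
  mu <- growth_rate(theta, glc)
  mu_d <- death_rate(theta, max(state[["amm"]], 0))
  q_glc <- mu / theta[["Y_X_glc"]] + theta[["m_glc"]]
  consume <- if (lactate_switch_as_printed) glc >= constants$alpha_glc
             else glc < constants$alpha_glc
  q_lac <- if (consume) -mu / theta[["Y_X_lac"]] else theta[["Y_lac_glc"]] * q_glc
  list(q_P = mu * theta[["Y_P_X"]],
       q_glc = q_glc,
       q_glu = mu / theta[["Y_X_glu"]],
       q_gln = mu / theta[["Y_X_gln"]],
       q_amm = mu / theta[["Y_X_amm"]],
       q_lac = q_lac,
       mu = mu, mu_d = mu_d)
}

#' Right-hand side of the batch kinetic model
#'
#' The eight coupled ODEs of the batch (between-feeds) model: biomass growth
#' and death, growth-associated product formation, substrate consumption,
#' by-product formation, the lactate switch, and the auxiliary growth-rate
#' state d(mu_est)/dt = mu_max * (dglc/dt) * K_glc / (K_glc + glc)^2, the
#' exact time derivative of the Monod rate, which constrains the regression
#' toward realistic growth dynamics.
#'
#' Depleted states cannot go negative: each concentration's outgoing flux
#' ramps linearly to zero over its last 1e-6 units (far below assay
#' resolution), which keeps the right-hand side continuous so adaptive
#' step-size control remains valid through depletion events.
#'
#' This is the reference R implementation; the integrators use an identical
#' compiled version for speed (their agreement is tested).
#'
#' @inheritParams specific_rates
#' @param t Time, h (unused; the system is autonomous).
#' @return Named vector of time derivatives of the eight states.
#' @export
batch_rhs <- function(t, state, theta, constants,
                      lactate_switch_as_printed = FALSE) {
  if (any(!is.finite(state))) stop("non-finite state in batch_rhs")
  q <- specific_rates(theta, state, constants, lactate_switch_as_printed)
  Xv <- max(state[["Xv"]], 0)
  d <- c(Xv  = (q$mu - q$mu_d) * Xv,
         P   = q$q_P * Xv,
         glc = -q$q_glc * Xv,
         glu = -q$q_glu * Xv,
         gln = -q$q_gln * Xv + theta[["Y_gln_glu"]] * q$q_glu * Xv,
         amm = q$q_amm * Xv,
         lac = q$q_lac * Xv,
         mu_est = 0)
  conc <- mckm_state_names[1:7]
  out <- d[conc] < 0
  w <- pmin(pmax(state[conc][out] / 1e-6, 0), 1)
  d[conc][out] <- d[conc][out] * w
  glc <- max(state[["glc"]], 0)
  d[["mu_est"]] <- theta[["mu_max"]] * d[["glc"]] * theta[["K_glc"]] /
    (theta[["K_glc"]] + glc)^2
  d
}

# parameter vector handed to the compiled RHS; accepts a named vector or an
# unnamed one already in canonical order
.batch_parms <- function(theta, constants, lactate_switch_as_printed = FALSE) {
  if (!is.null(names(theta))) theta <- theta[mckm_parameter_names]
  stopifnot(length(theta) == 13L)
  c(unname(theta), constants$alpha_glc,
    as.numeric(lactate_switch_as_printed))
}
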