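#' Default clone-population parameter means and spreads
#'
#' Population means and between-clone standard deviations used by the
#' synthetic campaign generator. The values describe a realistic GS-CHO
#' screening population: maximum growth rate near 0.026 h^-1, biomass yield
#' on glucose near 2e9 cells/g, modest lactate yield, and an ammonium death
#' half-saturation near 6.5 mM, with generous clone-to-clone spread. The
#' glutamine yield Y_X_gln is kept at 8 +/- 4 (1e9 cells/mmol) so the whole
#' population lies inside the shipped regression bounds box.
#'
#' @return List with named 13-vectors \code{mean} and \code{sd}.
#' @export
mckm_population_defaults <- function() {
  list(
    mean = c(mu_max = 0.0258, k_d = 0.0180, K_glc = 1.05, Y_X_glc = 2.03,
             Y_X_gln = 8.0, Y_X_glu = 8.94, Y_lac_glc = 0.286,
             Y_X_amm = 11.0, Y_gln_glu = 0.387, Y_P_X = 0.0481,
             Y_X_lac = 3.16, m_glc = 1.51e-6, KD_amm = 6.47),
    sd = c(mu_max = 0.00831, k_d = 0.0194, K_glc = 2.60, Y_X_glc = 1.29,
           Y_X_gln = 4.0, Y_X_glu = 4.19, Y_lac_glc = 0.158,
           Y_X_amm = 4.71, Y_gln_glu = 0.165, Y_P_X = 0.0258,
           Y_X_lac = 5.37, m_glc = 2.07e-3, KD_amm = 3.14)
  )
}

#' Default seed-train initial state of a synthetic run
#'
#' Plausible inoculation values for a 15 mL screening culture: 0.3e9
#' viable cells/L, 6 g/L glucose, 4 mM glutamate, 0.5 mM glutamine, 1 mM
#' ammonium, 0.2 g/L lactate, and no product. Synthetic stand-ins; override
#' per campaign when better values are known.
#'
#' @return A \code{\link{culture_state}}.
#' @export
default_initial_state <- function() {
  culture_state(Xv = 0.3, P = 0, glc = 6, glu = 4, gln = 0.5, amm = 1,
                lac = 0.2)
}

#' Specify a synthetic screening campaign
#'
#' Describes an Ambr15-style cell line development campaign for the
#' synthetic generator: how many clones, how many sequential passages
#' (Ambr runs) and replicates, the clone-population parameter distribution,
#' the stability model (a per-passage multiplicative drift factor on the
#' specific productivity Y_P_X: unstable clones decline, stable clones
#' hold), the multiplicative measurement noise per variable, and the
#' missing-entry rate.
#'
#' @param n_clones Number of unique clones.
#' @param passages Number of sequential passages ("Ambr-1".."Ambr-k").
#' @param replicates Replicate runs per clone and passage.
#' @param means,sds Named 13-vectors of the clone-population parameter
#'   means and standard deviations (defaults:
#'   \code{\link{mckm_population_defaults}}).
#' @param unstable_fraction Fraction of clones labelled unstable.
#' @param drift_unstable,drift_stable Ranges of the per-passage
#'   multiplicative drift factor on Y_P_X for unstable and stable clones.
#' @param noise_cv Multiplicative lognormal measurement noise, as a scalar
#'   coefficient of variation or a named per-variable vector (the 7
#'   measured quantities; mu_est is derived, never noised directly).
#' @param missing_rate Probability that a measured entry is missing (the
#'   first viable-cell value is never removed).
#' @param initial_state Inoculation \code{\link{culture_state}}.
#' @param sample_times Sampling grid, h.
#' @param constants \code{\link{model_constants}}.
#' @param schedule \code{\link{feed_schedule}} applied to every run.
#' @param bounds \code{\link{parameter_bounds}}; sampled parameters are
#'   truncated to this box, and every population mean must lie inside it.
#' @return List of class \code{campaign_spec}.
#' @export
campaign_spec <- function(n_clones = 24, passages = 4, replicates = 1,
                          means = mckm_population_defaults()$mean,
                          sds = mckm_population_defaults()$sd,
                          unstable_fraction = 0.3,
                          drift_unstable = c(0.6, 0.9),
                          drift_stable = c(0.97, 1.03),
                          noise_cv = 0.03, missing_rate = 0.02,
                          initial_state = default_initial_state(),
                          sample_times = default_sample_times(),
                          constants = model_constants(),
                          schedule = default_feed_schedule(
                            sample_times, constants),
                          bounds = parameter_bounds()) {
  means <- means[mckm_parameter_names]
  sds <- sds[mckm_parameter_names]
  if (anyNA(means) || anyNA(sds))
    stop("means and sds must cover all 13 parameters")
  if (any(sds < 0)) stop("parameter standard deviations must be >= 0")
  if (any(means < bounds$lb | means > bounds$ub))
    stop("population means must lie within the parameter bounds")
  measured <- setdiff(mckm_state_names, "mu_est")
  if (is.null(names(noise_cv)))
    noise_cv <- setNames(rep_len(noise_cv, length(measured)), measured)
  if (any(noise_cv < 0)) stop("noise CVs must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(n_clones = n_clones, passages = passages,
                 replicates = replicates, means = means, sds = sds,
                 unstable_fraction = unstable_fraction,
                 drift_unstable = drift_unstable,
                 drift_stable = drift_stable, noise_cv = noise_cv,
                 missing_rate = missing_rate,
                 initial_state = initial_state,
                 sample_times = sample_times, constants = constants,
                 schedule = schedule, bounds = bounds),
            class = "campaign_spec")
}

# one truncated-normal draw per parameter via inverse-CDF sampling
.rtruncnorm <- function(n, mean, sd, lb, ub) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lb, mean, sd)
  phi <- stats::pnorm(ub, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Sample clone parameter vectors from the population
#'
#' Draws each of the 13 parameters independently from a normal distribution
#' with the campaign's mean and standard deviation, truncated to the bounds
#' box (no parameter covariance is modelled). Deterministic under a fixed
#' RNG seed.
#'
#' @param spec A \code{\link{campaign_spec}}.
#' @param n Number of clones to draw (default: \code{spec$n_clones}).
#' @return n x 13 matrix; each row is a valid parameter vector.
#' @export
sample_parameters <- function(spec, n = spec$n_clones) {
  th <- matrix(NA_real_, n, 13,
               dimnames = list(NULL, mckm_parameter_names))
  for (p in mckm_parameter_names)
    th[, p] <- .rtruncnorm(n, spec$means[[p]], spec$sds[[p]],
                           spec$bounds$lb[[p]], spec$bounds$ub[[p]])
  th
}

#' Generate one synthetic culture run
#'
#' Simulates the fed-batch model for one parameter vector, samples the
#' trajectory at the campaign's sampling times, applies multiplicative
#' lognormal measurement noise per variable (unit mean), masks entries at
#' the missingness rate (never the first viable-cell value), and attaches
#' the growth-rate estimate computed from the noisy viable-cell series —
#' exactly as it would be derived from real at-line data.
#'
#' @param theta Kinetic parameter vector of the clone.
#' @param spec A \code{\link{campaign_spec}}.
#' @param metadata Named list stored on the run.
#' @return A \code{\link{culture_run}} whose true parameters are attached
#'   as attribute \code{"theta_true"}.
#' @export
generate_run <- function(theta, spec, metadata = list()) {
  sim <- simulate_fedbatch(theta, spec$initial_state, spec$constants,
                           spec$schedule, spec$sample_times, dense_n = 2)
  obs <- sim$states
  measured <- setdiff(mckm_state_names, "mu_est")
  Tn <- length(spec$sample_times)
  for (v in measured) {
    cv <- spec$noise_cv[[v]]
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      obs[, v] <- obs[, v] * stats::rlnorm(Tn, -sdlog^2 / 2, sdlog)
    }
  }
  if (spec$missing_rate > 0) {
    mask <- matrix(runif(Tn * length(measured)) < spec$missing_rate,
                   Tn, length(measured))
    mask[1, match("Xv", measured)] <- FALSE
    obs[, measured][mask] <- NA_real_
  }
  obs[, "mu_est"] <- estimate_mu_from_vcc(spec$sample_times, obs[, "Xv"])
  run <- culture_run(spec$sample_times, obs, spec$schedule, metadata)
  attr(run, "theta_true") <- kinetic_parameters(theta)
  run
}

#' Generate a full synthetic screening campaign
#'
#' Draws clone-level parameter vectors, applies the per-passage stability
#' drift to the specific productivity Y_P_X (cumulative across passages,
#' truncated to bounds), and simulates every clone x passage x replicate
#' run. Returns the runs together with a ground-truth table for recovery
#' and classification experiments.
#'
#' @param spec A \code{\link{campaign_spec}}.
#' @param campaign Campaign identifier stored in metadata.
#' @param seed Optional integer seed for full reproducibility.
#' @return List of class \code{mckm_campaign} with \code{runs} (list of
#'   \code{\link{culture_run}}) and \code{ground_truth} (data.frame: clone,
#'   passage, replicate, stable flag, and the 13 true parameters per run).
#' @export
generate_campaign <- function(spec, campaign = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_theta <- sample_parameters(spec)
  n_unstable <- round(spec$unstable_fraction * spec$n_clones)
  stable <- rep(TRUE, spec$n_clones)
  if (n_unstable > 0)
    stable[sample.int(spec$n_clones, n_unstable)] <- FALSE
  runs <- list()
  gt <- list()
  k <- 0L
  for (cl in seq_len(spec$n_clones)) {
    th <- base_theta[cl, ]
    for (pa in seq_len(spec$passages)) {
      if (pa > 1) {
        rng <- if (stable[cl]) spec$drift_stable else spec$drift_unstable
        th[["Y_P_X"]] <- th[["Y_P_X"]] * runif(1, rng[1], rng[2])
      }
      th <- .clip_bounds(th, spec$bounds)
      for (re in seq_len(spec$replicates)) {
        k <- k + 1L
        md <- list(campaign = campaign, clone = sprintf("clone%03d", cl),
                   passage = paste0("Ambr-", pa), replicate = re,
                   stable = stable[cl])
        runs[[k]] <- generate_run(th, spec, md)
        gt[[k]] <- data.frame(campaign = campaign,
                              clone = md$clone, passage = md$passage,
                              replicate = re, stable = stable[cl],
                              t(th))
      }
    }
  }
  structure(list(runs = runs, ground_truth = do.call(rbind, gt),
                 spec = spec),
            class = "mckm_campaign")
}

#' @export
print.mckm_campaign <- function(x, ...) {
  cat(sprintf("Synthetic campaign: %d runs (%d clones x %d passages x %d replicates)\n",
              length(x$runs), x$spec$n_clones, x$spec$passages,
              x$spec$replicates))
  invisible(x)
}
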