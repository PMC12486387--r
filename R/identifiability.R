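#' Local sensitivity matrix of the fed-batch model
#'
#' Time-averaged relative sensitivities of the eight model variables to the
#' 13 kinetic parameters: each parameter is perturbed by a central finite
#' difference (relative step, default 1e-3), the fed-batch model is
#' re-simulated, and the state derivatives are averaged over the sampling
#' times. Entries are made comparable across units by scaling with the
#' parameter value and with the variable's range over the nominal
#' trajectory (a variable with no range is scaled by its magnitude).
#'
#' @param theta Kinetic parameter vector (nominal point).
#' @param initial Initial \code{\link{culture_state}}.
#' @param constants \code{\link{model_constants}}.
#' @param schedule \code{\link{feed_schedule}}.
#' @param sample_times Sampling times, h.
#' @param rel_step Relative finite-difference step.
#' @param rtol,atol Solver tolerances.
#' @param use_compiled Use the compiled derivative.
#' @return 8 x 13 matrix (variables x parameters) of time-averaged relative
#'   sensitivities.
#' @export
sensitivity_matrix <- function(theta, initial, constants,
                               schedule = default_feed_schedule(),
                               sample_times = default_sample_times(),
                               rel_step = 1e-3, rtol = 1e-8, atol = 1e-10,
                               use_compiled = TRUE) {
  theta <- kinetic_parameters(theta)
  y0 <- unclass(initial)[mckm_state_names]
  if (is.na(y0[["mu_est"]]))
    y0[["mu_est"]] <- growth_rate(theta, y0[["glc"]])
  sim <- function(th) .simulate_states(unname(th[mckm_parameter_names]), y0,
                                       constants, schedule, sample_times,
                                       rtol, atol, use_compiled)
  nominal <- sim(theta)
  rng <- apply(nominal, 2, function(x) diff(range(x)))
  scale_i <- ifelse(rng > 0, rng, pmax(apply(abs(nominal), 2, max), 1))
  S <- matrix(0, 8, 13, dimnames = list(mckm_state_names,
                                        mckm_parameter_names))
  for (j in mckm_parameter_names) {
    h <- rel_step * max(abs(theta[[j]]), 1e-4)
    up <- theta; up[j] <- theta[[j]] + h
    dn <- theta; dn[j] <- theta[[j]] - h
    pred_up <- tryCatch(sim(up), error = function(e) NULL)
    pred_dn <- tryCatch(sim(dn), error = function(e) NULL)
    if (is.null(pred_up) && is.null(pred_dn))
      stop("sensitivity simulation failed for parameter ", j)
    deriv <- if (is.null(pred_up)) {
      warning("one-sided difference used for ", j)
      (nominal - pred_dn) / h
    } else if (is.null(pred_dn)) {
      warning("one-sided difference used for ", j)
      (pred_up - nominal) / h
    } else {
      (pred_up - pred_dn) / (2 * h)
    }
    S[, j] <- theta[[j]] * colMeans(deriv) / scale_i
  }
  S
}

#' Per-parameter mean-squared sensitivity
#'
#' Root-mean-square of each parameter's sensitivity column over the model
#' variables: delta_j = sqrt(mean_i s_ij^2). A parameter whose column is
#' zero (it never enters an active branch) scores 0.
#'
#' @param S Sensitivity matrix (variables x parameters).
#' @return Named vector of per-parameter scores.
#' @export
mean_squared_sensitivity <- function(S) {
  sqrt(colMeans(S^2))
}

#' Collinearity index of a parameter subset
#'
#' Columns of the sensitivity matrix are normalized to unit length; for the
#' chosen subset K the index is CI_K = 1 / sqrt(lambda_min), with
#' lambda_min the smallest eigenvalue of the subset's Gram matrix. CI = 1
#' for orthogonal columns and grows without bound as columns become
#' linearly dependent; exactly proportional columns give +Inf. For two
#' columns at angle phi the closed form is CI = 1/sqrt(1 - |cos phi|).
#'
#' @param S Sensitivity matrix.
#' @param subset Parameter names or indices (any size >= 2).
#' @return Scalar collinearity index (\code{NA} if a column has zero norm).
#' @export
collinearity_index <- function(S, subset) {
  Sk <- S[, subset, drop = FALSE]
  norms <- sqrt(colSums(Sk^2))
  if (any(norms == 0)) return(NA_real_)
  Sn <- sweep(Sk, 2, norms, "/")
  lam <- min(eigen(crossprod(Sn), symmetric = TRUE,
                   only.values = TRUE)$values)
  if (lam <= .Machine$double.eps) return(Inf)
  1 / sqrt(lam)
}

#' Pairwise collinearity indices
#'
#' Collinearity index for each of the 78 parameter pairs. Pairs with
#' CI > 20 are flagged as practically non-identifiable: roughly 95 percent
#' of the output change from one parameter can be compensated by the other.
#'
#' @param S Sensitivity matrix.
#' @param flag_threshold Threshold above which a pair is flagged.
#' @return List with \code{CI} (13 x 13 symmetric matrix, diagonal
#'   \code{NA}) and \code{flagged} (data.frame of pairs with CI above the
#'   threshold, including infinite CI).
#' @export
collinearity_pairs <- function(S, flag_threshold = 20) {
  pn <- colnames(S)
  k <- length(pn)
  CI <- matrix(NA_real_, k, k, dimnames = list(pn, pn))
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      ci <- collinearity_index(S, c(a, b))
      CI[a, b] <- CI[b, a] <- ci
    }
  }
  idx <- which(upper.tri(CI) & (CI > flag_threshold), arr.ind = TRUE)
  flagged <- data.frame(param1 = pn[idx[, 1]], param2 = pn[idx[, 2]],
                        CI = CI[idx])
  flagged <- flagged[order(-flagged$CI), ]
  rownames(flagged) <- NULL
  list(CI = CI, flagged = flagged)
}

#' Full identifiability report
#'
#' Convenience wrapper running \code{\link{sensitivity_matrix}},
#' \code{\link{mean_squared_sensitivity}} and
#' \code{\link{collinearity_pairs}} at one parameter point.
#'
#' @inheritParams sensitivity_matrix
#' @param flag_threshold CI flagging threshold.
#' @return List of class \code{sensitivity_report} with \code{S},
#'   \code{S_norm} (unit-normalized columns), \code{delta_msqr}, \code{CI}
#'   and \code{flagged}.
#' @export
identifiability_report <- function(theta, initial, constants,
                                   schedule = default_feed_schedule(),
                                   sample_times = default_sample_times(),
                                   rel_step = 1e-3, flag_threshold = 20,
                                   rtol = 1e-8, atol = 1e-10,
                                   use_compiled = TRUE) {
  S <- sensitivity_matrix(theta, initial, constants, schedule, sample_times,
                          rel_step, rtol, atol, use_compiled)
  norms <- sqrt(colSums(S^2))
  S_norm <- sweep(S, 2, ifelse(norms > 0, norms, 1), "/")
  cp <- collinearity_pairs(S, flag_threshold)
  structure(list(S = S, S_norm = S_norm,
                 delta_msqr = mean_squared_sensitivity(S),
                 CI = cp$CI, flagged = cp$flagged),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report\n  delta_msqr:\n")
  print(round(x$delta_msqr, 4))
  cat(sprintf("  %d parameter pairs flagged collinear (CI > 20)\n",
              nrow(x$flagged)))
  if (nrow(x$flagged)) print(x$flagged)
  invisible(x)
}
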