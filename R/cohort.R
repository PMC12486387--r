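#' Assemble a cohort table from per-run fits
#'
#' One row per fitted culture run: metadata, balancing mode, the 13 fitted
#' parameters, and the per-variable goodness-of-fit metrics, ready for
#' campaign-level summaries and discriminant analysis.
#'
#' @param fits List of \code{\link{fit_run}} results.
#' @return data.frame of class \code{cohort_table}.
#' @export
cohort_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    md <- f$run$metadata
    data.frame(campaign = md$campaign %||% NA_character_,
               clone = md$clone %||% NA_character_,
               passage = md$passage %||% NA_character_,
               replicate = md$replicate %||% NA_integer_,
               mode = f$mode, objective = f$objective,
               t(unclass(f$theta_hat)),
               setNames(as.list(f$r2), paste0("r2_", names(f$r2))),
               setNames(as.list(f$nrmse), paste0("nrmse_", names(f$nrmse))),
               final_titre = f$run$observations[
                 nrow(f$run$observations), "P"])
  })
  structure(do.call(rbind, rows), class = c("cohort_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Campaign-level parameter summaries
#'
#' Mean and sample standard deviation of each of the 13 fitted parameters
#' per group (by default per campaign), the standard cohort summary layout.
#' Groups with a single row report \code{NA} spread; empty groups are
#' dropped with a warning.
#'
#' @param cohort A \code{\link{cohort_table}} (or compatible data.frame
#'   with the 13 parameter columns).
#' @param by Grouping column name(s), e.g. \code{"campaign"} or
#'   \code{c("campaign", "passage")}.
#' @return data.frame with one row per group x parameter: group labels,
#'   \code{parameter}, \code{mean}, \code{sd}, \code{n}.
#' @export
summarize_parameters <- function(cohort, by = "campaign") {
  if (!all(by %in% names(cohort)))
    stop("grouping columns not found: ",
         paste(setdiff(by, names(cohort)), collapse = ", "))
  groups <- interaction(cohort[by], drop = TRUE, sep = "/")
  if (any(table(groups) < 2))
    warning("groups with fewer than 2 runs report NA spread")
  out <- list()
  for (g in levels(groups)) {
    sub <- cohort[groups == g, mckm_parameter_names, drop = FALSE]
    out[[g]] <- data.frame(group = g,
                           parameter = mckm_parameter_names,
                           mean = colMeans(sub),
                           sd = apply(sub, 2, sd),
                           n = nrow(sub))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label well-performing runs by median titre split
#'
#' A run is labelled top-performing when its final product titre is at or
#' above the within-campaign median ("top 50 percent titre"; ties at the
#' median fall in the top class). Rank-based, hence invariant to monotone
#' rescaling of titre.
#'
#' @param cohort A \code{\link{cohort_table}}.
#' @param titre_col Column holding the run-level titre (default
#'   \code{"final_titre"}).
#' @param by Column defining the campaigns within which the split is made.
#' @return Logical vector, \code{TRUE} for the top class.
#' @export
label_performance <- function(cohort, titre_col = "final_titre",
                              by = "campaign") {
  titre <- cohort[[titre_col]]
  if (is.null(titre)) stop("titre column not found: ", titre_col)
  groups <- if (by %in% names(cohort)) cohort[[by]] else rep(1, nrow(cohort))
  top <- logical(nrow(cohort))
  for (g in unique(groups)) {
    i <- which(groups == g)
    top[i] <- titre[i] >= median(titre[i], na.rm = TRUE)
  }
  top
}

#' Fisher linear discriminant analysis of kinetic parameters
#'
#' Two-class Fisher LDA on the (standardized) parameter matrix: the
#' discriminant direction is w proportional to S_pooled^-1 (m1 - m0), and
#' classification uses the induced linear score with the midpoint
#' threshold. Accuracy is estimated by leave-one-out cross-validation
#' (each held-out run classified by a discriminant refit on the rest).
#' Because the 13 parameters span several orders of magnitude, columns are
#' standardized to zero mean and unit variance by default; a ridge term
#' (epsilon x trace/p on the pooled covariance diagonal) is available for
#' small cohorts.
#'
#' @param X n x p numeric matrix of kinetic parameters (p = 13 typically).
#' @param y Binary labels (logical or two-level factor/vector).
#' @param standardize Standardize columns first (default \code{TRUE}).
#' @param ridge Ridge fraction epsilon (0 disables; use e.g. 1e-6 when the
#'   pooled covariance is singular).
#' @return List of class \code{lda_result}: \code{coefficients} (named,
#'   unit-norm, on the standardized scale), \code{class_means},
#'   \code{accuracy_loo}, \code{n}, \code{standardize}, \code{ridge}.
#' @export
fisher_lda <- function(X, y, standardize = TRUE, ridge = 0) {
  X <- as.matrix(X)
  y <- as.logical(factor(y, levels = sort(unique(y))) ==
                    levels(factor(y, levels = sort(unique(y))))[2])
  if (length(unique(y)) < 2) stop("both classes must be non-empty")
  n <- nrow(X); p <- ncol(X)
  if (standardize) {
    mu <- colMeans(X); sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  }
  direction <- function(X, y) {
    m0 <- colMeans(X[!y, , drop = FALSE])
    m1 <- colMeans(X[y, , drop = FALSE])
    S0 <- stats::cov(X[!y, , drop = FALSE]) * (sum(!y) - 1)
    S1 <- stats::cov(X[y, , drop = FALSE]) * (sum(y) - 1)
    Sp <- (S0 + S1) / (length(y) - 2)
    if (ridge > 0) Sp <- Sp + diag(ridge * sum(diag(Sp)) / ncol(X), ncol(X))
    w <- tryCatch(solve(Sp, m1 - m0), error = function(e)
      stop("pooled covariance is singular; refit with a positive ridge",
           call. = FALSE))
    list(w = w, m0 = m0, m1 = m1)
  }
  d <- direction(X, y)
  w <- d$w / sqrt(sum(d$w^2))
  # leave-one-out with the midpoint threshold
  hits <- logical(n)
  for (i in seq_len(n)) {
    di <- direction(X[-i, , drop = FALSE], y[-i])
    thr <- sum(di$w * (di$m0 + di$m1)) / 2
    hits[i] <- (sum(di$w * X[i, ]) > thr) == y[i]
  }
  structure(list(coefficients = setNames(w, colnames(X)),
                 class_means = rbind(class0 = d$m0, class1 = d$m1),
                 accuracy_loo = mean(hits), n = n,
                 standardize = standardize, ridge = ridge),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf("Fisher LDA (n=%d): leave-one-out accuracy %.1f%%\n",
              x$n, 100 * x$accuracy_loo))
  ord <- order(-abs(x$coefficients))
  cat("coefficients (|largest| first):\n")
  print(round(x$coefficients[ord], 3))
  invisible(x)
}
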