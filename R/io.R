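# Run CSVs use unit-bearing headers so the mM / g-L ambiguity of kinetic
# datasets cannot leak into files silently.
.run_cols <- c(Xv = "Xv", P = "P_gL", glc = "glc_gL", glu = "glu_mM",
               gln = "gln_mM", amm = "amm_mM", lac = "lac_gL",
               mu_est = "mu_est_h")

#' Read a culture run from CSV
#'
#' Expected columns: \code{time_h}, \code{Xv}, \code{P_gL}, \code{glc_gL},
#' \code{glu_mM}, \code{gln_mM}, \code{amm_mM}, \code{lac_gL}, optionally
#' \code{mu_est_h} (recomputed from the viable-cell column when absent).
#' Blank cells are missing values. Unknown columns, duplicate or
#' non-increasing times are schema errors.
#'
#' @param path Run CSV path.
#' @param schedule Optional \code{\link{feed_schedule}} or path to a feed
#'   CSV to attach.
#' @param metadata Named list stored on the run.
#' @return A \code{\link{culture_run}}.
#' @export
read_run <- function(path, schedule = NULL, metadata = list()) {
  d <- read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(d)) stop("run file lacks a time_h column: ", path)
  unknown <- setdiff(names(d), c("time_h", unname(.run_cols)))
  if (length(unknown))
    stop("unknown run columns in ", path, ": ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(d$time_h) || any(diff(d$time_h) <= 0))
    stop("times must be strictly increasing in ", path)
  obs <- matrix(NA_real_, nrow(d), 0)
  for (v in names(.run_cols)) {
    col <- .run_cols[[v]]
    if (col %in% names(d))
      obs <- cbind(obs, setNames(d[col], v))
  }
  if (is.null(schedule))
    schedule <- feed_schedule(numeric(0), numeric(0), numeric(0),
                              numeric(0))
  else if (is.character(schedule))
    schedule <- read_feed_schedule(schedule)
  culture_run(d$time_h, obs, schedule, metadata)
}

#' Write a culture run to CSV
#' @param run A \code{\link{culture_run}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run <- function(run, path) {
  d <- data.frame(time_h = run$sample_times)
  for (v in names(.run_cols)) d[[.run_cols[[v]]]] <- run$observations[, v]
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a feed schedule
#'
#' CSV columns: \code{time_h}, \code{V_feed_L}, \code{glc_feed_gL},
#' \code{glu_feed_mM}. JSON files hold the same records.
#'
#' @param path File path (\code{.csv} or \code{.json}).
#' @return A \code{\link{feed_schedule}}.
#' @export
read_feed_schedule <- function(path) {
  d <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.csv(path, check.names = FALSE)
  }
  need <- c("time_h", "V_feed_L", "glc_feed_gL", "glu_feed_mM")
  if (!all(need %in% names(d)))
    stop("feed file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  feed_schedule(d$time_h, d$V_feed_L, d$glc_feed_gL, d$glu_feed_mM)
}

#' @rdname read_feed_schedule
#' @param schedule A \code{\link{feed_schedule}}.
#' @export
write_feed_schedule <- function(schedule, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(as.data.frame(schedule), path, digits = NA)
  else
    write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#' @param sim A \code{\link{simulate_fedbatch}} result.
#' @param path Output path.
#' @export
write_simulation <- function(sim, path) {
  write.csv(sim$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Read model constants and parameter bounds from YAML or JSON
#'
#' The configuration may carry a \code{constants} block (alpha_glc,
#' glc_F_in, glu_F_in, V0) and a \code{bounds} block with named \code{lb},
#' \code{ub}, \code{ig} maps overriding individual defaults. The shipped
#' canonical configuration is in
#' \code{system.file("extdata", "mckm_config.yaml", package = "mckm")}.
#'
#' @param path Config path (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return List with \code{constants} (\code{\link{model_constants}}) and
#'   \code{bounds} (\code{\link{parameter_bounds}}).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  cons <- do.call(model_constants, cfg$constants %||% list())
  b <- cfg$bounds %||% list()
  bounds <- parameter_bounds(lb = unlist(b$lb), ub = unlist(b$ub),
                             ig = unlist(b$ig))
  list(constants = cons, bounds = bounds)
}

#' Write a regression result to JSON
#'
#' Serializes the fitted parameters (with units), balancing mode, metrics
#' and solver status; readable back with \code{\link{read_fit}}.
#'
#' @param fit A \code{\link{fit_run}} result.
#' @param path Output JSON path.
#' @export
write_fit <- function(fit, path) {
  units <- c(mu_max = "1/h", k_d = "1/h", K_glc = "g/L",
             Y_X_glc = "1e9cells/g", Y_X_gln = "1e9cells/mmol",
             Y_X_glu = "1e9cells/mmol", Y_lac_glc = "g/g",
             Y_X_amm = "1e9cells/mmol", Y_gln_glu = "mol/mol",
             Y_P_X = "g/1e9cells", Y_X_lac = "1e9cells/g",
             m_glc = "g/1e9cells/h", KD_amm = "mM")
  obj <- list(theta_hat = as.list(unclass(fit$theta_hat)),
              units = as.list(units),
              mode = fit$mode, status = fit$status,
              objective = fit$objective,
              r2 = as.list(fit$r2), nrmse = as.list(fit$nrmse),
              theta_ig = as.list(fit$theta_ig),
              metadata = fit$run$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a regression result written by \code{\link{write_fit}}
#' @param path JSON path.
#' @return List with the stored fields; \code{theta_hat} is restored as a
#'   \code{\link{kinetic_parameters}} vector.
#' @export
read_fit <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$theta_hat <- kinetic_parameters(unlist(obj$theta_hat))
  obj$r2 <- unlist(obj$r2)
  obj$nrmse <- unlist(obj$nrmse)
  obj
}

#' Write a synthetic campaign to a directory
#'
#' One run CSV per culture (\code{<clone>_<passage>_<rep>.csv}), the shared
#' \code{feeds.csv}, and \code{ground_truth.csv}.
#'
#' @param campaign A \code{\link{generate_campaign}} result.
#' @param dir Output directory (created if needed).
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feed_schedule(campaign$spec$schedule, file.path(dir, "feeds.csv"))
  write.csv(campaign$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  for (run in campaign$runs) {
    md <- run$metadata
    write_run(run, file.path(dir, sprintf("%s_%s_rep%d.csv", md$clone,
                                          md$passage, md$replicate)))
  }
  invisible(dir)
}
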