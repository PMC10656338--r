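#' Configuration of the Monte-Carlo benchmark study
#'
#' Crosses sample size, number of transitions and stable-trait variance, and
#' runs each replication through the requested centerings and estimators.
#' The benchmark grid is `N` in (200, 600, 1000), `K` in (4, 8) and trait
#' variances (10/9, 30/7, 10); the full protocol uses 200 replications, the
#' desk-scale default 50.
#'
#' @param N,K,phi2 grid values (vectors are crossed).
#' @param replications replications per cell.
#' @param methods estimators to run: subset of `c("msm", "snmm")`.
#' @param centerings subset of `c("true_score", "proposed", "observed_mean",
#'   "none", "ihat")`.
#' @param scenario passed to [dgp_spec()].
#' @param base_seed per-replication seed is `base_seed + replication index`.
#' @param spec_args extra arguments for [dgp_spec()].
#' @param measurement a [measurement_spec()] for the model-based centerings.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(N = c(200, 600, 1000), K = c(4, 8),
                         phi2 = c(10 / 9, 30 / 7, 10),
                         replications = 50,
                         methods = c("msm", "snmm"),
                         centerings = c("true_score", "proposed",
                                        "observed_mean", "none"),
                         scenario = "none", base_seed = 1L,
                         spec_args = list(),
                         measurement = measurement_spec()) {
  structure(list(N = N, K = K, phi2 = phi2, replications = replications,
                 methods = match.arg(methods, several.ok = TRUE),
                 centerings = centerings, scenario = scenario,
                 base_seed = as.integer(base_seed), spec_args = spec_args,
                 measurement = measurement),
            class = "study_config")
}

# one replication of one cell: returns per (centering x method) estimates
# plus first-step bookkeeping
.run_replication <- function(spec, config, msm_args = list(),
                             snmm_args = list()) {
  panel <- simulate_panel(spec)
  window <- spec$window
  horizons <- seq(min(window) + 1L, spec$K)
  n_fits <- 0L; n_improper <- 0L
  out <- list()
  for (ctr in config$centerings) {
    improper <- FALSE
    scores <- tryCatch({
      if (ctr %in% c("proposed", "ihat")) {
        ord <- c("Y", "A", "L")
        fits <- lapply(ord, function(v)
          fit_measurement_model(panel$values[[v]], config$measurement))
        names(fits) <- ord
        n_fits <- n_fits + length(fits)
        n_improper <- n_improper + sum(vapply(fits, `[[`, logical(1), "improper"))
        improper <- any(vapply(fits, `[[`, logical(1), "improper"))
        apply_centering(panel, ctr, fits = fits)
      } else apply_centering(panel, ctr)
    }, error = function(e) e)
    if (inherits(scores, "error")) {
      out[[ctr]] <- list(error = conditionMessage(scores)); next
    }
    res <- list(improper = improper)
    if (!improper) {   # improper first step: replication discarded
      for (meth in config$methods) {
        est <- tryCatch({
          if (meth == "msm") {
            fit <- do.call(msm, c(list(scores = scores, horizons = horizons,
                                       window = window), msm_args))
            fit$tau
          } else {
            fit <- do.call(snmm, c(list(scores = scores,
                                        blip = blip_spec(spec$K, window)),
                                   snmm_args))
            fit$tau
          }
        }, error = function(e) e)
        res[[meth]] <- if (inherits(est, "error"))
          structure(NA, error = conditionMessage(est)) else est
      }
    }
    out[[ctr]] <- res
  }
  list(estimates = out, n_fits = n_fits, n_improper = n_improper)
}

#' Run the Monte-Carlo benchmark study
#'
#' For every grid cell, simulates `replications` seeded panels, applies each
#' centering and estimator, and scores the estimates against the analytic
#' joint-effect oracle. Replications whose first-step measurement model
#' yields an improper solution are discarded (and counted); estimator crashes
#' are recorded per replication, never fatal to the study.
#'
#' @param config a [study_config()].
#' @param msm_args,snmm_args extra arguments for [msm()] / [snmm()].
#' @param verbose print per-cell progress.
#' @return object of class `"study_result"`: `cells`, a data frame with one
#'   row per (cell, centering, method, parameter) carrying bias and RMSE;
#'   `improper` (count and total of first-step fits); `estimates`, the raw
#'   per-replication estimates; `truth`, the oracle values per `K`.
#' @export
run_simulation_study <- function(config, msm_args = list(),
                                 snmm_args = list(), verbose = FALSE) {
  grid <- expand.grid(N = config$N, K = config$K, phi2 = config$phi2,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list(); raw <- list()
  tot_fits <- 0L; tot_improper <- 0L
  truth <- list()
  for (ci in seq_len(nrow(grid))) {
    N <- grid$N[ci]; K <- grid$K[ci]; phi2 <- grid$phi2[ci]
    spec0 <- do.call(dgp_spec, c(list(N = N, K = K, phi2 = phi2,
                                      scenario = config$scenario),
                                 config$spec_args))
    tk <- as.character(K)
    if (is.null(truth[[tk]]))
      truth[[tk]] <- .oracle_tau(true_joint_effects(spec0$coefficients, K,
                                                    spec0$window))
    tau_true <- truth[[tk]]
    reps <- lapply(seq_len(config$replications), function(r) {
      spec <- spec0; spec$seed <- config$base_seed + r
      .run_replication(spec, config, msm_args, snmm_args)
    })
    tot_fits <- tot_fits + sum(vapply(reps, `[[`, integer(1), "n_fits"))
    tot_improper <- tot_improper +
      sum(vapply(reps, `[[`, integer(1), "n_improper"))
    cell_key <- sprintf("N%d_K%d_phi%.3g", N, K, phi2)
    raw[[cell_key]] <- reps
    for (ctr in config$centerings) {
      for (meth in config$methods) {
        est <- lapply(reps, function(r) {
          e <- r$estimates[[ctr]]
          if (is.null(e) || isTRUE(e$improper) || is.null(e[[meth]])) return(NULL)
          v <- e[[meth]]
          if (length(v) == 1 && is.na(v)) return(NULL)
          v
        })
        est <- Filter(Negate(is.null), est)
        if (!length(est)) next
        M <- do.call(rbind, lapply(est, function(v) v[names(tau_true)]))
        bias <- colMeans(M, na.rm = TRUE) - tau_true
        rmse <- sqrt(colMeans(sweep(M, 2, tau_true)^2, na.rm = TRUE))
        avail <- colSums(!is.na(M))
        rows[[length(rows) + 1L]] <-
          data.frame(N = N, K = K, phi2 = phi2, centering = ctr,
                     method = meth, parameter = names(tau_true),
                     truth = unname(tau_true), bias = unname(bias),
                     rmse = unname(rmse), n_used = length(est),
                     n_available = unname(avail))
      }
    }
    if (verbose)
      message(sprintf("cell %s done (%d improper fits so far)",
                      cell_key, tot_improper))
  }
  structure(list(cells = do.call(rbind, rows),
                 improper = list(count = tot_improper, total = tot_fits,
                                 rate = if (tot_fits > 0)
                                   tot_improper / tot_fits else NA_real_),
                 estimates = raw, truth = truth, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Monte-Carlo study result\n")
  agg <- stats::aggregate(cbind(abs_bias = abs(bias), rmse) ~
                            centering + method + N + K + phi2,
                          data = x$cells, FUN = mean)
  print(agg, digits = 3)
  if (x$improper$total > 0)
    cat(sprintf("first-step improper solutions: %d / %d (%.3f%%)\n",
                x$improper$count, x$improper$total, 100 * x$improper$rate))
  invisible(x)
}

#' Two-step pipeline on one panel
#'
#' Composes the full analysis: per-variable measurement models, score
#' prediction (or another centering), and the requested second-step
#' estimator(s). Identical to running the stages by hand with the same
#' settings.
#'
#' @param panel a [panel_data()].
#' @param centering centering method (see [apply_centering()]).
#' @param measurement a [measurement_spec()].
#' @param methods subset of `c("msm", "snmm")`.
#' @param window intervened treatment occasions (default: all, or the last
#'   four when `K > 4`).
#' @param interactions confounder names moderating each blip (SNMM), e.g.
#'   the Table-1-style analysis uses every confounder.
#' @param nboot bootstrap replicates for standard errors.
#' @param msm_args,snmm_args extra arguments for the estimators.
#' @return list of class `"wps_pipeline"` with `scores` and the fitted
#'   `msm` / `snmm` objects, plus a tidy `coefficients` table.
#' @export
run_pipeline <- function(panel, centering = "proposed",
                         measurement = measurement_spec(),
                         methods = c("snmm", "msm"), window = NULL,
                         interactions = character(0), nboot = 0,
                         msm_args = list(), snmm_args = list()) {
  methods <- match.arg(methods, c("snmm", "msm"), several.ok = TRUE)
  scores <- tryCatch(apply_centering(panel, centering, spec = measurement),
                     error = function(e)
                       .stopf("step 1 (scores): %s", conditionMessage(e)))
  window <- window %||% .default_window(scores)
  horizons <- seq(min(window) + 1L, panel$K)
  out <- list(scores = scores)
  if ("msm" %in% methods)
    out$msm <- tryCatch(
      do.call(msm, c(list(scores = scores, horizons = horizons,
                          window = window, nboot = nboot), msm_args)),
      error = function(e) .stopf("step 2 (msm): %s", conditionMessage(e)))
  if ("snmm" %in% methods)
    out$snmm <- tryCatch(
      do.call(snmm, c(list(scores = scores,
                           blip = blip_spec(panel$K, window, interactions),
                           nboot = nboot), snmm_args)),
      error = function(e) .stopf("step 2 (snmm): %s", conditionMessage(e)))
  tabs <- list()
  if (!is.null(out$snmm))
    tabs$snmm <- data.frame(method = "snmm",
                            parameter = names(out$snmm$tau),
                            estimate = unname(out$snmm$tau),
                            se = if (!is.null(out$snmm$se))
                              unname(out$snmm$se) else NA_real_)
  if (!is.null(out$msm))
    tabs$msm <- data.frame(method = "msm",
                           parameter = names(out$msm$tau),
                           estimate = unname(out$msm$tau),
                           se = if (!is.null(out$msm$se))
                             unname(out$msm$se) else NA_real_)
  out$coefficients <- do.call(rbind, tabs)
  rownames(out$coefficients) <- NULL
  class(out) <- "wps_pipeline"
  out
}

#' @export
print.wps_pipeline <- function(x, ...) {
  cat(sprintf("two-step pipeline (%s centering)\n", x$scores$method))
  print(x$coefficients, digits = 4)
  invisible(x)
}
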