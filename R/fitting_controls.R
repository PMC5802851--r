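#' Sweep specification for the three global parameters
#'
#' Grids for the long-range coupling `G` and the drive weights `w_BG_E`
#' and `w_BG_I`; the inhibitory-to-excitatory drive ratio
#' `w_BG_I / w_BG_E` is constrained to a biologically plausible range
#' (inhibitory postsynaptic currents exceed excitatory ones), default
#' \[5, 200\]. Combinations violating the constraint are excluded before
#' the sweep.
#'
#' @param G_grid,w_BG_E_grid,w_BG_I_grid numeric grids (nonempty).
#' @param ratio_bounds length-2 bounds on `w_BG_I / w_BG_E`.
#' @param fic_iterations FIC iterations per combination (default 12).
#' @param objective scoring rule: region-wise time-series correlation,
#'   static FC similarity, or sliding-window dynamic FC quality.
#' @return Object of class `sweep_spec` with the admissible combination
#'   table in `$combinations`.
#' @export
sweep_spec <- function(G_grid, w_BG_E_grid, w_BG_I_grid,
                       ratio_bounds = c(5, 200), fic_iterations = 12,
                       objective = c("timeseries", "static_fc",
                                     "dynamic_fc")) {
  objective <- match.arg(objective)
  if (length(G_grid) == 0 || length(w_BG_E_grid) == 0 ||
      length(w_BG_I_grid) == 0)
    stop("parameter grids must be nonempty")
  combos <- expand.grid(G = G_grid, w_BG_E = w_BG_E_grid,
                        w_BG_I = w_BG_I_grid, KEEP.OUT.ATTRS = FALSE)
  ratio <- combos$w_BG_I / combos$w_BG_E
  keep <- is.finite(ratio) & ratio >= ratio_bounds[1] &
    ratio <= ratio_bounds[2]
  if (!any(keep))
    stop("ratio bounds exclude every grid combination")
  structure(list(combinations = combos[keep, , drop = FALSE],
                 ratio_bounds = ratio_bounds,
                 fic_iterations = fic_iterations,
                 objective = objective),
            class = "sweep_spec")
}

#' Brute-force parameter sweep with FIC in the loop
#'
#' For every admissible `(G, w_BG_E, w_BG_I)` combination: tune feedback
#' inhibition, simulate, run the hemodynamic forward model, and score the
#' simulated BOLD against the target by the configured objective. Failing
#' combinations are recorded (score `NA`) and the sweep continues.
#'
#' @param C a [structural_connectome()].
#' @param drive a [drive_timeseries()].
#' @param target_bold a [bold_series()] to score against (empirical or
#'   synthetic ground truth).
#' @param spec a [sweep_spec()].
#' @param p base [model_parameters()]; the three swept parameters override
#'   its values per combination.
#' @param duration_s simulated seconds per run (defaults to drive duration).
#' @param hp [hemodynamic_parameters()].
#' @param progress print one line per combination.
#' @return Object of class `sweep_result`: `results` (one row per
#'   combination with score and FIC summary), `best` (the argmax row),
#'   `best_J` (tuned weights of the best combination).
#' @export
run_sweep <- function(C, drive, target_bold, spec, p = model_parameters(),
                      duration_s = NULL, hp = hemodynamic_parameters(),
                      progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  combos <- spec$combinations
  scores <- rep(NA_real_, nrow(combos))
  fic_err <- rep(NA_real_, nrow(combos))
  J_list <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pi <- p
    pi$G <- combos$G[i]
    pi$w_BG_E <- combos$w_BG_E[i]
    pi$w_BG_I <- combos$w_BG_I[i]
    res <- tryCatch({
      fic <- fic_tune(C, drive, pi, duration_s = duration_s,
                      max_iterations = spec$fic_iterations)
      tr <- simulate_network(C, drive, J = fic$J, p = pi,
                             duration_s = duration_s,
                             record_vars = "S_E")
      sim_bold <- trace_to_bold(tr, hp)
      score <- switch(spec$objective,
        timeseries = prediction_quality(sim_bold, target_bold),
        static_fc = fc_similarity(functional_connectivity(sim_bold),
                                  functional_connectivity(target_bold)),
        dynamic_fc = dynamic_fc_quality(sim_bold, target_bold,
                                        window = min(100,
                                          ncol(sim_bold$values) - 1)))
      list(score = score, J = fic$J,
           err = fic$diagnostics$global_error[fic$selected_iteration])
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      scores[i] <- res$score
      fic_err[i] <- res$err
      J_list[[i]] <- res$J
    }
    if (progress)
      message(sprintf("combination %d/%d: G=%g wE=%g wI=%g score=%s",
                      i, nrow(combos), combos$G[i], combos$w_BG_E[i],
                      combos$w_BG_I[i], format(scores[i], digits = 4)))
  }
  results <- cbind(combos, score = scores, fic_global_error = fic_err)
  best_i <- if (all(is.na(scores))) NA_integer_ else which.max(scores)
  structure(list(results = results,
                 best = if (is.na(best_i)) NULL else results[best_i, ],
                 best_J = if (is.na(best_i)) NULL else J_list[[best_i]],
                 objective = spec$objective),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep (%s objective): %d combinations, %d failed\n",
              x$objective, nrow(x$results), sum(is.na(x$results$score))))
  if (!is.null(x$best)) {
    cat("  best: ")
    print(x$best, row.names = FALSE)
  }
  invisible(x)
}

#' Noise-driven control model
#'
#' The original dynamic mean-field configuration: no injected drive
#' (`w_BG_E = w_BG_I = 0`), local recurrence enabled, additive Gaussian
#' current noise. FIC tuning and the hemodynamic pipeline are identical to
#' the drive-injected model. This control predicts functional connectivity
#' through the connectome but cannot predict the target's time course.
#'
#' @param C a [structural_connectome()].
#' @param p [model_parameters()]; drive weights are forced to zero and
#'   recurrence on; `noise_sigma` defaults to 0.01 nA if unset.
#' @param duration_s simulated seconds.
#' @param seed integer seed for the noise stream.
#' @param fic_iterations FIC iterations (default 12).
#' @param hp [hemodynamic_parameters()].
#' @return List: `bold` (a [bold_series()]), `fic` (the tuning result),
#'   `trace`.
#' @export
control_noise_model <- function(C, p = model_parameters(), duration_s,
                                seed = 1, fic_iterations = 12,
                                hp = hemodynamic_parameters()) {
  p$w_BG_E <- 0
  p$w_BG_I <- 0
  p$recurrence_enabled <- TRUE
  if (p$noise_sigma <= 0) p$noise_sigma <- 0.01
  fic <- fic_tune(C, NULL, p, duration_s = duration_s,
                  max_iterations = fic_iterations, seed = seed)
  tr <- simulate_network(C, NULL, J = fic$J, p = p, duration_s = duration_s,
                         record_vars = "S_E", seed = seed + 1L)
  list(bold = trace_to_bold(tr, hp), fic = fic, trace = tr)
}

#' Permutation control model
#'
#' Randomly permutes the drive samples in time (independently per region)
#' and runs the identical FIC + simulation + hemodynamics pipeline. The
#' permuted drive keeps each region's amplitude distribution but carries no
#' temporal information, so time-series prediction collapses while
#' FC structure (carried by the connectome and drive variances) survives.
#'
#' @param C a [structural_connectome()].
#' @param drive a [drive_timeseries()].
#' @param p [model_parameters()].
#' @param seed permutation seed.
#' @param duration_s simulated seconds (defaults to drive duration).
#' @param fic_iterations FIC iterations.
#' @param hp [hemodynamic_parameters()].
#' @return List: `bold`, `fic`, `trace`, `permuted_drive`.
#' @export
control_permuted <- function(C, drive, p = model_parameters(), seed = 1,
                             duration_s = NULL, fic_iterations = 12,
                             hp = hemodynamic_parameters()) {
  pd <- permute_drive(drive, seed)
  fic <- fic_tune(C, pd, p, duration_s = duration_s,
                  max_iterations = fic_iterations)
  tr <- simulate_network(C, pd, J = fic$J, p = p, duration_s = duration_s,
                         record_vars = "S_E")
  list(bold = trace_to_bold(tr, hp), fic = fic, trace = tr,
       permuted_drive = pd)
}

#' Write sweep results to CSV + JSON summary
#'
#' @param sweep a `sweep_result`.
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_sweep <- function(sweep, prefix) {
  p1 <- paste0(prefix, "_results.csv")
  p2 <- paste0(prefix, "_summary.json")
  utils::write.csv(sweep$results, p1, row.names = FALSE)
  jsonlite::write_json(
    list(objective = sweep$objective,
         n_combinations = nrow(sweep$results),
         n_failed = sum(is.na(sweep$results$score)),
         best = as.list(sweep$best)),
    p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
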