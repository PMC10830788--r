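#' Configuration for a replicate simulation ensemble
#'
#' Describes the full factorial design: kinetic parameter sets (one per
#' excited mode) x hole radii x seeded repetitions. The defaults reproduce
#' the reference study design: four parameter sets at
#' \eqn{(a, b) = (0.20, 1.00)} with \eqn{(\gamma, d, k)} =
#' (6.87, 20, 0.01), (20.62, 18, 0.01), (41.24, 17.5, 0.005),
#' (68.73, 17.5, 0.005) for modes 1--4; 15 hole radii from 0 to 0.70 in
#' steps of 0.05; 20 repetitions; final time 50 — 1200 simulations in all.
#' The radius grid is an assumption (the source states 15 radii spanning
#' [0, 0.70] without listing them) and can be overridden.
#'
#' The diffusion ratios for modes 3 and 4 are not printed in the source;
#' values slightly above the critical diffusion 17.01 are used, consistent
#' with "d sufficiently close to d_c".
#'
#' @param parameter_sets Tibble with columns `mode`, `a`, `b`, `gamma`, `d`,
#'   `k` (step size).
#' @param radii Hole radii in radians, within `[0, 0.7]`.
#' @param repetitions Repetitions per cell (>= 1).
#' @param T_final Final time.
#' @param resolution Mesh target edge length.
#' @param base_seed Integer; per-run seeds are derived deterministically from
#'   it (see Details).
#' @param lumped Mass-lumping flag for the stepper.
#' @param n_max Largest harmonic degree recorded per run.
#'
#' @details Per-run seeds are
#'   `(base_seed * 100003 + param_index * 10007 + radius_index * 101 + rep) mod (2^31 - 1)`,
#'   so any sub-design can be reproduced independently of the rest.
#'
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(
    parameter_sets = tibble::tibble(
      mode = 1:4,
      a = 0.2, b = 1,
      gamma = c(6.87, 20.62, 41.24, 68.73),
      d = c(20, 18, 17.5, 17.5),
      k = c(0.01, 0.01, 0.005, 0.005)
    ),
    radii = seq(0, 0.70, by = 0.05),
    repetitions = 20L,
    T_final = 50,
    resolution = 0.05,
    base_seed = 1L,
    lumped = FALSE,
    n_max = 4L) {
  stopifnot(all(radii >= 0), all(radii <= 0.7), repetitions >= 1)
  req <- c("mode", "a", "b", "gamma", "d", "k")
  if (!all(req %in% names(parameter_sets))) {
    stop("parameter_sets needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(parameter_sets = parameter_sets, radii = radii,
         repetitions = as.integer(repetitions), T_final = T_final,
         resolution = resolution, base_seed = as.integer(base_seed),
         lumped = lumped, n_max = as.integer(n_max)),
    class = "ensemble_config"
  )
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf(
    "<ensemble_config> %d parameter set(s) x %d radii x %d reps = %d runs (T=%g, h=%g)\n",
    nrow(x$parameter_sets), length(x$radii), x$repetitions,
    nrow(x$parameter_sets) * length(x$radii) * x$repetitions,
    x$T_final, x$resolution))
  invisible(x)
}

run_seed <- function(base_seed, param_index, radius_index, rep) {
  as.integer((as.numeric(base_seed) * 100003 + param_index * 10007 +
                radius_index * 101 + rep) %% (2^31 - 1))
}

#' Run a replicate ensemble of pattern simulations
#'
#' Executes one simulation per (parameter set, hole radius, repetition) cell
#' and collects the pattern metrics and harmonic coefficients into a long
#' tibble. Meshes are built once per radius and their FEM operators reused
#' across repetitions. Individual run failures are caught, logged, and marked
#' in the `failed` column; they never abort the ensemble and are excluded
#' from summaries.
#'
#' @param config An [ensemble_config()].
#' @param progress Print a line per run (seed, radius, u range, runtime).
#' @param previous Optional earlier `ensemble_results` for the same config:
#'   its successful rows are kept as-is and only the missing or failed cells
#'   are (re)computed, so interrupted ensembles resume cheaply.
#' @return An `ensemble_results` tibble with one row per run: design keys
#'   (`mode`, `epsilon`, `rep`, `seed`), the [pattern_metrics()] columns,
#'   harmonic coefficients in wide columns `U<n>_<m>`, and `failed`.
#' @export
run_ensemble <- function(config, progress = FALSE, previous = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  ps <- config$parameter_sets
  done <- if (is.null(previous)) character(0) else {
    with(previous[!previous$failed, ],
         paste(mode, epsilon, rep, sep = "|"))
  }
  rows <- list()
  for (ri in seq_along(config$radii)) {
    eps <- config$radii[ri]
    mesh <- cap_mesh(eps, config$resolution)
    ops <- assemble_operators(mesh)
    for (pi in seq_len(nrow(ps))) {
      params <- schnak_params(ps$a[pi], ps$b[pi], ps$gamma[pi], ps$d[pi])
      for (rep in seq_len(config$repetitions)) {
        key <- paste(ps$mode[pi], eps, rep, sep = "|")
        if (key %in% done) {
          prev <- previous[!previous$failed &
                             previous$mode == ps$mode[pi] &
                             previous$epsilon == eps & previous$rep == rep, ]
          rows[[length(rows) + 1L]] <- prev[1L, ]
          next
        }
        seed <- run_seed(config$base_seed, pi, ri, rep)
        row <- tryCatch({
          sim <- simulate_schnakenberg(
            mesh, params, T_final = config$T_final, k = ps$k[pi],
            seed = seed, snapshot_times = numeric(0), lumped = config$lumped
          )
          met <- pattern_metrics(sim$state, mesh)
          coef <- project_harmonics(sim$state, mesh, n_max = config$n_max,
                                    ops = ops)
          wide <- stats::setNames(
            as.list(coef$coefficient),
            sprintf("U%d_%d", coef$n, coef$m)
          )
          if (progress) {
            message(sprintf(
              "mode=%d eps=%.2f rep=%d seed=%d u=[%.3f, %.3f] (%.1fs)",
              ps$mode[pi], eps, rep, seed, met$u_min, met$u_max,
              sim$log$runtime_s))
          }
          dplyr::bind_cols(
            tibble::tibble(mode = ps$mode[pi], epsilon = eps, rep = rep,
                           seed = seed, failed = FALSE),
            met, tibble::as_tibble(wide)
          )
        }, error = function(e) {
          warning(sprintf("run failed (mode=%d eps=%.2f rep=%d): %s",
                          ps$mode[pi], eps, rep, conditionMessage(e)),
                  call. = FALSE)
          tibble::tibble(mode = ps$mode[pi], epsilon = eps, rep = rep,
                         seed = seed, failed = TRUE)
        })
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ensemble_results", setdiff(class(out), "ensemble_results"))
  out
}

#' Percentile summary of ensemble metrics
#'
#' Empirical percentiles of every numeric metric per (mode, hole radius)
#' cell, using linear interpolation between order statistics
#' (`stats::quantile` type 7). The reference study plots the 5th, 50th and
#' 95th percentiles over 20 repetitions.
#'
#' @param results [run_ensemble()] output (failed rows are dropped).
#' @param levels Percentile levels in percent (default `c(5, 50, 95)`).
#' @param metrics Columns to summarise; defaults to all numeric metric and
#'   coefficient columns.
#' @return Long tibble: `mode`, `epsilon`, `metric`, `percentile`, `value`.
#' @export
percentile_summary <- function(results, levels = c(5, 50, 95),
                               metrics = NULL) {
  stopifnot(all(levels >= 0), all(levels <= 100))
  res <- dplyr::filter(results, !.data$failed)
  if (nrow(res) == 0L) stop("no successful runs to summarise", call. = FALSE)
  if (is.null(metrics)) {
    drop <- c("mode", "epsilon", "rep", "seed", "failed", "threshold_used")
    metrics <- setdiff(names(res)[vapply(res, is.numeric, TRUE)], drop)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(res, dplyr::all_of(c("mode", "epsilon", metrics))),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(.data$mode, .data$epsilon, .data$metric) |>
    dplyr::reframe(
      percentile = levels,
      value = as.vector(stats::quantile(.data$value, probs = levels / 100,
                                        type = 7, na.rm = TRUE))
    )
  class(out) <- c("ensemble_summary", class(out))
  out
}

#' Test for a linear trend in a metric against the hole radius
#'
#' The trend test used for the robustness claims: repetition values are first
#' averaged per hole radius, then the cell means are regressed on the radius
#' by ordinary least squares, and the slope is tested against zero with a
#' two-sided t test at level `alpha`. Averaging before regressing is part of
#' the procedure (pooled rows would inflate the sample size).
#'
#' @param radii Hole radii (numeric, >= 3 distinct values).
#' @param cell_means Mean metric value per radius (same length). `NA` cells
#'   (e.g. the hole-distance metric at `epsilon = 0`, where it is undefined)
#'   are dropped pairwise.
#' @param alpha Significance level (default 0.05).
#' @return A `slope_test` object; see [tidy.slope_test()] and
#'   [glance.slope_test()]. Printing shows slope, p-value and the verdict.
#' @examples
#' slope_test(1:5, 2 * (1:5) + 3)
#' @export
slope_test <- function(radii, cell_means, alpha = 0.05) {
  stopifnot(length(radii) == length(cell_means))
  ok <- is.finite(radii) & is.finite(cell_means)
  radii <- radii[ok]
  cell_means <- cell_means[ok]
  if (length(radii) < 3L) {
    stop("slope_test() needs at least 3 radii with data", call. = FALSE)
  }
  fit <- stats::lm(cell_means ~ radii)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(sm["radii", "Estimate"])
  p <- unname(sm["radii", "Pr(>|t|)"])
  if (is.nan(p)) p <- 1  # exactly collinear (e.g. perfectly flat) data
  structure(
    list(fit = fit, slope = slope, p_value = p, alpha = alpha,
         significant = p < alpha, n = length(radii)),
    class = "slope_test"
  )
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("<slope_test> slope = %.6g, p = %.4g (%ssignificant at %.2g)\n",
              x$slope, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Tidy a slope test
#'
#' @param x A [slope_test()] object.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` for the slope.
#' @export
tidy.slope_test <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = "radius",
    estimate = unname(sm["radii", "Estimate"]),
    std.error = unname(sm["radii", "Std. Error"]),
    statistic = unname(sm["radii", "t value"]),
    p.value = x$p_value
  )
}

#' Glance at a slope test
#'
#' @param x A [slope_test()] object.
#' @param ... Unused.
#' @return One-row tibble: `slope`, `p.value`, `significant`, `alpha`,
#'   `r.squared`, `n`.
#' @export
glance.slope_test <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, p.value = x$p_value, significant = x$significant,
    alpha = x$alpha,
    r.squared = suppressWarnings(summary(x$fit))$r.squared, n = x$n
  )
}
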