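# numeric markov_arm fields a sweep or PSA may target, with invariant ranges
arm_param_ranges <- function() {
  list(incidence = c(0, 1), recovery = c(0, 1),
       utility_baseline = c(0, 1), utility_deteriorated = c(0, 1),
       cost_baseline = c(0, Inf), cost_deteriorated = c(0, Inf),
       rr_baseline = c(1e-12, Inf), rr_deteriorated = c(1e-12, Inf),
       one_off_cost = c(0, Inf), recurring_cost = c(0, Inf))
}

available_paths <- function() {
  as.vector(outer(c("intervention", "comparator"),
                  names(arm_param_ranges()), paste, sep = "."))
}

resolve_path <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  ok <- length(parts) == 2 && parts[1] %in% c("intervention", "comparator") &&
    parts[2] %in% names(arm_param_ranges())
  if (!ok)
    stop("unknown parameter path '", path, "'; available paths:\n  ",
         paste(available_paths(), collapse = ", "), call. = FALSE)
  list(arm = parts[1], field = parts[2],
       range = arm_param_ranges()[[parts[2]]])
}

set_path <- function(model, path, value) {
  p <- resolve_path(path)
  model[[p$arm]][[p$field]] <- pmin(pmax(value, p$range[1]), p$range[2])
  model
}

get_path <- function(model, path) {
  p <- resolve_path(path)
  model[[p$arm]][[p$field]]
}

#' One-way sensitivity sweep specification
#'
#' @param parameter one or more parameter paths of the form
#'   `"<arm>.<field>"` (e.g. `"intervention.utility_baseline"`); when
#'   several paths are given they are perturbed jointly by the same factor.
#' @param relative_range relative perturbation bounds, default `c(-0.05, 0.05)`.
#' @param n_points grid size (default 21, i.e. 0.5% steps across +/-5%).
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, relative_range = c(-0.05, 0.05),
                       n_points = 21, wtp = 15000) {
  lapply(parameter, resolve_path)  # fail fast on unknown paths
  if (length(relative_range) != 2 || relative_range[1] > relative_range[2])
    stop("relative_range bounds must be ordered", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  structure(list(parameter = parameter, relative_range = relative_range,
                 n_points = as.integer(n_points), wtp = wtp),
            class = "sweep_spec")
}

#' Deterministic one-way sensitivity sweep
#'
#' Multiplies the target parameter(s) by `(1 + delta)` over a relative grid,
#' reruns both model arms at each grid point (perturbed values are clipped
#' to the parameter's invariant range, e.g. utilities to `[0, 1]`) and
#' records the incremental results. The zero-perturbation grid point
#' reproduces the base case exactly.
#'
#' @param model a [markov_cea()] fit.
#' @param spec a [sweep_spec()], or a parameter path which is promoted to
#'   one with default settings.
#' @return object of class `cea_sweep`: `grid` (data.frame `perturbation`,
#'   `delta_cost`, `delta_effect`, `icer`), `max_icer` (maximum finite ICER
#'   over grid points with positive incremental effect), `all_below_wtp`,
#'   `spec`.
#' @export
#' @examples
#' m <- markov_cea(default_model_inputs()$intervention,
#'                 default_model_inputs()$comparator)
#' sw <- one_way_sweep(m, "intervention.utility_baseline")
#' sw$max_icer
one_way_sweep <- function(model, spec) {
  stopifnot(inherits(model, "markov_cea"))
  if (is.character(spec)) spec <- sweep_spec(spec)
  stopifnot(inherits(spec, "sweep_spec"))
  deltas <- seq(spec$relative_range[1], spec$relative_range[2],
                length.out = spec$n_points)
  base_vals <- lapply(spec$parameter, get_path, model = model)
  rows <- vector("list", length(deltas))
  for (i in seq_along(deltas)) {
    m <- model
    if (deltas[i] != 0)
      for (j in seq_along(spec$parameter))
        m <- set_path(m, spec$parameter[j], base_vals[[j]] * (1 + deltas[i]))
    fit <- markov_cea(m$intervention, m$comparator, m$econ, m$life_table,
                      wtp = spec$wtp)
    res <- fit$result
    rows[[i]] <- data.frame(perturbation = deltas[i],
                            delta_cost = res$delta_cost,
                            delta_effect = res$delta_effect,
                            icer = res$icer)
  }
  grid <- do.call(rbind, rows)
  ok <- is.finite(grid$icer) & grid$delta_effect > 0
  max_icer <- if (any(ok)) max(grid$icer[ok]) else NA_real_
  structure(list(grid = grid, max_icer = max_icer,
                 all_below_wtp = all(ok) && max_icer <= spec$wtp,
                 spec = spec),
            class = "cea_sweep")
}

#' @export
print.cea_sweep <- function(x, ...) {
  cat("One-way sensitivity sweep of ",
      paste(x$spec$parameter, collapse = " + "), "\n", sep = "")
  cat(sprintf("  %d grid points over [%+.1f%%, %+.1f%%]\n",
              x$spec$n_points, 100 * x$spec$relative_range[1],
              100 * x$spec$relative_range[2]))
  cat(sprintf("  max ICER %.2f EUR/QALY; all below WTP %.0f: %s\n",
              x$max_icer, x$spec$wtp, x$all_below_wtp))
  invisible(x)
}

#' @export
plot.cea_sweep <- function(x, ...) {
  graphics::plot(100 * x$grid$perturbation, x$grid$icer, type = "b", pch = 19,
                 xlab = "Parameter change (%)", ylab = "ICER (EUR/QALY)",
                 main = paste("Sweep:", paste(x$spec$parameter, collapse = " + ")),
                 ylim = range(c(x$grid$icer, x$spec$wtp), finite = TRUE), ...)
  graphics::abline(h = x$spec$wtp, lty = 2, col = "red")
  graphics::mtext(sprintf("WTP = %.0f", x$spec$wtp), side = 4, col = "red")
  invisible(x)
}

#' Threshold verdict over a sweep
#'
#' `TRUE` iff every grid point with positive incremental effect has a
#' finite ICER at or below the willingness-to-pay threshold. Dominated grid
#' points (negative incremental effect at extra cost) make the verdict
#' `FALSE`, with the offending perturbations attached as an attribute.
#'
#' @param sweep a [one_way_sweep()] result.
#' @param wtp willingness-to-pay threshold (euro/QALY).
#' @return logical scalar; attribute `failing_points` lists perturbations
#'   that break the verdict.
#' @export
threshold_verdict <- function(sweep, wtp) {
  stopifnot(inherits(sweep, "cea_sweep"))
  g <- sweep$grid
  dominated <- g$delta_effect < 0 & g$delta_cost >= 0
  over <- !dominated & is.finite(g$icer) & g$delta_effect > 0 & g$icer > wtp
  bad <- g$perturbation[dominated | over]
  structure(length(bad) == 0, failing_points = bad)
}

#' Cost-effectiveness plane
#'
#' Serializable (incremental effect, incremental cost) points with the
#' willingness-to-pay line `delta_cost = wtp * delta_effect`, for plotting
#' incremental results, sweep grids or probabilistic clouds.
#'
#' @param results a list of [compare_arms()] results, a `cea_sweep`, or a
#'   `cea_psa` object.
#' @param wtp willingness-to-pay threshold (the line slope).
#' @return object of class `ce_plane`: `points` (data.frame `delta_effect`,
#'   `delta_cost`, `label`) and `wtp`.
#' @export
ce_plane <- function(results, wtp = 15000) {
  if (inherits(results, "cea_sweep")) {
    pts <- data.frame(delta_effect = results$grid$delta_effect,
                      delta_cost = results$grid$delta_cost,
                      label = sprintf("%+.1f%%", 100 * results$grid$perturbation))
  } else if (inherits(results, "cea_psa")) {
    pts <- data.frame(delta_effect = results$draws$delta_effect,
                      delta_cost = results$draws$delta_cost,
                      label = paste0("draw_", seq_len(nrow(results$draws))))
  } else {
    if (inherits(results, "cea_result")) results <- list(results)
    if (!length(results)) stop("no points to plot", call. = FALSE)
    pts <- do.call(rbind, lapply(seq_along(results), function(i) {
      r <- results[[i]]
      stopifnot(inherits(r, "cea_result"))
      data.frame(delta_effect = r$delta_effect, delta_cost = r$delta_cost,
                 label = paste(r$arms, collapse = "_vs_"))
    }))
  }
  if (!nrow(pts)) stop("no points to plot", call. = FALSE)
  if (any(!is.finite(pts$delta_effect)) || any(!is.finite(pts$delta_cost)))
    stop("non-finite plane coordinates", call. = FALSE)
  structure(list(points = pts, wtp = wtp), class = "ce_plane")
}

#' @export
plot.ce_plane <- function(x, ...) {
  p <- x$points
  xlim <- range(c(0, p$delta_effect)); ylim <- range(c(0, p$delta_cost, x$wtp * xlim))
  graphics::plot(p$delta_effect, p$delta_cost, pch = 19, col = "steelblue",
                 xlim = xlim, ylim = ylim,
                 xlab = "Incremental effect (QALYs)",
                 ylab = "Incremental cost (EUR)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = x$wtp, lty = 2, col = "red")
  graphics::mtext(sprintf("WTP = %.0f EUR/QALY", x$wtp), side = 3, col = "red",
                  cex = 0.8)
  invisible(x)
}

# moment-matched distribution sampler for one parameter
sample_param <- function(spec, n) {
  m <- spec$mean; s <- spec$sd
  switch(spec$dist,
    fixed = rep(m, n),
    beta = {
      if (s <= 0) return(rep(m, n))
      if (m <= 0 || m >= 1) return(rep(m, n))
      v <- min(s^2, m * (1 - m) * 0.999)
      k <- m * (1 - m) / v - 1
      stats::rbeta(n, m * k, (1 - m) * k)
    },
    gamma = {
      if (s <= 0 || m <= 0) return(rep(m, n))
      stats::rgamma(n, shape = (m / s)^2, rate = m / s^2)
    },
    normal = stats::rnorm(n, m, s),
    stop("unknown distribution: ", spec$dist, call. = FALSE))
}

#' Default probabilistic distributions for a fitted model
#'
#' Beta distributions (moment-matched) for probabilities and utilities and
#' gamma distributions for costs, each centred on the base-case value with
#' a relative standard deviation `cv`. Parameters with a zero base value
#' are held fixed.
#'
#' @param model a [markov_cea()] fit.
#' @param cv relative standard deviation of each sampled parameter
#'   (default 0.1).
#' @return named list of distribution specs, keyed by parameter path.
#' @export
default_psa_distributions <- function(model, cv = 0.1) {
  stopifnot(inherits(model, "markov_cea"))
  probs <- c("incidence", "recovery", "utility_baseline", "utility_deteriorated")
  costs <- c("cost_baseline", "cost_deteriorated", "recurring_cost")
  out <- list()
  for (arm in c("intervention", "comparator")) {
    for (f in c(probs, costs)) {
      m <- model[[arm]][[f]]
      out[[paste(arm, f, sep = ".")]] <-
        list(dist = if (m == 0) "fixed" else if (f %in% probs) "beta" else "gamma",
             mean = m, sd = cv * m)
    }
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws the model parameters from declared distributions, reruns the full
#' two-arm model per draw and summarises the resulting cloud of incremental
#' results. Draws landing outside a parameter's invariant range are
#' resampled (up to 100 times, then clipped); the number of capped draws is
#' reported. This is an optional extension beyond the deterministic sweeps;
#' it is seeded and fully reproducible.
#'
#' @param model a [markov_cea()] fit.
#' @param distributions named list of distribution specs (`dist` in
#'   `"beta"`, `"gamma"`, `"normal"`, `"fixed"`; `mean`; `sd`), keyed by
#'   parameter path; default [default_psa_distributions()].
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param wtp willingness-to-pay for the cost-effective fraction.
#' @return object of class `cea_psa`: `draws` (data.frame `delta_effect`,
#'   `delta_cost`, `icer`), `ce_fraction`, `n_capped`, `wtp`.
#' @export
psa <- function(model, distributions = default_psa_distributions(model),
                n_draws = 1000, seed = NULL, wtp = model$wtp) {
  stopifnot(inherits(model, "markov_cea"), n_draws >= 1)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n_capped <- 0L
  draw_mat <- matrix(NA_real_, n_draws, length(distributions),
                     dimnames = list(NULL, names(distributions)))
  for (path in names(distributions)) {
    rng <- resolve_path(path)$range
    x <- sample_param(distributions[[path]], n_draws)
    for (tries in seq_len(100)) {
      bad <- x < rng[1] | x > rng[2]
      if (!any(bad)) break
      x[bad] <- sample_param(distributions[[path]], sum(bad))
    }
    bad <- x < rng[1] | x > rng[2]
    if (any(bad)) {
      n_capped <- n_capped + sum(bad)
      x <- pmin(pmax(x, rng[1]), rng[2])
    }
    draw_mat[, path] <- x
  }
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    m <- model
    for (path in colnames(draw_mat)) m <- set_path(m, path, draw_mat[i, path])
    fit <- markov_cea(m$intervention, m$comparator, m$econ, m$life_table, wtp)
    rows[[i]] <- data.frame(delta_effect = fit$result$delta_effect,
                            delta_cost = fit$result$delta_cost,
                            icer = fit$result$icer)
  }
  draws <- do.call(rbind, rows)
  structure(list(draws = draws,
                 ce_fraction = mean(nmb(draws$delta_cost, draws$delta_effect,
                                        wtp) > 0),
                 n_capped = n_capped, wtp = wtp),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis: ", nrow(x$draws), " draws\n", sep = "")
  cat(sprintf("  cost-effective fraction at WTP %.0f: %.3f (%d capped draws)\n",
              x$wtp, x$ce_fraction, x$n_capped))
  invisible(x)
}

#' @export
plot.cea_psa <- function(x, ...) plot(ce_plane(x, x$wtp), ...)
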