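# Monte Carlo layer: log-normal uncertainty on concentrations, body weight,
# and inhalation rate, propagated through the deterministic risk engine;
# percentile summaries, exceedance probabilities, and Spearman rank-
# correlation sensitivity.

#' Build the default Monte Carlo input specification
#'
#' The varied inputs are the per-metal dust concentration (log-normal fitted
#' to the pooled sample mean/SD via [fit_lognormal()]) and, per population,
#' body weight and inhalation rate (log-normal around the registry value
#' with fixed coefficients of variation). All other exposure parameters are
#' held at their registry values. Truncating concentrations to the observed
#' sample range is optional and off by default.
#'
#' @param samples A dust sample tibble; concentrations are pooled across
#'   zones (per-zone simulation: filter the samples first).
#' @param registry A `dust_registry`.
#' @param bw_cv,inhr_cv Coefficients of variation for body weight and
#'   inhalation rate (defaults 0.15 and 0.2).
#' @param truncate_to_range Truncate concentration draws to the observed
#'   per-metal sample range.
#' @return A tibble `variable, family, mean, sd, lower, upper`.
#' @export
mc_default_specs <- function(samples, registry = default_registry(),
                             bw_cv = 0.15, inhr_cv = 0.2,
                             truncate_to_range = FALSE) {
  metals <- intersect(dust_metals, names(samples))
  conc <- purrr::map_dfr(metals, function(m) {
    v <- samples[[m]]
    tibble::tibble(
      variable = paste0("conc_", m), family = "lognormal",
      mean = mean(v), sd = sd(v),
      lower = if (truncate_to_range) min(v) else NA_real_,
      upper = if (truncate_to_range) max(v) else NA_real_
    )
  })
  pops <- purrr::map_dfr(dust_populations, function(pop) {
    p <- exposure_params(registry, pop)
    tibble::tibble(
      variable = c(paste0("BW_", pop), paste0("InhR_", pop)),
      family = "lognormal",
      mean = c(p$BW, p$InhR),
      sd = c(p$BW * bw_cv, p$InhR * inhr_cv),
      lower = NA_real_, upper = NA_real_
    )
  })
  dplyr::bind_rows(conc, pops)
}

# Stable per-variable seed so adding a variable does not perturb the others.
variable_seed <- function(master_seed, variable) {
  h <- sum(utf8ToInt(variable) * seq_along(utf8ToInt(variable)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

draw_variable <- function(spec_row, iterations, master_seed) {
  set.seed(variable_seed(master_seed, spec_row$variable))
  if (spec_row$family == "point" || spec_row$sd == 0) {
    return(rep(spec_row$mean, iterations))
  }
  fit <- fit_lognormal(spec_row$mean, spec_row$sd)
  if (is.na(spec_row$lower) || is.na(spec_row$upper)) {
    stats::rlnorm(iterations, fit[["meanlog"]], fit[["sdlog"]])
  } else {
    rtrunc_lnorm(iterations, fit[["meanlog"]], fit[["sdlog"]],
                 spec_row$lower, spec_row$upper, label = spec_row$variable)
  }
}

#' Run the Monte Carlo risk simulation
#'
#' Each iteration draws all varied inputs independently (one reproducible
#' substream per variable derived from the master seed), evaluates the full
#' dose-risk chain with the same equations as [compute_risk()], and records
#' the hazard index and total cancer risk per population. With all spreads
#' at zero every draw equals the deterministic result exactly.
#'
#' @param specs Input specification tibble (see [mc_default_specs()]).
#' @param registry A `dust_registry`.
#' @param ba A tibble `metal, ba` for the bioaccessible scenario, or `NULL`
#'   for total content.
#' @param iterations Number of iterations (default 10000).
#' @param seed Master seed (required).
#' @param populations Populations to simulate.
#' @param include_pef Passed to [ladd()].
#' @return A `dust_mc` object; see [tidy.dust_mc()], [exceedance()],
#'   [mc_percentile()], [sensitivity()].
#' @examples
#' s <- generate_samples(seed = 1)
#' sim <- run_simulation(mc_default_specs(s), iterations = 200, seed = 1)
#' tidy(sim)
#' @export
run_simulation <- function(specs, registry = default_registry(), ba = NULL,
                           iterations = 10000, seed,
                           populations = dust_populations,
                           include_pef = FALSE) {
  if (missing(seed)) {
    abort("An explicit `seed` is required.", class = "roaddust_config_error")
  }
  stopifnot(inherits(registry, "dust_registry"), iterations >= 1)
  conc_vars <- specs$variable[startsWith(specs$variable, "conc_")]
  metals <- sub("^conc_", "", conc_vars)
  assert_metal(metals)

  draws <- purrr::map(seq_len(nrow(specs)), function(i) {
    draw_variable(specs[i, ], iterations, seed)
  })
  names(draws) <- specs$variable
  bad <- names(draws)[!purrr::map_lgl(draws, ~ all(is.finite(.x)))]
  if (length(bad) > 0) {
    abort(sprintf("Non-finite draws for variable(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "roaddust_domain_error")
  }

  ba_tab <- if (is.null(ba)) {
    setNames(rep(1, length(metals)), metals)
  } else {
    v <- setNames(rep(1, length(metals)), metals)
    v[ba$metal[ba$metal %in% metals]] <-
      ba$ba[ba$metal %in% metals]
    v
  }

  out <- purrr::map_dfr(populations, function(pop) {
    p <- exposure_params(registry, pop)
    bw_var <- paste0("BW_", pop); inhr_var <- paste0("InhR_", pop)
    if (bw_var %in% names(draws)) p$BW <- draws[[bw_var]]
    if (inhr_var %in% names(draws)) p$InhR <- draws[[inhr_var]]
    hi_draws <- numeric(iterations)
    tcr_draws <- numeric(iterations)
    for (m in metals) {
      cvec <- draws[[paste0("conc_", m)]]
      bam <- ba_tab[[m]]
      for (route in dust_routes) {
        add <- switch(route,
                      ingestion = add_ingestion(cvec, bam, p),
                      inhalation = add_inhalation(cvec, p),
                      dermal = add_dermal(cvec, p))
        rfd <- rfd_value(registry, m, route)
        if (!is.na(rfd)) hi_draws <- hi_draws + add / rfd
        if (m %in% dust_carcinogens) {
          sf <- sf_value(registry, m, route)
          if (!is.na(sf)) {
            tcr_draws <- tcr_draws +
              ladd(cvec, bam, p, route, include_pef = include_pef) * sf
          }
        }
      }
    }
    tibble::tibble(iteration = seq_len(iterations), population = pop,
                   hi = hi_draws, tcr = tcr_draws)
  })

  structure(
    list(draws = out, inputs = tibble::as_tibble(draws),
         specs = specs, iterations = iterations, seed = seed,
         populations = populations,
         scenario = if (is.null(ba)) "total" else "bioaccessible"),
    class = "dust_mc"
  )
}

#' @export
print.dust_mc <- function(x, ...) {
  cat(sprintf("<dust_mc> %d iterations, seed %s, scenario: %s\n",
              x$iterations, format(x$seed), x$scenario))
  print(tidy(x))
  invisible(x)
}

#' Percentile summary of a simulation
#'
#' One row per population and output (`hi`, `tcr`) with mean, SD, and the
#' 5th/50th/95th percentiles (type-7 quantiles).
#'
#' @param x A `dust_mc` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy dust_mc
tidy.dust_mc <- function(x, ...) {
  x$draws |>
    tidyr::pivot_longer(c("hi", "tcr"), names_to = "output",
                        values_to = "value") |>
    dplyr::group_by(.data$population, .data$output) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = sd(.data$value),
      p5 = quantile(.data$value, 0.05, names = FALSE),
      p50 = quantile(.data$value, 0.50, names = FALSE),
      p95 = quantile(.data$value, 0.95, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(scenario = x$scenario, .before = 1)
}

#' @export
#' @method glance dust_mc
glance.dust_mc <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, seed = x$seed,
                 scenario = x$scenario,
                 populations = length(x$populations),
                 variables = nrow(x$specs))
}

#' Exceedance probability
#'
#' Fraction of draws strictly above a threshold (e.g. 1 for the hazard
#' index, 1e-6 or 1e-4 for cancer risk).
#'
#' @param sim A `dust_mc` object.
#' @param threshold Threshold value.
#' @param output `"hi"` or `"tcr"`.
#' @param population A single population, or `NULL` for all.
#' @return A tibble `population, output, threshold, probability`.
#' @export
exceedance <- function(sim, threshold, output = c("hi", "tcr"),
                       population = NULL) {
  stopifnot(inherits(sim, "dust_mc"))
  output <- match.arg(output)
  d <- sim$draws
  if (!is.null(population)) d <- dplyr::filter(d, .data$population %in% .env$population)
  d |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(probability = mean(.data[[output]] > threshold),
                     .groups = "drop") |>
    dplyr::mutate(output = output, threshold = threshold,
                  .after = "population")
}

#' Empirical quantile of a simulation output
#'
#' Type-7 (linear interpolation) quantiles, the fixed convention of the
#' package.
#'
#' @inheritParams exceedance
#' @param q Probability level(s) in `[0, 1]`.
#' @return A tibble `population, output, q, value`.
#' @export
mc_percentile <- function(sim, q, output = c("hi", "tcr"), population = NULL) {
  stopifnot(inherits(sim, "dust_mc"))
  output <- match.arg(output)
  d <- sim$draws
  if (!is.null(population)) d <- dplyr::filter(d, .data$population %in% .env$population)
  d |>
    dplyr::group_by(.data$population) |>
    dplyr::reframe(q = q,
                   value = quantile(.data[[output]], q, names = FALSE, type = 7)) |>
    dplyr::mutate(output = output, .after = "population")
}

#' Rank-correlation sensitivity of the simulation output
#'
#' Spearman rank correlation between each varied input's draws and the
#' output draws, sorted by absolute value. Point-mass inputs have undefined
#' correlation and are reported as 0 with `degenerate = TRUE`.
#'
#' @inheritParams exceedance
#' @param population Population whose output to correlate against.
#' @return A tibble `variable, rho, degenerate`.
#' @export
sensitivity <- function(sim, output = c("hi", "tcr"),
                        population = "children") {
  stopifnot(inherits(sim, "dust_mc"))
  output <- match.arg(output)
  y <- sim$draws[[output]][sim$draws$population == population]
  if (length(y) == 0) {
    abort(sprintf("No draws for population `%s`.", population),
          class = "roaddust_validation_error")
  }
  purrr::map_dfr(names(sim$inputs), function(v) {
    xvec <- sim$inputs[[v]]
    degenerate <- sd(xvec) == 0 || sd(y) == 0
    rho <- if (degenerate) 0 else cor(xvec, y, method = "spearman")
    tibble::tibble(variable = v, rho = rho, degenerate = degenerate)
  }) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho)))
}
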