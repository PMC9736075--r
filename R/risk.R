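# USEPA-style dose and risk equations with bioaccessibility adjustment.
# Bioaccessibility enters the ingestion route only; inhaled particles and
# dust-on-skin doses use the total concentration.

#' Average daily dose, ingestion route
#'
#' `ADD_ing = C x BA x IngR x EF x ED / (BW x AT_nc) x 1e-6`, in mg metal per
#' kg body weight per day. The `1e-6` converts mg/kg dust to mg/mg.
#'
#' @param c Dust concentration, mg/kg. Vectorised.
#' @param ba Bioaccessible fraction in `[0, 1]`.
#' @param p Exposure parameter list (see [exposure_params()]).
#' @return Dose in mg/kg/day.
#' @export
add_ingestion <- function(c, ba, p) {
  assert_nonnegative(c, "c")
  if (any(ba < 0 | ba > 1)) {
    abort("`ba` must lie in [0, 1].", class = "roaddust_domain_error")
  }
  c * ba * p$IngR * p$EF * p$ED / (p$BW * p$AT_nc) * 1e-6
}

#' Average daily dose, inhalation route
#'
#' `ADD_inh = C x InhR x EF x ED / (PEF x BW x AT_nc)`; the particle emission
#' factor PEF (m^3/kg) converts the dust concentration to an airborne one,
#' so no mg-to-kg factor is needed.
#'
#' @inheritParams add_ingestion
#' @return Dose in mg/kg/day.
#' @export
add_inhalation <- function(c, p) {
  assert_nonnegative(c, "c")
  c * p$InhR * p$EF * p$ED / (p$PEF * p$BW * p$AT_nc)
}

#' Average daily dose, dermal route
#'
#' `ADD_dermal = C x AF x SA x ABS x EF x ED / (BW x AT_nc) x 1e-6`.
#'
#' @inheritParams add_ingestion
#' @return Dose in mg/kg/day.
#' @export
add_dermal <- function(c, p) {
  assert_nonnegative(c, "c")
  c * p$AF * p$SA * p$ABS * p$EF * p$ED / (p$BW * p$AT_nc) * 1e-6
}

#' Lifetime average daily dose for one population
#'
#' Carcinogenic doses average the exposure over a 70-year lifetime
#' (`AT_ca`). The per-population bracket is `IngR x ED / BW` (ingestion),
#' `InhR x ED / BW` (inhalation, divided by PEF), or `AF x SA x ED / BW`
#' times ABS (dermal). Bioaccessibility applies to ingestion only.
#'
#' @inheritParams add_ingestion
#' @param route One of `"ingestion"`, `"inhalation"`, `"dermal"`.
#' @param include_pef Divide the ingestion dose by PEF as well. Off by
#'   default: PEF is a particle-emission factor belonging to the inhalation
#'   route, and including it in ingestion suppresses the cancer risk by ~9
#'   orders of magnitude relative to reported urban-dust values.
#' @return Dose in mg/kg/day.
#' @export
ladd <- function(c, ba, p, route = dust_routes, include_pef = FALSE) {
  route <- match.arg(route)
  assert_nonnegative(c, "c")
  base <- c * p$EF / p$AT_ca
  switch(route,
    ingestion = {
      d <- base * ba * (p$IngR * p$ED / p$BW) * 1e-6
      if (include_pef) d / p$PEF else d
    },
    inhalation = base / p$PEF * (p$InhR * p$ED / p$BW),
    dermal = base * p$ABS * (p$AF * p$SA * p$ED / p$BW) * 1e-6
  )
}

#' Two-life-stage lifetime average daily dose
#'
#' The combined childhood + adulthood form: the bracket sums
#' `IngR_child x ED_child / BW_child + IngR_adult x ED_adult / BW_adult`
#' (analogously for the other routes). Used when a single lifetime receptor
#' integrating both life stages is wanted rather than the per-population
#' tables.
#'
#' @inheritParams ladd
#' @param p_child,p_adult Exposure parameter lists for the two life stages.
#' @return Dose in mg/kg/day.
#' @export
ladd_lifetime <- function(c, ba, p_child, p_adult, route = dust_routes,
                          include_pef = FALSE) {
  route <- match.arg(route)
  assert_nonnegative(c, "c")
  at <- p_child$AT_ca
  ef <- p_child$EF
  bracket <- function(f) f(p_child) + f(p_adult)
  switch(route,
    ingestion = {
      d <- c * ba * ef / at * bracket(function(p) p$IngR * p$ED / p$BW) * 1e-6
      if (include_pef) d / p_child$PEF else d
    },
    inhalation = c * ef / (at * p_child$PEF) *
      bracket(function(p) p$InhR * p$ED / p$BW),
    dermal = c * ef * p_child$ABS / at *
      bracket(function(p) p$AF * p$SA * p$ED / p$BW) * 1e-6
  )
}

#' Hazard quotient and hazard index
#'
#' `hq = add / rfd`; the hazard index sums hazard quotients over routes and
#' metals. `HI > 1` flags possible noncarcinogenic effects.
#'
#' @param add Dose, mg/kg/day.
#' @param rfd Reference dose, mg/kg/day (> 0).
#' @return Unitless quotients.
#' @export
hq <- function(add, rfd) {
  assert_nonnegative(add, "add")
  assert_positive(rfd, "rfd")
  add / rfd
}

#' @param hqs Numeric vector of hazard quotients.
#' @rdname hq
#' @export
hi <- function(hqs) sum(hqs)

#' Incremental cancer risk and total cancer risk
#'
#' `cr = ladd x sf`; the total cancer risk sums over routes with a
#' configured slope factor and over the carcinogenic metals.
#'
#' @param ladd Lifetime dose, mg/kg/day.
#' @param sf Slope factor, (mg/kg/day)^-1.
#' @return Unitless risks.
#' @export
cr <- function(ladd, sf) {
  assert_nonnegative(ladd, "ladd")
  assert_nonnegative(sf, "sf")
  ladd * sf
}

#' @param crs Numeric vector of incremental risks.
#' @rdname cr
#' @export
tcr <- function(crs) sum(crs)

#' Advisory labels for hazard index and cancer risk
#'
#' `HI > 1` signals possible noncarcinogenic effects. Cancer risk below
#' `1e-6` is negligible (acceptable), above `1e-4` unacceptable, in between
#' tolerable.
#'
#' @param hi Hazard index values. Vectorised.
#' @param cr Cancer risk values. Vectorised.
#' @return For `classify_hi`, a factor `negligible | concern`; for
#'   `classify_cr`, a factor `negligible | tolerable | unacceptable`.
#' @export
classify_hi <- function(hi) {
  factor(ifelse(hi > 1, "noncarcinogenic concern", "negligible"),
         levels = c("negligible", "noncarcinogenic concern"))
}

#' @rdname classify_hi
#' @export
classify_cr <- function(cr) {
  cut(cr, breaks = c(-Inf, 1e-6, 1e-4, Inf),
      labels = c("negligible", "tolerable", "unacceptable"),
      right = FALSE, ordered_result = TRUE)
}

#' Deterministic risk assessment over metals, routes, and populations
#'
#' Evaluates the full dose-risk chain for a vector of representative dust
#' concentrations: per-route average daily doses and hazard quotients for
#' all metals with a configured RfD, and per-route lifetime doses and cancer
#' risks for the carcinogenic metals with a configured slope factor (routes
#' without an SF contribute zero).
#'
#' @param conc A tibble `metal, concentration` (mg/kg), e.g. per-metal means
#'   of a sample table.
#' @param registry A `dust_registry`.
#' @param ba A tibble `metal, ba`, e.g. from [ba_table()]; `NULL` means the
#'   total-content scenario (BA = 1 everywhere).
#' @param populations Populations to assess.
#' @param include_pef Passed to [ladd()].
#' @return A `dust_risk` object: a tibble `population, metal, route, add,
#'   ladd, hq, cr` with the scenario recorded in attributes. Use
#'   [risk_summary()], [tidy()] or [glance()] on it.
#' @examples
#' s <- generate_samples(seed = 1)
#' conc <- dplyr::summarise(tidyr::pivot_longer(s, As:V, names_to = "metal",
#'   values_to = "conc"), concentration = mean(conc), .by = metal)
#' r <- compute_risk(conc, default_registry())
#' risk_summary(r)
#' @export
compute_risk <- function(conc, registry = default_registry(), ba = NULL,
                         populations = dust_populations, include_pef = FALSE) {
  stopifnot(inherits(registry, "dust_registry"))
  stopifnot(all(c("metal", "concentration") %in% names(conc)))
  assert_metal(unique(conc$metal))
  assert_nonnegative(conc$concentration, "concentration")
  ba_tab <- if (is.null(ba)) {
    tibble::tibble(metal = conc$metal, ba = 1)
  } else {
    stopifnot(all(c("metal", "ba") %in% names(ba)))
    ba
  }
  grid <- tidyr::expand_grid(
    population = populations,
    metal = conc$metal,
    route = dust_routes
  ) |>
    dplyr::left_join(conc, by = "metal") |>
    dplyr::left_join(ba_tab, by = "metal") |>
    dplyr::mutate(ba = dplyr::coalesce(.data$ba, 1))

  rows <- purrr::pmap(grid, function(population, metal, route, concentration, ba) {
    p <- exposure_params(registry, population)
    add <- switch(route,
                  ingestion = add_ingestion(concentration, ba, p),
                  inhalation = add_inhalation(concentration, p),
                  dermal = add_dermal(concentration, p))
    rfd <- rfd_value(registry, metal, route)
    hq_val <- if (is.na(rfd)) 0 else hq(add, rfd)
    if (metal %in% dust_carcinogens) {
      ladd_val <- ladd(concentration, ba, p, route, include_pef = include_pef)
      sf <- sf_value(registry, metal, route)
      cr_val <- if (is.na(sf)) 0 else cr(ladd_val, sf)
    } else {
      ladd_val <- NA_real_
      cr_val <- 0
    }
    tibble::tibble(add = add, ladd = ladd_val, hq = hq_val, cr = cr_val)
  })
  out <- dplyr::bind_cols(grid[, c("population", "metal", "route")],
                          dplyr::bind_rows(rows))
  structure(out,
            class = c("dust_risk", class(out)),
            scenario = if (is.null(ba)) "total" else "bioaccessible",
            include_pef = include_pef)
}

#' Per-population risk summary
#'
#' Hazard index (sum of all hazard quotients), total cancer risk (sum over
#' carcinogens and routes), advisory labels, and the top-contributing metal
#' for each.
#'
#' @param risk A `dust_risk` object from [compute_risk()].
#' @return A tibble `population, hi, hi_class, top_hi_metal, tcr, cr_class,
#'   top_tcr_metal`.
#' @export
risk_summary <- function(risk) {
  stopifnot(inherits(risk, "dust_risk"))
  by_metal <- risk_contributions(risk)
  top <- by_metal |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      top_hi_metal = .data$metal[which.max(.data$hq)],
      top_tcr_metal = .data$metal[which.max(.data$cr)],
      .groups = "drop"
    )
  risk |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(hi = sum(.data$hq), tcr = sum(.data$cr), .groups = "drop") |>
    dplyr::mutate(hi_class = classify_hi(.data$hi),
                  cr_class = classify_cr(.data$tcr)) |>
    dplyr::left_join(top, by = "population")
}

#' Per-metal contribution to hazard index and total cancer risk
#'
#' @inheritParams risk_summary
#' @return A tibble `population, metal, hq, cr, hi_share, tcr_share`;
#'   shares sum to 1 within each population.
#' @export
risk_contributions <- function(risk) {
  stopifnot(inherits(risk, "dust_risk"))
  risk |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$population, .data$metal) |>
    dplyr::summarise(hq = sum(.data$hq), cr = sum(.data$cr), .groups = "drop") |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(hi_share = .data$hq / sum(.data$hq),
                  tcr_share = if (sum(.data$cr) > 0) .data$cr / sum(.data$cr) else 0) |>
    dplyr::ungroup()
}

#' @export
#' @method tidy dust_risk
tidy.dust_risk <- function(x, ...) tibble::as_tibble(x)

#' @export
#' @method glance dust_risk
glance.dust_risk <- function(x, ...) {
  s <- risk_summary(x)
  s$scenario <- attr(x, "scenario")
  s[, c("scenario", setdiff(names(s), "scenario"))]
}
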