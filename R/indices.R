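# Contamination and ecological-risk indices: geoaccumulation index (Igeo),
# improved Nemerow index (INI), Hakanson single-metal risk (Er) and potential
# ecological risk index (RI), and simple enrichment ratios.

#' Geoaccumulation index
#'
#' `Igeo = log2(c / (1.5 * b))`, where `c` is the measured concentration,
#' `b` the geochemical background, and the factor 1.5 absorbs natural
#' lithologic variation in the background. A zero concentration returns
#' `-Inf` with a warning.
#'
#' @param c Measured concentration (mg/kg), nonnegative. Vectorised.
#' @param b Background concentration (mg/kg), strictly positive.
#' @return Unitless index values.
#' @examples
#' igeo(640, 47.3)   # ~3.17: heavily polluted
#' @export
igeo <- function(c, b) {
  assert_nonnegative(c, "c")
  if (any(!is.finite(b) | b <= 0)) {
    abort("Background `b` must be strictly positive.",
          class = "roaddust_domain_error")
  }
  if (any(c == 0)) {
    warn("Zero concentration: Igeo reported as -Inf.")
  }
  log2(c / (1.5 * b))
}

#' Classify a geoaccumulation index (seven-class scheme)
#'
#' Half-open bins at 0, 1, 2, 3, 4, 5: class 0 (unpolluted, `Igeo <= 0`)
#' through class 6 (extremely contaminated, `Igeo > 5`).
#'
#' @param igeo Index values (finite or `-Inf`). Vectorised.
#' @return An ordered factor of class labels, with the numeric class in
#'   `as.integer()` minus 1.
#' @export
classify_igeo <- function(igeo) {
  labels <- c(
    "unpolluted",
    "unpolluted to moderately polluted",
    "moderately polluted",
    "moderately to heavily polluted",
    "heavily polluted",
    "heavily to extremely polluted",
    "extremely polluted"
  )
  cls <- pmin(pmax(floor(igeo), -1) + 1, 6)
  cls[igeo <= 0] <- 0
  factor(labels[cls + 1], levels = labels, ordered = TRUE)
}

#' Improved Nemerow index
#'
#' Aggregates the per-metal geoaccumulation indices of one sample into a
#' single contamination score: `INI = sqrt((Igeo_max^2 + Igeo_avg^2) / 2)`.
#'
#' @param igeo_values Nonempty numeric vector of per-metal Igeo values.
#' @return A single unitless value.
#' @examples
#' ini(c(1, 2, 3))   # sqrt((9 + 4) / 2)
#' @export
ini <- function(igeo_values) {
  igeo_values <- igeo_values[!is.na(igeo_values)]
  if (length(igeo_values) == 0 || !any(is.finite(igeo_values))) {
    abort("`igeo_values` must contain at least one finite value.",
          class = "roaddust_domain_error")
  }
  sqrt((max(igeo_values)^2 + mean(igeo_values)^2) / 2)
}

#' Classify an improved Nemerow index
#'
#' Half-open bins with cut points 1, 2, 3, 4, 5.
#'
#' @param ini Index values (>= 0). Vectorised.
#' @return An ordered factor of class labels.
#' @export
classify_ini <- function(ini) {
  labels <- c(
    "unpolluted",
    "slightly to moderately contaminated",
    "moderately to heavily contaminated",
    "heavily contaminated",
    "heavily to extremely contaminated",
    "extremely contaminated"
  )
  cut(ini, breaks = c(-Inf, 1, 2, 3, 4, 5, Inf), labels = labels,
      right = FALSE, ordered_result = TRUE)
}

#' Single-metal ecological risk and potential ecological risk index
#'
#' `er = tr * c / b` is the Hakanson single-metal risk (toxicity coefficient
#' times contamination factor); `ri` sums `er` over metals.
#'
#' @param c Measured concentration (mg/kg), nonnegative. Vectorised.
#' @param b Background concentration (mg/kg), strictly positive.
#' @param tr Toxicity response coefficient, strictly positive.
#' @return Unitless risk values.
#' @examples
#' er(0.74, 0.06, 30)   # Cd: 370
#' @export
er <- function(c, b, tr) {
  assert_nonnegative(c, "c")
  assert_positive(b, "b")
  assert_positive(tr, "tr")
  tr * c / b
}

#' @param er_values Named numeric vector of per-metal Er values. Unless
#'   `subset = TRUE`, all eight metals must be present.
#' @param subset Allow summation over an explicit subset of metals.
#' @rdname er
#' @export
ri <- function(er_values, subset = FALSE) {
  if (!subset) {
    missing <- setdiff(dust_metals, names(er_values))
    if (length(missing) > 0) {
      abort(sprintf(
        "RI requires all eight metals (missing: %s); use `subset = TRUE` for a partial sum.",
        paste(missing, collapse = ", ")), class = "roaddust_validation_error")
    }
  }
  sum(er_values)
}

#' Classify a potential ecological risk index
#'
#' Half-open bins: `[0, 150)` low, `[150, 300)` moderate, `[300, 600)`
#' considerable, `[600, Inf)` high.
#'
#' @param ri Index values (>= 0). Vectorised.
#' @return An ordered factor of class labels.
#' @export
classify_ri <- function(ri) {
  assert_nonnegative(ri, "ri")
  cut(ri, breaks = c(-Inf, 150, 300, 600, Inf),
      labels = c("low", "moderate", "considerable", "high"),
      right = FALSE, ordered_result = TRUE)
}

#' Classify a single-metal ecological risk (Er)
#'
#' Standard Hakanson cuts at 40, 80, 160, 320.
#'
#' @param er Er values (>= 0). Vectorised.
#' @return An ordered factor of class labels.
#' @export
classify_er <- function(er) {
  assert_nonnegative(er, "er")
  cut(er, breaks = c(-Inf, 40, 80, 160, 320, Inf),
      labels = c("low", "moderate", "considerable", "high", "very high"),
      right = FALSE, ordered_result = TRUE)
}

#' Enrichment ratio over background
#'
#' The plain concentration-to-background ratio `c / b` (the contamination
#' factor of the ecological-risk index).
#'
#' @inheritParams igeo
#' @return Unitless ratios.
#' @export
enrichment_ratio <- function(c, b) {
  assert_nonnegative(c, "c")
  assert_positive(b, "b")
  c / b
}

#' Per-sample contamination and ecological-risk indices
#'
#' Computes, for every sample, the per-metal geoaccumulation index and
#' single-metal risk, the improved Nemerow index over the metals present,
#' the potential ecological risk index, and their class labels.
#'
#' @param samples A dust sample tibble.
#' @param registry A `dust_registry` supplying background values and
#'   toxicity coefficients.
#' @return A tibble with one row per sample: `sample_id, zone,
#'   igeo_<metal>..., ini, ini_class, er_<metal>..., ri, ri_class`.
#' @examples
#' s <- generate_samples(seed = 1)
#' head(assess_contamination(s, default_registry()))
#' @export
assess_contamination <- function(samples, registry = default_registry()) {
  stopifnot(inherits(registry, "dust_registry"))
  metals <- intersect(dust_metals, names(samples))
  out <- samples[, c("sample_id", "zone")]
  for (m in metals) {
    b <- registry$background[[m]]
    tr <- registry$toxicity[[m]]
    out[[paste0("igeo_", m)]] <- igeo(samples[[m]], b)
    out[[paste0("er_", m)]] <- er(samples[[m]], b, tr)
  }
  igeo_mat <- as.matrix(out[, paste0("igeo_", metals), drop = FALSE])
  er_mat <- as.matrix(out[, paste0("er_", metals), drop = FALSE])
  out$ini <- apply(igeo_mat, 1, ini)
  out$ini_class <- classify_ini(out$ini)
  out$ri <- rowSums(er_mat)
  out$ri_class <- classify_ri(out$ri)
  tibble::as_tibble(out)
}
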