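# Sequential-extraction bookkeeping: residual pool by subtraction from the
# pseudo-total, percentage profiles, and mobility summaries. Only the mass
# accounting is modelled, not the extraction chemistry.

#' Residual fraction by subtraction
#'
#' The residual pool is defined by difference from the pseudo-total digest:
#' `f5 = max(total - (f1 + f2 + f3 + f4), 0)`. Analytical over-recovery
#' (extracted pools exceeding the pseudo-total) is clamped to zero and
#' flagged rather than renormalised, preserving the subtraction definition.
#'
#' @param total Pseudo-total concentration (mg/kg). Vectorised.
#' @param f1,f2,f3,f4 Measured pool concentrations (mg/kg), nonnegative.
#' @return A tibble with columns `f5` and `clamped` (and `raw_f5`, the
#'   unclamped difference, for audit).
#' @export
residual_fraction <- function(total, f1, f2, f3, f4) {
  assert_nonnegative(total, "total")
  assert_nonnegative(f1, "f1"); assert_nonnegative(f2, "f2")
  assert_nonnegative(f3, "f3"); assert_nonnegative(f4, "f4")
  raw <- total - (f1 + f2 + f3 + f4)
  tibble::tibble(f5 = pmax(raw, 0), clamped = raw < 0, raw_f5 = raw)
}

#' Complete sequential-extraction records
#'
#' Takes measured records (`sample_id, metal, total, f1, f2, f3, f4`),
#' derives the residual pool F5, and appends percentage shares of each pool.
#' Shares use the reconstructed sum `f1 + ... + f5` as denominator so they
#' always total 100%, including for clamped (over-recovered) records.
#'
#' @param records A tibble in the speciation input dialect (e.g. from
#'   [generate_speciation()] or `readr::read_csv()`).
#' @return The input plus `f5, clamped, pct_f1 ... pct_f5`.
#' @export
speciate <- function(records) {
  needed <- c("sample_id", "metal", "total", "f1", "f2", "f3", "f4")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) {
    abort(sprintf("Speciation records lack column(s): %s.",
                  paste(miss, collapse = ", ")),
          class = "roaddust_schema_error")
  }
  assert_metal(unique(records$metal))
  res <- residual_fraction(records$total, records$f1, records$f2,
                           records$f3, records$f4)
  out <- dplyr::bind_cols(tibble::as_tibble(records),
                          res[, c("f5", "clamped")])
  denom <- out$f1 + out$f2 + out$f3 + out$f4 + out$f5
  if (any(denom == 0)) {
    abort("Percentage shares undefined for records with zero total mass.",
          class = "roaddust_domain_error")
  }
  for (k in 1:5) {
    fk <- paste0("f", k)
    out[[paste0("pct_", fk)]] <- out[[fk]] / denom * 100
  }
  out
}

#' Percentage profile of one speciation record
#'
#' @param f1,f2,f3,f4,f5 Pool concentrations (mg/kg).
#' @return A named numeric vector of five shares summing to 100.
#' @export
fraction_percentages <- function(f1, f2, f3, f4, f5) {
  total <- f1 + f2 + f3 + f4 + f5
  if (total <= 0) {
    abort("Shares are undefined when all pools are zero.",
          class = "roaddust_domain_error")
  }
  c(pct_f1 = f1, pct_f2 = f2, pct_f3 = f3, pct_f4 = f4, pct_f5 = f5) / total * 100
}

#' Per-metal mobility summary
#'
#' Mean percentage share of each pool per metal, the mean mobile share
#' (exchangeable + carbonate-bound, F1 + F2), and the dominant pool.
#'
#' @param records Completed speciation records (from [speciate()]).
#' @return A tibble `metal, pct_f1 ... pct_f5, mobile_pct, dominant_fraction`.
#' @export
mobility_summary <- function(records) {
  if (!"pct_f1" %in% names(records)) records <- speciate(records)
  pool_names <- c(
    pct_f1 = "exchangeable",
    pct_f2 = "carbonate-bound",
    pct_f3 = "Fe/Mn oxide",
    pct_f4 = "organic/sulfide",
    pct_f5 = "residual"
  )
  records |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(names(pool_names)), mean),
                     .groups = "drop") |>
    dplyr::mutate(
      mobile_pct = .data$pct_f1 + .data$pct_f2,
      dominant_fraction = unname(pool_names[
        names(pool_names)[max.col(dplyr::pick(dplyr::all_of(names(pool_names))))]
      ])
    ) |>
    dplyr::arrange(match(.data$metal, dust_metals))
}
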