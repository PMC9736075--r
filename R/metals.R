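#' The eight trace metals tracked by the pipeline
#'
#' All analyses operate on this closed set of elements, in this canonical
#' order. Unknown metal symbols are rejected at parse time.
#'
#' @format A character vector of length 8.
#' @export
dust_metals <- c("As", "Cd", "Cr", "Pb", "Cu", "Zn", "Ni", "V")

#' Functional-zone labels recognised for dust samples
#'
#' @format A character vector of length 3.
#' @export
dust_zones <- c("industrial", "traffic", "agricultural")

#' Metals treated as carcinogens in the cancer-risk summation
#'
#' Incremental lifetime cancer risk is summed over these five elements;
#' the remaining metals contribute to the noncarcinogenic hazard index only.
#'
#' @format A character vector of length 5.
#' @export
dust_carcinogens <- c("As", "Pb", "Ni", "Cr", "Cd")

#' Exposure routes of the dose model
#' @format A character vector of length 3.
#' @export
dust_routes <- c("ingestion", "inhalation", "dermal")

#' Populations of the exposure model
#' @format A character vector of length 3.
#' @export
dust_populations <- c("children", "adult_women", "adult_men")

# Internal validators ---------------------------------------------------------

assert_metal <- function(metal, arg = "metal") {
  bad <- setdiff(metal, dust_metals)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown metal symbol(s) in `%s`: %s. Known metals: %s.",
      arg, paste(bad, collapse = ", "), paste(dust_metals, collapse = ", ")
    ), class = "roaddust_validation_error")
  }
  invisible(metal)
}

normalize_zone <- function(zone) {
  z <- tolower(trimws(as.character(zone)))
  # accept common synonyms seen in field sheets
  z[z %in% c("industry", "industrial park", "industrial")] <- "industrial"
  z[z %in% c("traffic road", "road", "traffic")] <- "traffic"
  z[z %in% c("agriculture", "agricultural field", "agricultural")] <- "agricultural"
  bad <- setdiff(unique(z), dust_zones)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown zone label(s): %s. Known zones: %s.",
      paste(bad, collapse = ", "), paste(dust_zones, collapse = ", ")
    ), class = "roaddust_validation_error")
  }
  factor(z, levels = dust_zones)
}

assert_positive <- function(x, arg) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite.", arg),
          class = "roaddust_domain_error")
  }
  invisible(x)
}

assert_nonnegative <- function(x, arg) {
  if (any(is.na(x) | x < 0)) {
    abort(sprintf("`%s` must be nonnegative.", arg),
          class = "roaddust_domain_error")
  }
  invisible(x)
}
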