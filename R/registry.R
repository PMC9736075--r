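#' Read a reference registry from a YAML file
#'
#' The registry bundles everything the indices and the risk engine need that
#' is not a measurement: per-metal geochemical background values (mg/kg),
#' Hakanson toxicity coefficients, route-specific reference doses (RfD,
#' mg/kg/day) and cancer slope factors (SF, (mg/kg/day)^-1), and per-population
#' exposure parameters. Registries are configuration files, never code
#' constants, so that a run can be reproduced from its logged registry.
#'
#' @param path Path to a YAML file with sections `background`, `toxicity`,
#'   `rfd`, `sf`, `exposure`.
#' @return A `dust_registry` object (a validated list).
#' @seealso [default_registry()] for the bundled defaults,
#'   [write_registry()] to save an edited registry.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Registry file not found: %s", path),
          class = "roaddust_config_error")
  }
  validate_registry(yaml::read_yaml(path))
}

#' The bundled default reference registry
#'
#' Reads the registry shipped with the package: Guangzhou soil background
#' values, the standard Hakanson toxicity coefficients (Cu 5, Cr 2, Ni 5,
#' Zn 1, Pb 5, Cd 30, As 10, V 2), USEPA-convention RfD/SF tables, and USEPA
#' default exposure parameters for children, adult women, and adult men.
#'
#' @return A `dust_registry` object.
#' @examples
#' reg <- default_registry()
#' reg$background[["Zn"]]
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "default_registry.yaml",
                            package = "roaddust", mustWork = TRUE))
}

#' Write a registry to YAML
#'
#' @param registry A `dust_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "dust_registry"))
  yaml::write_yaml(unclass(registry), path)
  invisible(path)
}

validate_registry <- function(reg) {
  for (section in c("background", "toxicity", "rfd", "sf", "exposure")) {
    if (is.null(reg[[section]])) {
      abort(sprintf("Registry is missing the `%s` section.", section),
            class = "roaddust_config_error")
    }
  }
  for (section in c("background", "toxicity")) {
    missing <- setdiff(dust_metals, names(reg[[section]]))
    if (length(missing) > 0) {
      abort(sprintf("Registry `%s` lacks metal(s): %s.",
                    section, paste(missing, collapse = ", ")),
            class = "roaddust_config_error")
    }
    vals <- unlist(reg[[section]][dust_metals])
    assert_positive(vals, section)
  }
  assert_metal(names(reg$rfd), "rfd")
  assert_metal(names(reg$sf), "sf")
  missing_pop <- setdiff(dust_populations, names(reg$exposure))
  if (length(missing_pop) > 0) {
    abort(sprintf("Registry `exposure` lacks population(s): %s.",
                  paste(missing_pop, collapse = ", ")),
          class = "roaddust_config_error")
  }
  needed <- c("IngR", "InhR", "EF", "ED", "BW", "AF", "SA", "ABS", "PEF", "AT_ca")
  for (pop in dust_populations) {
    p <- reg$exposure[[pop]]
    miss <- setdiff(needed, names(p))
    if (length(miss) > 0) {
      abort(sprintf("Exposure parameters for `%s` lack: %s.",
                    pop, paste(miss, collapse = ", ")),
            class = "roaddust_config_error")
    }
    assert_positive(unlist(p[needed]), paste0("exposure$", pop))
    if (p$ABS > 1) {
      abort(sprintf("ABS for `%s` must lie in (0, 1].", pop),
            class = "roaddust_config_error")
    }
  }
  structure(reg, class = "dust_registry")
}

#' Exposure parameters for one population
#'
#' Returns the parameter list for a population, adding the noncarcinogenic
#' averaging time `AT_nc = ED * 365` (days) unless the registry overrides it.
#'
#' @param registry A `dust_registry`.
#' @param population One of `"children"`, `"adult_women"`, `"adult_men"`.
#' @return A named list of exposure parameters.
#' @export
exposure_params <- function(registry, population) {
  stopifnot(inherits(registry, "dust_registry"))
  population <- match.arg(population, dust_populations)
  p <- registry$exposure[[population]]
  if (is.null(p$AT_nc)) p$AT_nc <- p$ED * 365
  p$population <- population
  p
}

#' Look up a reference dose or slope factor
#'
#' Routes without an established value return `NA` (the risk engine treats a
#' missing SF as zero cancer-risk contribution for that route and logs it).
#'
#' @param registry A `dust_registry`.
#' @param metal Metal symbol.
#' @param route One of `"ingestion"`, `"inhalation"`, `"dermal"`.
#' @return A single numeric, or `NA_real_` if not configured.
#' @export
rfd_value <- function(registry, metal, route) {
  lookup_tox(registry, "rfd", metal, route)
}

#' @rdname rfd_value
#' @export
sf_value <- function(registry, metal, route) {
  lookup_tox(registry, "sf", metal, route)
}

lookup_tox <- function(registry, section, metal, route) {
  stopifnot(inherits(registry, "dust_registry"))
  assert_metal(metal)
  route <- match.arg(route, dust_routes)
  v <- registry[[section]][[metal]][[route]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}

#' @export
print.dust_registry <- function(x, ...) {
  cat("<dust_registry>\n")
  cat("  background (mg/kg):",
      paste(sprintf("%s=%g", dust_metals, unlist(x$background[dust_metals])),
            collapse = " "), "\n")
  cat("  toxicity coefficients:",
      paste(sprintf("%s=%g", dust_metals, unlist(x$toxicity[dust_metals])),
            collapse = " "), "\n")
  cat("  RfD for:", paste(names(x$rfd), collapse = ", "), "\n")
  cat("  SF for:", paste(names(x$sf), collapse = ", "), "\n")
  cat("  populations:", paste(names(x$exposure), collapse = ", "), "\n")
  invisible(x)
}
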