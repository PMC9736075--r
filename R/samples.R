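#' Read a per-sample dust concentration table
#'
#' Expects a CSV with header `sample_id, zone, As, Cd, Cr, Pb, Cu, Zn, Ni, V`
#' (concentrations in mg/kg dry dust; extra columns are passed through
#' untouched). Zone labels are case-normalised to
#' `industrial | traffic | agricultural`. Missing metal columns are allowed
#' but flagged with a warning; negative or unparseable concentrations are
#' errors naming the offending cell.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per sample, `zone` as a factor, and one
#'   numeric column per metal; row order preserved.
#' @export
read_dust_samples <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Sample file not found: %s", path),
          class = "roaddust_config_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  validate_dust_samples(raw, source = path)
}

#' Validate a raw sample data frame
#'
#' Used by [read_dust_samples()] and available directly for in-memory tables.
#'
#' @param x A data frame with at least `sample_id` and `zone` columns plus
#'   metal concentration columns.
#' @param source Label used in error messages.
#' @return A validated tibble of dust samples.
#' @export
validate_dust_samples <- function(x, source = "samples") {
  x <- tibble::as_tibble(x)
  for (col in c("sample_id", "zone")) {
    if (!col %in% names(x)) {
      abort(sprintf("%s: mandatory column `%s` is missing.", source, col),
            class = "roaddust_schema_error")
    }
  }
  present <- intersect(dust_metals, names(x))
  absent <- setdiff(dust_metals, present)
  if (length(absent) > 0) {
    warn(sprintf("%s: no column for metal(s) %s; they will be absent from results.",
                 source, paste(absent, collapse = ", ")))
  }
  if (length(present) == 0) {
    abort(sprintf("%s: no metal concentration columns found.", source),
          class = "roaddust_schema_error")
  }
  for (m in present) {
    v <- x[[m]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("%s: unparseable value %s in column `%s`, row %d.",
                    source, dQuote(v[bad[1]]), m, bad[1]),
            class = "roaddust_validation_error")
    }
    neg <- which(num < 0)
    if (length(neg) > 0) {
      abort(sprintf("%s: negative concentration (%s) in column `%s`, row %d.",
                    source, v[neg[1]], m, neg[1]),
            class = "roaddust_validation_error")
    }
    x[[m]] <- num
  }
  x$zone <- normalize_zone(x$zone)
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Write a dust sample table to CSV
#'
#' Inverse of [read_dust_samples()]: `read -> write -> read` is lossless.
#'
#' @param samples A dust sample tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dust_samples <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Per-zone, per-metal summary statistics
#'
#' Reproduces the structure of a survey summary table: n, mean, sample SD
#' (n - 1 denominator), median, min, and max per zone and metal. Groups with a
#' single sample report `sd = 0` with a degenerate-group warning so the
#' summary stays total.
#'
#' @param samples A dust sample tibble (from [read_dust_samples()] or
#'   [generate_samples()]).
#' @param zones Zones to include; defaults to those present.
#' @return A tibble with columns `zone, metal, n, mean, sd, median, min, max`.
#' @export
summarize_by_zone <- function(samples, zones = NULL) {
  present <- intersect(dust_metals, names(samples))
  if (is.null(zones)) {
    zones <- as.character(unique(samples$zone))
  }
  missing_zone <- setdiff(zones, as.character(unique(samples$zone)))
  if (length(missing_zone) > 0) {
    abort(sprintf("No samples in requested zone(s): %s.",
                  paste(missing_zone, collapse = ", ")),
          class = "roaddust_validation_error")
  }
  long <- samples |>
    dplyr::filter(.data$zone %in% zones) |>
    tidyr::pivot_longer(dplyr::all_of(present),
                        names_to = "metal", values_to = "conc")
  out <- long |>
    dplyr::group_by(.data$zone, .data$metal) |>
    dplyr::summarise(
      n = sum(!is.na(.data$conc)),
      mean = mean(.data$conc, na.rm = TRUE),
      sd = if (sum(!is.na(.data$conc)) > 1) sd(.data$conc, na.rm = TRUE) else 0,
      median = median(.data$conc, na.rm = TRUE),
      min = min(.data$conc, na.rm = TRUE),
      max = max(.data$conc, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(metal = factor(.data$metal, levels = dust_metals)) |>
    dplyr::arrange(.data$zone, .data$metal)
  if (any(out$n == 1)) {
    warn("Some zone/metal groups contain a single sample; their SD is reported as 0.")
  }
  out
}
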