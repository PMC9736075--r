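# Small in-code fixtures shared across test files.

write_sample_csv <- function(path, rows = NULL) {
  header <- "sample_id,zone,As,Cd,Cr,Pb,Cu,Zn,Ni,V"
  if (is.null(rows)) {
    rows <- c(
      "S1,industrial,18.4,0.74,200,166,133,640,34.8,37.3",
      "S2,traffic,25.1,0.72,116,115,116,368,41.2,41.0",
      "S3,agricultural,19.2,0.74,55.7,219,46.9,143,15.1,41.6"
    )
  }
  writeLines(c(header, rows), path)
  path
}

# A tiny deterministic sample tibble (one per zone, Table-style values).
tiny_samples <- function() {
  validate_dust_samples(tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    zone = c("industrial", "traffic", "agricultural"),
    As = c(18.4, 25.1, 19.2), Cd = c(0.74, 0.72, 0.74),
    Cr = c(200, 116, 55.7), Pb = c(166, 115, 219),
    Cu = c(133, 116, 46.9), Zn = c(640, 368, 143),
    Ni = c(34.8, 41.2, 15.1), V = c(37.3, 41.0, 41.6)
  ))
}

# Mean concentration table in canonical metal order (stable summation order).
mean_conc <- function(samples) {
  metals <- intersect(dust_metals, names(samples))
  tibble::tibble(
    metal = metals,
    concentration = unname(vapply(metals, function(m) mean(samples[[m]]),
                                  numeric(1)))
  )
}

# A point-mass Monte Carlo spec matching a concentration table and registry.
point_specs <- function(conc, registry) {
  pops <- dust_populations
  dplyr::bind_rows(
    tibble::tibble(variable = paste0("conc_", conc$metal), family = "point",
                   mean = conc$concentration, sd = 0,
                   lower = NA_real_, upper = NA_real_),
    purrr::map_dfr(pops, function(pop) {
      p <- exposure_params(registry, pop)
      tibble::tibble(variable = c(paste0("BW_", pop), paste0("InhR_", pop)),
                     family = "point", mean = c(p$BW, p$InhR), sd = 0,
                     lower = NA_real_, upper = NA_real_)
    })
  )
}
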