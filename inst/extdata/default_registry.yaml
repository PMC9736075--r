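# Reference registry: geochemical background values, Hakanson toxicity
# coefficients, route-specific toxicological reference doses (RfD) and cancer
# slope factors (SF), and per-population exposure parameters.
#
# These are editable configuration, not code constants. Background values are
# local Guangzhou soil backgrounds (mg/kg); toxicity coefficients are the
# standard Hakanson set. RfD (mg/kg/day) and SF ((mg/kg/day)^-1) follow the
# USEPA IRIS/RSL conventions widely reused in urban-dust risk studies; routes
# with no established SF are simply omitted and contribute zero cancer risk.
# Exposure parameters follow USEPA defaults (children / adult women / adult
# men): soil ingestion rate IngR (mg/day), inhalation rate InhR (m^3/day),
# exposure frequency EF (day/year), exposure duration ED (year), body weight
# BW (kg), dermal adherence factor AF (mg/cm^2/day), exposed skin area SA
# (cm^2), dermal absorption fraction ABS (-), particle emission factor PEF
# (m^3/kg), carcinogenic averaging time AT_ca (days; 70-year lifetime).
# The noncarcinogenic averaging time is AT_nc = ED x 365 by convention.
background:
  As: 17.4
  Cd: 0.06
  Cr: 50.5
  Pb: 36.0
  Cu: 17.0
  Zn: 47.3
  Ni: 14.4
  V: 70.7
toxicity:
  As: 10
  Cd: 30
  Cr: 2
  Pb: 5
  Cu: 5
  Zn: 1
  Ni: 5
  V: 2
rfd:
  As: {ingestion: 3.0e-4, inhalation: 3.01e-4, dermal: 1.23e-4}
  Cd: {ingestion: 1.0e-3, inhalation: 1.0e-3, dermal: 1.0e-5}
  Cr: {ingestion: 3.0e-3, inhalation: 2.86e-5, dermal: 6.0e-5}
  Pb: {ingestion: 3.5e-3, inhalation: 3.52e-3, dermal: 5.25e-4}
  Cu: {ingestion: 4.0e-2, inhalation: 4.02e-2, dermal: 1.2e-2}
  Zn: {ingestion: 3.0e-1, inhalation: 3.0e-1, dermal: 6.0e-2}
  Ni: {ingestion: 2.0e-2, inhalation: 2.06e-2, dermal: 5.4e-3}
  V:  {ingestion: 7.0e-3, inhalation: 7.0e-3, dermal: 7.0e-5}
sf:
  As: {ingestion: 1.5, inhalation: 15.1, dermal: 3.66}
  Cd: {ingestion: 6.1, inhalation: 6.3}
  Cr: {ingestion: 0.5, inhalation: 42.0}
  Pb: {ingestion: 8.5e-3, inhalation: 4.2e-2}
  Ni: {inhalation: 0.84}
exposure:
  children:
    IngR: 200
    InhR: 7.6
    EF: 350
    ED: 6
    BW: 15
    AF: 0.2
    SA: 2800
    ABS: 0.001
    PEF: 1.36e+9
    AT_ca: 25550
  adult_women:
    IngR: 100
    InhR: 12.8
    EF: 350
    ED: 24
    BW: 56.8
    AF: 0.07
    SA: 5000
    ABS: 0.001
    PEF: 1.36e+9
    AT_ca: 25550
  adult_men:
    IngR: 100
    InhR: 15.7
    EF: 350
    ED: 24
    BW: 61.8
    AF: 0.07
    SA: 5700
    ABS: 0.001
    PEF: 1.36e+9
    AT_ca: 25550
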