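# Built-in parameter registries (versioned, immutable): Windkessel outlet
# constants, Fung elastic constants and electrical conductivities / cell
# model assignments for the cardiac regions.

REGISTRY_VERSION <- "1.0"

.windkessel_table <- function() {
  data.frame(
    region = c("ao", "epi", "pv", "pa", "vcs", "vci"),
    alpha = c(3.13, 16.62, 0.062, 0.78, 0.39, 0.39) * 1e6,   # kg m^-3 s^-1
    beta  = c(2.96, 10.36, 0.059, 1.18, 0.11, 0.11) * 1e6,   # kg m^-3 s^-2
    gamma = c(18.43, 25.68, 0.00, 4.17, 0.00, 0.00) * 1e6,   # kg m^-2 s^-2
    stringsAsFactors = FALSE)
}

.fung_table <- function() {
  data.frame(
    region = c("LV", "LA", "RV", "RA", "vessel", "mitral_tricuspid",
               "aortic_pulmonary"),
    c_kPa = c(11.59, 8.31, 9.20, 2.95, 16.77, 0.14, 0.0093),
    a_par = c(9.97, 3.77, 8.22, 6.50, 16.39, 98.58, 120.8),
    a_cross = c(3.17, 3.52, 4.09, 6.52, 15.76, 71.24, 85.87),
    stringsAsFactors = FALSE)
}

.conductivity_table <- function() {
  data.frame(
    region = c("ventricle", "atrium", "purkinje", "bundle"),
    pde = c("bidomain", "bidomain", "monodomain", "monodomain"),
    cell_model = c("ventricular", "atrial", "purkinje", "atrial"),
    m_ext_par = c(0.62, 0.66, NA, NA),
    m_ext_cross = c(0.24, 0.25, NA, NA),
    m_int_par = c(0.17, 0.18, NA, NA),
    m_int_cross = c(0.019, 0.02, NA, NA),
    m_mono = c(NA, NA, 3.95, 1.29),          # already-reduced scalars
    calibrated_cv = c(NA, 0.5, 4.0, 1.54),   # m/s
    stringsAsFactors = FALSE)
}

#' Built-in parameter registries
#'
#' Exact transcriptions of the cardiac parameter tables: three-element
#' Windkessel constants per inlet/outlet region (`ao`, `epi`, `pv`, `pa`,
#' `vcs`, `vci`; SI units), Fung elastic constants per tissue (kPa and
#' dimensionless exponents; the cross-fiber exponents are equal for the
#' sheet and sheet-normal directions), and electrical conductivities with
#' the PDE/cell-model assignment per conductive medium (mS/mm).
#'
#' @return List with `windkessel`, `fung`, `conductivity` data.frames and
#'   `version`.
#' @export
registries <- function() {
  list(windkessel = .windkessel_table(), fung = .fung_table(),
       conductivity = .conductivity_table(), version = REGISTRY_VERSION)
}

#' Look up one registry entry
#'
#' @param table `"windkessel"`, `"fung"` or `"conductivity"`.
#' @param region Region key.
#' @return One-row list of the entry's fields.
#' @export
registry_lookup <- function(table, region) {
  tb <- registries()[[match.arg(table, c("windkessel", "fung",
                                         "conductivity"))]]
  row <- tb[tb$region == region, ]
  if (nrow(row) != 1) stop("unknown region '", region, "'")
  as.list(row)
}

#' Fung material from the registry
#'
#' @param region Registry key (e.g. `"LV"`).
#' @return A `fung_material`.
#' @export
registry_fung <- function(region) {
  r <- registry_lookup("fung", region)
  fung_material(r$c_kPa, r$a_par, r$a_cross, r$a_cross)
}
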