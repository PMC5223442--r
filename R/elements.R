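# Built-in per-element parameter tables.
#
# vdW radii (Angstrom, Bondi) and Lennard-Jones well depths (kcal/mol,
# AMBER/UFF-flavoured) for the probe-field computation; Gasteiger-Marsili
# electronegativity polynomial coefficients (eV) a + b q + c q^2 by
# element/hybridisation for PEOE charge assignment.

.element_params <- data.frame(
  element = c("H", "C", "N", "O", "S", "F", "Cl", "Br", "I", "P"),
  radius  = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.47, 1.75, 1.85, 1.98, 1.80),
  eps     = c(0.0157, 0.1094, 0.17, 0.21, 0.25, 0.061, 0.265, 0.32, 0.40, 0.20),
  stringsAsFactors = FALSE)

#' Element van der Waals parameters
#'
#' Returns the built-in table of vdW radii and Lennard-Jones well depths used
#' by the steric probe field and the volume score.
#'
#' @return data.frame with columns `element`, `radius` (Angstrom), `eps`
#'   (kcal/mol).
#' @export
element_params <- function() .element_params

.element_lookup <- function(elements, what = c("radius", "eps")) {
  what <- match.arg(what)
  i <- match(elements, .element_params$element)
  if (anyNA(i))
    stop("unparameterized element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  .element_params[[what]][i]
}

# Gasteiger-Marsili (1980) electronegativity coefficients, keyed by
# element + hybridisation ("sp3", "sp2", "sp"); halogens/S/P have one row.
.gasteiger_params <- rbind(
  data.frame(key = "H",     a = 7.17,  b = 6.24,  c = -0.56),
  data.frame(key = "C.sp3", a = 7.98,  b = 9.18,  c = 1.88),
  data.frame(key = "C.sp2", a = 8.79,  b = 9.32,  c = 1.51),
  data.frame(key = "C.sp",  a = 10.39, b = 9.45,  c = 0.73),
  data.frame(key = "N.sp3", a = 11.54, b = 10.82, c = 1.36),
  data.frame(key = "N.sp2", a = 12.87, b = 11.15, c = 0.85),
  data.frame(key = "N.sp",  a = 15.68, b = 11.70, c = -0.27),
  data.frame(key = "O.sp3", a = 14.18, b = 12.92, c = 1.39),
  data.frame(key = "O.sp2", a = 17.07, b = 13.79, c = 0.47),
  data.frame(key = "F",     a = 14.66, b = 13.85, c = 2.31),
  data.frame(key = "Cl",    a = 11.00, b = 9.69,  c = 1.35),
  data.frame(key = "Br",    a = 10.08, b = 8.47,  c = 1.16),
  data.frame(key = "I",     a = 9.90,  b = 7.96,  c = 0.96),
  data.frame(key = "S",     a = 10.14, b = 9.13,  c = 1.38),
  data.frame(key = "P",     a = 8.90,  b = 8.24,  c = 0.96))
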