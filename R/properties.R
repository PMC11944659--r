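#' The fifteen modeled properties
#'
#' Registry of the physicochemical and ADME properties handled by the
#' pipeline, with their unit conventions. Eight physicochemical properties
#' (six computable from structure: MW, PSA, HBA, HBD, ROTB, AlogP; two
#' experimental: logS, pKa) and seven ADME properties (HIA, logER, logBB,
#' PPB, logVDss, logCL, logHL).
#'
#' Unit conventions: `log10_of` properties store the base-10 logarithm of the
#' native quantity (logS in log10 mol/L, logVDss in log10 L/kg, logCL in
#' log10 mL/min/kg, logHL in log10 h, logER and logBB log10 ratios); percent
#' properties (HIA, PPB) live on [0, 100]; MW (g/mol) and PSA (A^2) are
#' continuous positives; HBA/HBD/ROTB are counts; AlogP and pKa are
#' dimensionless.
#'
#' @return A data.frame with columns `property`, `unit_spec`
#'   (`log10_of`/`percent`/`count`/`dimensionless`/`continuous`),
#'   `native_unit`, and `experimental` (whether the pipeline models it from
#'   collected measurements, as opposed to computing it directly from
#'   structure).
#' @export
#' @examples
#' property_registry()
property_registry <- function() {
  data.frame(
    property = c("MW", "PSA", "HBA", "HBD", "ROTB", "AlogP",
                 "logS", "pKa",
                 "HIA", "logER", "logBB", "PPB", "logVDss", "logCL", "logHL"),
    unit_spec = c("continuous", "continuous", "count", "count", "count",
                  "dimensionless",
                  "log10_of", "dimensionless",
                  "percent", "log10_of", "log10_of", "percent",
                  "log10_of", "log10_of", "log10_of"),
    native_unit = c("g/mol", "A^2", "", "", "", "",
                    "mol/L", "",
                    "%", "ratio", "ratio", "%", "L/kg", "mL/min/kg", "h"),
    experimental = c(rep(FALSE, 6), rep(TRUE, 9)),
    stringsAsFactors = FALSE
  )
}

#' @rdname property_registry
#' @export
property_names <- function() property_registry()$property

# The nine experimentally collected properties (completeness-matrix columns).
#' @rdname property_registry
#' @export
experimental_properties <- function() {
  reg <- property_registry()
  reg$property[reg$experimental]
}

is_log_property <- function(property) {
  reg <- property_registry()
  identical(reg$unit_spec[match(property, reg$property)], "log10_of")
}

is_percent_property <- function(property) {
  reg <- property_registry()
  identical(reg$unit_spec[match(property, reg$property)], "percent")
}

assert_property <- function(property) {
  if (length(property) != 1L || !property %in% property_names())
    stopf("unknown property '%s'; must be one of: %s",
          paste(property, collapse = ","), paste(property_names(), collapse = ", "))
  invisible(property)
}
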