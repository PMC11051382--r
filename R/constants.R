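# Physical constants (SI unless noted) and unit conventions used throughout.
# Standard state is the ideal gas at 1 bar; temperatures are Kelvin internally,
# Celsius at user interfaces (conversion constant 273.15).

.RGAS <- 8.31446261815324      # J mol^-1 K^-1
.KB_CGS <- 1.380649e-16        # erg K^-1 (concentrations are cm^-3, pressures bar)
.BAR_CGS <- 1e6                # 1 bar in dyn cm^-2
.T0C <- 273.15

#' Convert Celsius to Kelvin
#'
#' @param celsius temperature in degrees Celsius
#' @return temperature in Kelvin
#' @export
celsius_to_kelvin <- function(celsius) celsius + .T0C

# number density (cm^-3) of an ideal gas at P bar, T K
.number_density <- function(P, T) P * .BAR_CGS / (.KB_CGS * T)

# package-level cache (default thermo table, reduced network)
.ventgas_cache <- new.env(parent = emptyenv())
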