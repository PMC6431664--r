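# Physical constants and unit conversions used across modules.

# Molar gas constant, kJ mol^-1 K^-1 (CODATA exact value / 1000)
GAS_CONSTANT_KJ <- 8.31446261815324e-3

# Thermochemical calorie
JOULES_PER_CALORIE <- 4.184

# Molarity of pure water, mol L^-1; the mole-fraction standard-state factor
# used when converting a partition constant into a transfer free energy.
WATER_MOLARITY <- 55.5

#' Convert degrees Celsius to kelvin
#' @param temp_C temperature in degrees Celsius
#' @return temperature in kelvin
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

# Heat-unit scale factors to joules (per 1 unit)
.heat_unit_to_J <- c(ucal = JOULES_PER_CALORIE * 1e-6, uJ = 1e-6, J = 1)
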