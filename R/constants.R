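#' Physical constants and unit conversions
#'
#' Internal unit policy: lengths in nm, times in ns, forces in pN, energies
#' in kcal/mol. Converters live only at the I/O boundary.
#'
#' @format A named list:
#' \describe{
#'   \item{kj_mol_nm_to_pn}{1.6605390 pN per kJ/(mol nm), i.e. 1e21/N_A.
#'     Also converts kJ/(mol nm^2) spring constants to pN/nm.}
#'   \item{kB_pn_nm}{Boltzmann constant, 0.0138065 pN nm / K.}
#'   \item{kB_kcal_mol}{Boltzmann constant times Avogadro, 0.0019872
#'     kcal/(mol K).}
#' }
#' @export
#' @examples
#' 500 * mech_constants$kj_mol_nm_to_pn  # spring constant in pN/nm, ~830
mech_constants <- list(
  kj_mol_nm_to_pn = 1.6605390,
  kB_pn_nm        = 0.0138065,
  kB_kcal_mol     = 0.0019872
)

#' Thermal energy kT
#'
#' @param T_K temperature in Kelvin (default 300, the thermostat setpoint).
#' @param units `"pN.nm"` or `"kcal/mol"`.
#' @return kT in the requested units (4.14195 pN nm or 0.59616 kcal/mol at
#'   300 K).
#' @export
kT <- function(T_K = 300, units = c("pN.nm", "kcal/mol")) {
  units <- match.arg(units)
  stopifnot(is.numeric(T_K), T_K > 0)
  switch(units,
    "pN.nm"    = mech_constants$kB_pn_nm * T_K,
    "kcal/mol" = mech_constants$kB_kcal_mol * T_K
  )
}
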