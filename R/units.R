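# Package-wide unit conventions (fixed; no unit inference anywhere):
#   time               seconds
#   counts             molecules cell^-1 (continuous quantities)
#   molecular mass     Da
#   membrane footprint nm^2 per molecule
#   length             um; volume um^3; cell mass g cell^-1

#' Unit conversion constants
#'
#' Constants used for mass and area conversions throughout the package.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{da_to_g}{grams per dalton (1.66054e-24)}
#'   \item{um2_to_nm2}{nm^2 per um^2 (1e6)}
#' }
#' @export
protocell_constants <- list(
  da_to_g    = 1.66054e-24,
  um2_to_nm2 = 1e6
)
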