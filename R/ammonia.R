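# Free-ammonia speciation. In ammonium-rich anaerobic digesters the
# unionized NH3 fraction of total ammonium nitrogen (TAN) is the inhibitory
# species; it is set by pH and temperature through the NH4+/NH3 acid
# dissociation equilibrium.

#' Temperature-dependent pKa of the ammonium ion
#'
#' Van't Hoff-type relation `pKa(T) = 0.09018 + 2729.92 / T` with T in
#' kelvin (Emerson et al. relation, the standard form used in anaerobic
#' digestion work).
#'
#' @param temp_k temperature in kelvin
#' @return pKa of NH4+
#' @export
ammonia_pka <- function(temp_k) {
  if (any(temp_k <= 273)) stopf("temperature must be above 273 K")
  0.09018 + 2729.92 / temp_k
}

#' Free ammonia from total ammonium nitrogen
#'
#' NH3-N = TAN / (1 + 10^(pKa(T) - pH)). Units follow the TAN input
#' (g N/L in, g NH3-N/L out).
#'
#' @param tan total ammonium nitrogen, g N/L (NH4+ plus NH3)
#' @param ph reactor pH
#' @param temp_k temperature in kelvin (55 degrees C is 328.15 K)
#' @return free ammonia as g NH3-N/L
#' @export
free_ammonia <- function(tan, ph, temp_k) {
  if (any(tan < 0)) stopf("TAN must be non-negative")
  if (any(ph <= 0 | ph >= 14)) stopf("pH must be in (0, 14)")
  pka <- ammonia_pka(temp_k)
  tan / (1 + 10^(pka - ph))
}
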