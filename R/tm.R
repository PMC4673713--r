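# Primer melting temperature.
#
# Nearest-neighbor duplex thermodynamics with the unified parameter set
# (SantaLucia 1998), entropic monovalent-salt correction and a two-state
# Tm at the supplied oligo concentration.  Short oligos (< 14 nt) fall
# back to the Wallace rule 2(A+T) + 4(G+C).

# dH in kcal/mol, dS in cal/(mol K); propagation step keyed by dinucleotide
NN_DH <- c(AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
           TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
           CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
           GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
           TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
           CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
           GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9)
# duplex initiation per terminal base pair
INIT_DH <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
INIT_DS <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)

#' Primer melting temperature
#'
#' @param core Primer sequence (DNA, no N), 5'->3'.
#' @param model `"nearest_neighbor"` (unified parameters; used for
#'   length >= 14 under `"auto"`), `"wallace"` (2(A+T)+4(G+C); used below
#'   14 nt under `"auto"`), or `"auto"`.
#' @param salt_molar Monovalent cation concentration (mol/L, default 0.05).
#' @param oligo_molar Total oligo concentration (mol/L, default 5e-7).
#' @return Tm in degrees Celsius.
#' @export
melting_temperature <- function(core, model = c("auto", "nearest_neighbor", "wallace"),
                                salt_molar = 0.05, oligo_molar = 5e-7) {
  model <- match.arg(model)
  core <- toupper(core)
  n <- nchar(core)
  if (n < 2L) stop("primer too short for a melting temperature: ", core)
  bases <- strsplit(core, "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) {
    stop("primer contains non-ACGT characters: ", core)
  }
  if (model == "auto") {
    model <- if (n >= 14L) "nearest_neighbor" else "wallace"
  }
  if (model == "wallace") {
    return(2 * sum(bases %in% c("A", "T")) + 4 * sum(bases %in% c("G", "C")))
  }
  steps <- paste0(bases[-n], bases[-1L])
  dH <- sum(NN_DH[steps]) + INIT_DH[bases[1L]] + INIT_DH[bases[n]]
  dS <- sum(NN_DS[steps]) + INIT_DS[bases[1L]] + INIT_DS[bases[n]]
  dS <- dS + 0.368 * (n - 1L) * log(salt_molar)
  unname(dH * 1000 / (dS + 1.987 * log(oligo_molar / 4)) - 273.15)
}
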