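#' The six gene expression variables, in canonical order
#'
#' All six-variable matrices and profiles in this package use the fixed
#' column order TR, RS, RA, TLRi, PS, PA: transcription rate, mRNA
#' stability, mRNA abundance, translation rate per mRNA molecule, protein
#' stability and protein abundance.  The first three describe the mRNA side
#' of gene expression, the last three the protein side.  Total translation
#' rate (TLR = RA x TLRi) is derivable and never stored.
#'
#' @format Character vector of length 6.
#' @export
SIXVP_VARIABLES <- c("TR", "RS", "RA", "TLRi", "PS", "PA")

#' @rdname SIXVP_VARIABLES
#' @export
SIXVP_MRNA_VARIABLES <- c("TR", "RS", "RA")

#' @rdname SIXVP_VARIABLES
#' @export
SIXVP_PROTEIN_VARIABLES <- c("TLRi", "PS", "PA")

match_variable <- function(variable) {
  match.arg(variable, SIXVP_VARIABLES)
}
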