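#' Physicochemical property scales for amino acids
#'
#' Returns a named numeric vector with one value per standard amino acid,
#' for use in co-variation analysis of alignment columns. Three canonical
#' published scales are shipped:
#'
#' * `"volume"` — residue volume in cubic Angstroms (Zamyatnin 1972).
#' * `"polarity"` — the Grantham (1974) polarity index.
#' * `"hydrophobicity"` — the Kyte-Doolittle (1982) hydropathy index.
#'
#' Columns are compared on one scale at a time; a residue pair co-varies on a
#' scale when the per-species property values of the two columns are linearly
#' correlated. The scales are deliberately simple vectors so that user-defined
#' scales can be substituted anywhere a `scale` argument is accepted.
#'
#' @param name One of `"volume"`, `"polarity"`, `"hydrophobicity"`, or a named
#'   numeric vector covering all 20 amino acids (returned unchanged after
#'   validation).
#' @return Named numeric vector over the 20 one-letter amino-acid codes, with
#'   a `"scale_name"` attribute.
#' @examples
#' v <- property_scale("volume")
#' v["G"] < v["W"]  # glycine is smaller than tryptophan
#' @export
property_scale <- function(name = c("volume", "polarity", "hydrophobicity")) {
  if (is.numeric(name)) {
    miss <- setdiff(AA_ALPHABET, names(name))
    if (length(miss) > 0L)
      stop("custom property scale is missing amino acids: ",
           paste(miss, collapse = ", "))
    if (any(!is.finite(name[AA_ALPHABET])))
      stop("custom property scale contains non-finite values")
    out <- name[AA_ALPHABET]
    if (is.null(attr(out, "scale_name"))) attr(out, "scale_name") <- "custom"
    return(out)
  }
  name <- match.arg(name)
  out <- switch(name,
    volume = c(
      A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
      Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
      L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
      S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0),
    polarity = c(
      A =  8.1, R = 10.5, N = 11.6, D = 13.0, C =  5.5,
      Q = 10.5, E = 12.3, G =  9.0, H = 10.4, I =  5.2,
      L =  4.9, K = 11.3, M =  5.7, F =  5.2, P =  8.0,
      S =  9.2, T =  8.6, W =  5.4, Y =  6.2, V =  5.9),
    hydrophobicity = c(
      A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
      Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
      L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2))
  attr(out, "scale_name") <- name
  out
}
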