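# Jones-Taylor-Thornton (1992) amino-acid exchangeabilities and stationary
# frequencies, in the standard PAML residue order (A R N D C Q E G H I L K M
# F P S T W Y V).  The exchangeability values are the integer accepted-point-
# mutation counts of the original publication, as distributed in PAML's
# jones.dat; only their relative magnitudes matter because the generator is
# rescaled to unit expected rate.

JTT_LOWER_TRIANGLE <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16
)

JTT_FREQUENCIES <- c(
  A = 0.076748, R = 0.051691, N = 0.042645, D = 0.051544, C = 0.019803,
  Q = 0.040752, E = 0.061830, G = 0.073152, H = 0.022944, I = 0.053761,
  L = 0.091904, K = 0.058676, M = 0.023826, F = 0.040126, P = 0.050901,
  S = 0.068765, T = 0.058565, W = 0.014261, Y = 0.032102, V = 0.066005
)

#' JTT exchangeability matrix
#'
#' Returns the symmetric 20x20 Jones-Taylor-Thornton exchangeability matrix
#' (diagonal zero) in the canonical residue order used throughout the
#' package.
#'
#' @return A symmetric numeric 20x20 matrix with residue dimnames.
#' @export
#' @examples
#' s <- jtt_exchangeabilities()
#' all(s == t(s))
jtt_exchangeabilities <- function() {
  s <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  s[lower.tri(s)] <- JTT_LOWER_TRIANGLE
  s <- s + t(s)
  s
}

#' JTT stationary frequencies
#'
#' The amino-acid frequencies published with the JTT model (normalised to sum
#' to one exactly).
#'
#' @return A named numeric vector of 20 frequencies.
#' @export
jtt_frequencies <- function() {
  JTT_FREQUENCIES / sum(JTT_FREQUENCIES)
}
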