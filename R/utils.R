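#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences over A, C, G, T, N (either case).
#' @return Character vector of reverse complements (case preserved).
#' @export
reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

# round half away from zero to `digits` decimals (printed-table convention;
# base round() is half-to-even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# all matches of a fixed pattern in a single subject; 0 x 2 matrix if none
locate_fixed_all <- function(subject, pattern) {
  m <- stringi::stri_locate_all_fixed(subject, pattern)[[1]]
  m[!is.na(m[, 1]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
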