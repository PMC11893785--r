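#' Locus model for the FGF14 intron-1 GAA repeat
#'
#' Builds the fixed locus template shared by every pipeline stage: the three
#' upstream and three downstream anchor sequences used to recognise
#' locus-spanning reads, the two junction 20-mers used for repeat sizing, the
#' flanking sequences they live in, the position of the upstream
#' rs534066520-like T>A SNP, and the six-motif lexicon used for waterfall
#' decomposition of the tract.
#'
#' The flanks are a model of the locus, not a copy of the reference genome:
#' they embed the anchor sequences (upstream anchors 1 and 2 overlap on their
#' shared "TCTTA"; anchor 3 is extended so that the upstream flank ends in
#' "...AACCAACTTTCTGTGAA") such that a tract beginning with at least one GAA
#' unit creates the upstream junction 20-mer verbatim, and a tract ending with
#' at least two GAA units creates the downstream junction 20-mer verbatim.
#' Total flank length is 150 nt, matching the product-size model in which a
#' 200-unit repeat plus flanks runs at 750 bp.
#'
#' @return An object of class `locus_template`: a list with elements
#'   `up_anchors`, `down_anchors`, `junction_up`, `junction_down`, `up_flank`,
#'   `down_flank`, `snp_offset` (0-based index into `up_flank`), `snp_wt`,
#'   `snp_alt`, `motif_lexicon` (longest-first; the two 9-nt motifs ordered
#'   (GCA)2GAA before GCA(GAA)2), and `up_anchor_offsets` (0-based start of
#'   each upstream anchor within `up_flank`, used for SNP localisation).
#' @examples
#' tpl <- locus_template()
#' tpl$junction_up
#' @export
locus_template <- function() {
  up_anchors <- c(
    "TGCAAATGAAGGAAAACTCTTA",
    "TCTTAGTTGTAAAATATCAATA",
    "TTCTCTATGCAACCAACTTT"
  )
  down_anchors <- c(
    "GAAATGTGTTTAAGAATTCCTCAA",
    "TAAGACTAAGCTCTATGTGGG",
    "CAGGAACTGCTTAATTCATCATTG"
  )
  # anchors 1+2 overlap on "TCTTA"; fixed non-repetitive spacer carries the
  # SNP site; anchor 3 is extended to the junction boundary
  spacer <- "CACTGTACGTCTC"
  up_flank <- paste0(
    up_anchors[1], substring(up_anchors[2], 6),
    spacer,
    up_anchors[3], "CTGTGAA"
  )
  down_flank <- paste0("TA", down_anchors[1], down_anchors[2], down_anchors[3])

  tpl <- structure(
    list(
      up_anchors = up_anchors,
      down_anchors = down_anchors,
      junction_up = "AACCAACTTTCTGTGAAGAA",
      junction_down = "GAAGAATAGAAATGTGTTTA",
      up_flank = up_flank,
      down_flank = down_flank,
      snp_offset = 44L, # 0-based; the T in the spacer
      snp_wt = "T",
      snp_alt = "A",
      motif_lexicon = c(
        "GCAGAAGAAGAAGAA", # GCA(GAA)4
        "GCAGAAGAAGAA",    # GCA(GAA)3
        "GCAGCAGAA",       # (GCA)2GAA
        "GCAGAAGAA",       # GCA(GAA)2
        "GCAGAA",
        "GAA"
      ),
      up_anchor_offsets = c(0L, 17L, 52L)
    ),
    class = "locus_template"
  )
  validate_locus_template(tpl)
  tpl
}

#' Validate a locus template
#'
#' Checks the structural invariants every stage relies on: junction 20-mers
#' arise from flank + tract, flanks total 150 nt, each anchor occurs exactly
#' once in its own flank and never in the opposite one, no GCA-containing
#' motif occurs in a flank, and the SNP site is a T lying outside all anchor
#' and junction matches.
#'
#' @param tpl A `locus_template`.
#' @return `tpl`, invisibly; errors if an invariant fails.
#' @export
validate_locus_template <- function(tpl) {
  stopifnot(inherits(tpl, "locus_template"))
  up <- tpl$up_flank
  dn <- tpl$down_flank
  if (nchar(up) + nchar(dn) != 150L) {
    stop("flanks must total 150 nt", call. = FALSE)
  }
  if (paste0(substring(up, nchar(up) - 16L), "GAA") != tpl$junction_up) {
    stop("junction_up must equal the last 17 nt of up_flank + 'GAA'",
      call. = FALSE
    )
  }
  if (paste0("GAAGAA", substring(dn, 1L, 14L)) != tpl$junction_down) {
    stop("junction_down must equal 'GAAGAA' + the first 14 nt of down_flank",
      call. = FALSE
    )
  }
  n_hits <- function(pattern, subject) {
    m <- stringi::stri_locate_all_fixed(subject, pattern)[[1]]
    sum(!is.na(m[, 1]))
  }
  for (a in tpl$up_anchors) {
    if (n_hits(a, up) != 1L) stop("upstream anchor not unique in up_flank: ", a, call. = FALSE)
    if (n_hits(a, dn) != 0L) stop("upstream anchor found in down_flank: ", a, call. = FALSE)
  }
  for (a in tpl$down_anchors) {
    if (n_hits(a, dn) != 1L) stop("downstream anchor not unique in down_flank: ", a, call. = FALSE)
    if (n_hits(a, up) != 0L) stop("downstream anchor found in up_flank: ", a, call. = FALSE)
  }
  # GCA-containing motifs must never occur in a flank (plain "GAA" inevitably
  # does, inside the printed anchors themselves, and is harmless because
  # tokenization is confined to the junction-delimited tract)
  for (m in setdiff(tpl$motif_lexicon, "GAA")) {
    if (n_hits(m, up) + n_hits(m, dn) > 0L) {
      stop("repeat motif found in a flank: ", m, call. = FALSE)
    }
  }
  if (substring(up, tpl$snp_offset + 1L, tpl$snp_offset + 1L) != tpl$snp_wt) {
    stop("up_flank must carry the wild-type base at snp_offset", call. = FALSE)
  }
  # SNP site outside all anchor matches
  for (a in tpl$up_anchors) {
    m <- stringi::stri_locate_first_fixed(up, a)
    if (tpl$snp_offset + 1L >= m[1] && tpl$snp_offset + 1L <= m[2]) {
      stop("SNP site overlaps an anchor match", call. = FALSE)
    }
  }
  invisible(tpl)
}

#' @export
print.locus_template <- function(x, ...) {
  cat("<locus_template>\n")
  cat("  up_flank   (", nchar(x$up_flank), " nt): ", x$up_flank, "\n", sep = "")
  cat("  down_flank (", nchar(x$down_flank), " nt): ", x$down_flank, "\n", sep = "")
  cat("  junctions: ", x$junction_up, " / ", x$junction_down, "\n", sep = "")
  cat("  SNP: offset ", x$snp_offset, " (", x$snp_wt, ">", x$snp_alt, ")\n", sep = "")
  cat("  motifs: ", paste(x$motif_lexicon, collapse = ", "), "\n", sep = "")
  invisible(x)
}
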