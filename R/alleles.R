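#' Describe a repeat allele as ordered motif blocks
#'
#' An allele configuration is the ground truth used by the synthetic-read
#' generator: an ordered list of (motif, count) blocks written upstream to
#' downstream in the transcription direction, plus the base carried at the
#' upstream SNP site.
#'
#' @param blocks A data frame (or tibble) with columns `motif` (character,
#'   one of the six lexicon motifs) and `count` (positive integer, tandem
#'   copies); or a list of `c(motif, count)` pairs.
#' @param snp_allele `"T"` (wild type) or `"A"`.
#' @param label Free-text label used in read ids and truth tables.
#' @param gel_override If `TRUE`, the amplicon-mode simulator treats this
#'   allele's LR-PCR product as excised from the gel even when its computed
#'   length fails the >750 bp rule. This emulates the approximate mobility of
#'   bands running near the cutoff (the published cohort reports a 191-unit,
#'   i.e. 723-bp, product among gel-selected samples).
#' @return An object of class `allele_config`.
#' @examples
#' allele_config(list(c("GAA", 269)), label = "pure_269")
#' allele_config(
#'   tibble::tibble(motif = c("GAA", "GCAGAA", "GAA"), count = c(27, 40, 134)),
#'   snp_allele = "A", label = "complex_134"
#' )
#' @export
allele_config <- function(blocks, snp_allele = "T", label = "",
                          gel_override = FALSE) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    blocks <- tibble::tibble(
      motif = vapply(blocks, function(b) as.character(b[[1]]), character(1)),
      count = vapply(blocks, function(b) as.integer(b[[2]]), integer(1))
    )
  }
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("motif", "count") %in% names(blocks)))
  blocks$count <- as.integer(blocks$count)
  if (nrow(blocks) == 0L) stop("allele must have at least one block", call. = FALSE)
  if (any(blocks$count < 1L)) stop("block counts must be >= 1", call. = FALSE)
  if (!snp_allele %in% c("T", "A")) stop("snp_allele must be 'T' or 'A'", call. = FALSE)
  structure(
    list(
      blocks = blocks, snp_allele = snp_allele, label = label,
      gel_override = isTRUE(gel_override)
    ),
    class = "allele_config"
  )
}

#' Tract sequence and unit accounting for an allele configuration
#'
#' `tract_sequence()` concatenates the blocks; `allele_units()` is the total
#' repeat-unit length of the tract (nt / 3); `allele_gaa_units()` counts GAA
#' trinucleotides contributed by pure GAA blocks only; `allele_longest_run()`
#' is the longest pure-GAA block (merging adjacent GAA blocks), the
#' ground-truth counterpart of the profiler's longest-run measurement.
#'
#' @param config An `allele_config`.
#' @return A string (`tract_sequence`) or integer.
#' @export
tract_sequence <- function(config) {
  stopifnot(inherits(config, "allele_config"))
  paste(strrep(config$blocks$motif, config$blocks$count), collapse = "")
}

#' @rdname tract_sequence
#' @export
allele_units <- function(config) {
  as.integer(nchar(tract_sequence(config)) / 3L)
}

#' @rdname tract_sequence
#' @export
allele_gaa_units <- function(config) {
  sum(config$blocks$count[config$blocks$motif == "GAA"])
}

#' @rdname tract_sequence
#' @export
allele_longest_run <- function(config) {
  is_gaa <- config$blocks$motif == "GAA"
  if (!any(is_gaa)) return(0L)
  grp <- cumsum(c(TRUE, diff(is_gaa) != 0L))
  runs <- tapply(config$blocks$count[is_gaa], grp[is_gaa], sum)
  as.integer(max(runs))
}

#' Build the full allele sequence carried by a read
#'
#' Concatenates the upstream flank (with the configured base substituted at
#' the SNP site), the repeat tract, and the downstream flank. By template
#' construction, a tract starting with >= 1 GAA unit contains the upstream
#' junction 20-mer exactly once and a tract ending with >= 2 GAA units
#' contains the downstream junction 20-mer exactly once.
#'
#' @param template A `locus_template`.
#' @param config An `allele_config`.
#' @return A nucleotide string of length `150 + 3 * allele_units(config)`.
#' @examples
#' tpl <- locus_template()
#' seq <- build_allele_sequence(tpl, allele_config(list(c("GAA", 269))))
#' nchar(seq) # 150 + 807
#' @export
build_allele_sequence <- function(template, config) {
  stopifnot(inherits(template, "locus_template"), inherits(config, "allele_config"))
  unknown <- setdiff(config$blocks$motif, template$motif_lexicon)
  if (length(unknown) > 0L) {
    stop(
      "unknown repeat motif: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  up <- template$up_flank
  if (config$snp_allele != template$snp_wt) {
    substr(up, template$snp_offset + 1L, template$snp_offset + 1L) <- config$snp_allele
  }
  paste0(up, tract_sequence(config), template$down_flank)
}

#' @export
print.allele_config <- function(x, ...) {
  blk <- paste0(x$blocks$motif, "x", x$blocks$count, collapse = " + ")
  cat("<allele_config> ", if (nzchar(x$label)) paste0(x$label, ": ") else "",
    blk, " (", allele_units(x), " units, SNP ", x$snp_allele, ")\n",
    sep = ""
  )
  invisible(x)
}
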