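#' Truth-mirrored three-group cohort specification
#'
#' Builds a [cohort_spec()] whose ground truth mirrors, individual for
#' individual, the category counts reported for a screen of 476 undiagnosed
#' ataxia patients, 548 MSA patients and 455 healthy controls: per group the
#' numbers of carriers of pure GAA expansions (>= 250 units, 200-249 units,
#' < 200 units), complex configurations with an embedded pure GAA run of
#' >= 100 units, and complex configurations with runs < 100 units, with the
#' published per-category unit ranges. Every carrier is heterozygous with a
#' (GAA)16 wild-type partner allele; all remaining individuals are
#' wild-type homozygotes. Pure and wild-type alleles carry the wild-type T
#' at the upstream SNP site, complex alleles carry A.
#'
#' Pure expanded alleles use the published per-individual unit counts where
#' a single individual's value is printed (269, 254, 245, 191, 212, 240) and
#' deterministic values spanning the published ranges otherwise. Complex
#' alleles place pure GAA runs at both tract ends (the published structure),
#' with the embedded GCAGAA block sized so every carrier's product exceeds
#' the 750 bp gel cutoff; the single 191-unit pure product (723 bp) is
#' marked `gel_override` since it was gel-selected despite running below the
#' nominal cutoff.
#'
#' @param depth_range Passed to [cohort_spec()].
#' @param seed Passed to [cohort_spec()].
#' @return A [cohort_spec()] with a `count` column suitable for
#'   `exact_counts = TRUE` simulation.
#' @export
reference_cohort_spec <- function(depth_range = c(20L, 200L), seed = 1L) {
  alleles <- list(wt = allele_config(list(c("GAA", 16)), "T", "wt"))
  pure <- function(n, override = FALSE) {
    allele_config(list(c("GAA", n)), "T", paste0("pure_", n), gel_override = override)
  }
  # complex tracts end their interrupt region with one (GCA)2GAA so that
  # greedy tokenization reproduces the terminal pure-GAA runs block-exactly
  # (a trailing GCAGAA would absorb three downstream units into GCA(GAA)4)
  cx_hi <- function(up, down) {
    allele_config(
      list(c("GAA", up), c("GCAGAA", 40), c("GCAGCAGAA", 1), c("GAA", down)),
      "A", sprintf("cx_%d_%d", up, down)
    )
  }
  cx_lo <- function(down, tag) {
    allele_config(
      list(c("GAA", 10), c("GCAGAA", 100), c("GCAGCAGAA", 1), c("GAA", down)),
      "A", sprintf("cxlo_%s_%d", tag, down)
    )
  }

  # pure expansions: published per-individual unit counts, ranges spanned
  # deterministically where only a range is printed
  ataxia_pure_hi <- c(251, 300, 305, 312, 330, 361) # five in the >=300 band
  for (n in ataxia_pure_hi) alleles[[paste0("pure_", n)]] <- pure(n)
  for (n in c(212, 240)) alleles[[paste0("pure_", n)]] <- pure(n)
  alleles$pure_191 <- pure(191, override = TRUE)
  alleles$pure_269 <- pure(269)
  for (n in c(254, 245)) alleles[[paste0("pure_", n)]] <- pure(n)

  # complex with embedded run >= 100: published terminal-run pairs
  alleles$cx_34_167 <- cx_hi(34, 167)
  alleles$cx_27_134 <- cx_hi(27, 134)
  alleles$cx_27_160 <- cx_hi(27, 160)
  alleles$cx_31_140 <- cx_hi(31, 140)

  # complex with runs < 100: longest runs spanning the published ranges
  lo_runs <- list(
    ataxia = round(seq(24, 83, length.out = 14)),
    msa = round(seq(21, 83, length.out = 34)),
    healthy = round(seq(23, 75, length.out = 24))
  )
  lo_names <- list()
  for (tag in names(lo_runs)) {
    nm <- character(0)
    for (d in lo_runs[[tag]]) {
      label <- sprintf("cxlo_%s_%d", tag, d)
      while (label %in% names(alleles)) label <- paste0(label, "b")
      cfg <- cx_lo(d, tag)
      cfg$label <- label
      alleles[[label]] <- cfg
      nm <- c(nm, label)
    }
    lo_names[[tag]] <- nm
  }

  carrier_rows <- function(group, n, carriers) {
    tibble::tibble(
      group = group, n = n,
      allele1 = carriers, allele2 = "wt", count = 1L
    )
  }
  g_ataxia <- dplyr::bind_rows(
    carrier_rows("ataxia", 476L, c(
      paste0("pure_", c(ataxia_pure_hi, 212, 240, 191)),
      "cx_34_167", lo_names$ataxia
    )),
    tibble::tibble(
      group = "ataxia", n = 476L, allele1 = "wt", allele2 = "wt",
      count = 476L - 24L
    )
  )
  g_msa <- dplyr::bind_rows(
    carrier_rows("msa", 548L, c("pure_269", "cx_27_134", lo_names$msa)),
    tibble::tibble(
      group = "msa", n = 548L, allele1 = "wt", allele2 = "wt",
      count = 548L - 36L
    )
  )
  g_healthy <- dplyr::bind_rows(
    carrier_rows("healthy", 455L, c(
      "pure_254", "pure_245", "cx_27_160", "cx_31_140", lo_names$healthy
    )),
    tibble::tibble(
      group = "healthy", n = 455L, allele1 = "wt", allele2 = "wt",
      count = 455L - 28L
    )
  )
  cohort_spec(
    dplyr::bind_rows(g_ataxia, g_msa, g_healthy), alleles,
    depth_range = depth_range, seed = seed
  )
}
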