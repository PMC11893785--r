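#' Classification thresholds
#'
#' Numeric boundaries used to interpret allele calls. Penetrance bands use
#' inclusive integer intervals: >= 300 units full penetrance, 250-299
#' incomplete, 200-249 uncertain significance, below 200 below the
#' pathogenic range. Configuration classes split complex tracts at an
#' embedded pure-GAA run of 100 units. A purity threshold converts the
#' visual pure-vs-complex waterfall judgement into a number. The RP-PCR
#' thresholds bracket the observed categories (largest negative run 83,
#' inconclusive runs 134-167, smallest positive pure allele 191 units); they
#' are an inference from those observations, not an assay specification, and
#' are exposed for tuning.
#'
#' @param full_penetrance_min,incomplete_min,uncertain_min Band boundaries
#'   in repeat units.
#' @param complex_run_split Run length (units) separating the two complex
#'   classes.
#' @param purity_min_for_pure Minimum consensus purity for a PURE call.
#' @param rp_positive_min_run,rp_inconclusive_min_run RP-PCR rule
#'   boundaries in units.
#' @param gel_bp Gel selection cutoff in bp.
#' @return A list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(full_penetrance_min = 300,
                                      incomplete_min = 250,
                                      uncertain_min = 200,
                                      complex_run_split = 100,
                                      purity_min_for_pure = 0.95,
                                      rp_positive_min_run = 191,
                                      rp_inconclusive_min_run = 100,
                                      gel_bp = 750) {
  if (!(full_penetrance_min > incomplete_min &&
    incomplete_min > uncertain_min &&
    uncertain_min > complex_run_split && complex_run_split > 0)) {
    stop("thresholds must satisfy full > incomplete > uncertain > run split > 0",
      call. = FALSE
    )
  }
  if (purity_min_for_pure <= 0 || purity_min_for_pure > 1) {
    stop("purity_min_for_pure must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      full_penetrance_min = full_penetrance_min,
      incomplete_min = incomplete_min,
      uncertain_min = uncertain_min,
      complex_run_split = complex_run_split,
      purity_min_for_pure = purity_min_for_pure,
      rp_positive_min_run = rp_positive_min_run,
      rp_inconclusive_min_run = rp_inconclusive_min_run,
      gel_bp = gel_bp
    ),
    class = "classification_thresholds"
  )
}

#' Configuration class of an allele
#'
#' `PURE` when consensus purity reaches the purity threshold; otherwise the
#' complex configuration is split by its longest embedded pure-GAA run:
#' `COMPLEX_RUN_GE100` at or above the run split, else `COMPLEX_RUN_LT100`.
#'
#' @param purity Consensus purity in \[0, 1\] (vectorized).
#' @param longest_run_units Longest embedded pure-GAA run (units).
#' @param thresholds A [classification_thresholds()].
#' @return Character vector of classes.
#' @export
classify_configuration <- function(purity, longest_run_units,
                                   thresholds = classification_thresholds()) {
  ifelse(purity >= thresholds$purity_min_for_pure, "PURE",
    ifelse(longest_run_units >= thresholds$complex_run_split,
      "COMPLEX_RUN_GE100", "COMPLEX_RUN_LT100"
    )
  )
}

#' Penetrance band of a repeat size
#'
#' @param unit_count Non-negative repeat-unit count (vectorized).
#' @param thresholds A [classification_thresholds()].
#' @return Character vector: `"FULL"` (>= 300), `"INCOMPLETE"` (250-299),
#'   `"UNCERTAIN"` (200-249) or `"BELOW"`.
#' @examples
#' penetrance_band(c(312, 269, 245, 191))
#' @export
penetrance_band <- function(unit_count, thresholds = classification_thresholds()) {
  if (any(unit_count < 0)) stop("unit_count must be non-negative", call. = FALSE)
  ifelse(unit_count >= thresholds$full_penetrance_min, "FULL",
    ifelse(unit_count >= thresholds$incomplete_min, "INCOMPLETE",
      ifelse(unit_count >= thresholds$uncertain_min, "UNCERTAIN", "BELOW")
    )
  )
}

#' Predict the repeat-primed PCR outcome
#'
#' RP-PCR produces a ladder whose extent tracks the longest contiguous GAA
#' stretch: per allele the score is the longest pure-GAA run, or the whole
#' allele size when the allele is PURE. Scores at or above the positive
#' threshold predict a positive ladder; scores reaching the inconclusive
#' threshold predict a ladder that fades mid-trace; anything shorter is
#' negative. An individual's prediction is the strongest across its alleles
#' (positive > inconclusive > negative).
#'
#' @param alleles Allele tibble from [cluster_alleles()] with columns
#'   `unit_count_median`, `longest_run_units`, `purity`.
#' @param thresholds A [classification_thresholds()].
#' @return A single string: `"positive"`, `"inconclusive"` or `"negative"`.
#' @export
predict_rp_pcr <- function(alleles, thresholds = classification_thresholds()) {
  if (nrow(alleles) == 0L) {
    return(NA_character_)
  }
  cls <- classify_configuration(alleles$purity, alleles$longest_run_units, thresholds)
  score <- pmax(
    alleles$longest_run_units,
    ifelse(cls == "PURE", alleles$unit_count_median, 0)
  )
  best <- max(score)
  if (best >= thresholds$rp_positive_min_run) {
    "positive"
  } else if (best >= thresholds$rp_inconclusive_min_run) {
    "inconclusive"
  } else {
    "negative"
  }
}

#' SNP genotype from allele calls
#'
#' Combines the per-allele majority bases (computed during clustering with
#' a coverage floor of 3 informative reads and an 80% majority rule) into a
#' diploid genotype. With a single allele call the genotype is reported as
#' homozygous for that base; any unknown allele base yields `"unknown"`.
#'
#' @param alleles Allele tibble with a `snp_base` column.
#' @return `"T/T"`, `"T/A"`, `"A/A"` or `"unknown"`.
#' @export
genotype_snp <- function(alleles) {
  if (nrow(alleles) == 0L) {
    return("unknown")
  }
  bases <- alleles$snp_base
  if (any(bases == "unknown" | is.na(bases))) {
    return("unknown")
  }
  if (length(bases) == 1L) bases <- rep(bases, 2L)
  paste(sort(bases, decreasing = TRUE), collapse = "/") # T before A
}

#' Call one individual from its reads
#'
#' Composes the whole per-sample pipeline: anchor extraction, read
#' profiling, uniform-region selection, allele clustering, configuration
#' and penetrance classification, RP-PCR prediction and SNP genotyping.
#'
#' @param reads Tibble with `read_id`, `sequence` for one sample.
#' @param sample_id,group Identifiers copied into the call row.
#' @param template A [locus_template()].
#' @param config A [pipeline_config()].
#' @return A one-row tibble: read accounting (`n_reads`, `n_accepted`,
#'   `n_sized`, `n_selected`, `n_alleles`), per-allele summaries
#'   (`allele{1,2}_units/_purity/_run/_class/_band/_snp`), `rp_prediction`,
#'   `snp_genotype`, and `flags` (`"no_locus_reads"` when nothing spans the
#'   locus, `"no_allele_call"` when too few reads cluster).
#' @export
call_individual <- function(reads, sample_id = "sample", group = NA_character_,
                            template = locus_template(),
                            config = pipeline_config()) {
  thr <- config$thresholds
  ext <- extract_repeat_reads(reads, template, config$max_mismatches)
  prof <- profile_reads(ext, template)
  sel <- select_uniform_region(
    prof,
    window_min_nt = config$window_min_nt, window_frac = config$window_frac,
    gap_units = config$split_gap_units, min_reads = config$min_reads
  )
  cl <- suppressWarnings(
    cluster_alleles(sel$selected, config$split_gap_units, config$min_reads)
  )
  al <- cl$alleles
  flag <- if (nrow(ext$anchored) == 0L) {
    "no_locus_reads"
  } else if (nrow(al) == 0L) {
    "no_allele_call"
  } else {
    ""
  }
  a_field <- function(i, what) {
    if (nrow(al) >= i) al[[what]][i] else NA
  }
  cls <- if (nrow(al) > 0L) {
    classify_configuration(al$purity, al$longest_run_units, thr)
  } else {
    character(0)
  }
  band <- if (nrow(al) > 0L) penetrance_band(al$unit_count_median, thr) else character(0)
  tibble::tibble(
    sample = sample_id, group = group,
    n_reads = nrow(tibble::as_tibble(reads)),
    n_accepted = nrow(ext$anchored),
    n_sized = sum(prof$sized),
    n_selected = nrow(sel$selected),
    n_alleles = nrow(al),
    allele1_units = a_field(1L, "unit_count_median"),
    allele1_purity = a_field(1L, "purity"),
    allele1_run = a_field(1L, "longest_run_units"),
    allele1_class = if (nrow(al) >= 1L) cls[1] else NA_character_,
    allele1_band = if (nrow(al) >= 1L) band[1] else NA_character_,
    allele1_snp = a_field(1L, "snp_base"),
    allele2_units = a_field(2L, "unit_count_median"),
    allele2_purity = a_field(2L, "purity"),
    allele2_run = a_field(2L, "longest_run_units"),
    allele2_class = if (nrow(al) >= 2L) cls[2] else NA_character_,
    allele2_band = if (nrow(al) >= 2L) band[2] else NA_character_,
    allele2_snp = a_field(2L, "snp_base"),
    rp_prediction = if (nrow(al) > 0L) predict_rp_pcr(al, thr) else NA_character_,
    snp_genotype = genotype_snp(al),
    flags = flag
  )
}

#' Call every individual of a cohort
#'
#' @param reads Tibble with `sample`, `read_id`, `sequence` (e.g. from
#'   [simulate_cohort()]); samples are taken from the explicit column, never
#'   parsed out of read ids.
#' @param manifest Tibble with `sample`, `group`; every individual in the
#'   manifest yields one call row, including individuals with no reads.
#' @param template A [locus_template()].
#' @param config A [pipeline_config()].
#' @return A tibble of [call_individual()] rows, in manifest order.
#' @export
call_cohort <- function(reads, manifest, template = locus_template(),
                        config = pipeline_config()) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("sample", "group") %in% names(manifest)))
  reads <- tibble::as_tibble(reads)
  unknown <- setdiff(unique(reads$sample), manifest$sample)
  if (length(unknown) > 0L) {
    stop("reads from sample(s) missing in manifest: ",
      paste(utils::head(unknown, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  by_sample <- split(reads[, c("read_id", "sequence")], reads$sample)
  rows <- purrr::map2(
    manifest$sample, manifest$group,
    function(s, g) {
      r <- by_sample[[s]] %||%
        tibble::tibble(read_id = character(0), sequence = character(0))
      call_individual(r, s, g, template, config)
    }
  )
  dplyr::bind_rows(rows)
}
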