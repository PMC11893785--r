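#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline: classification thresholds, anchor
#' mismatch tolerance, the uniform-length window rule, allele clustering
#' parameters, library mode and the master seed. Serializable to a YAML
#' file; unknown keys in a file are rejected.
#'
#' @param thresholds A [classification_thresholds()].
#' @param max_mismatches Per-anchor Hamming tolerance for extraction.
#' @param window_min_nt,window_frac Uniform-region window rule.
#' @param split_gap_units Allele split threshold (units).
#' @param min_reads Minimum reads per allele call.
#' @param mode `"amplicon"` (gel-selected LR-PCR products) or `"wgs"`.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = classification_thresholds(),
                            max_mismatches = 0L,
                            window_min_nt = 12, window_frac = 0.01,
                            split_gap_units = 10, min_reads = 3L,
                            mode = c("amplicon", "wgs"), seed = 1L) {
  mode <- match.arg(mode)
  structure(
    list(
      thresholds = thresholds, max_mismatches = as.integer(max_mismatches),
      window_min_nt = window_min_nt, window_frac = window_frac,
      split_gap_units = split_gap_units, min_reads = as.integer(min_reads),
      mode = mode, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration file
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a [pipeline_config()], rejecting
#'   unknown keys.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  thr_known <- names(formals(classification_thresholds))
  thr <- x$thresholds %||% list()
  unknown <- setdiff(names(thr), thr_known)
  if (length(unknown) > 0L) {
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  x$thresholds <- do.call(classification_thresholds, thr)
  do.call(pipeline_config, x)
}

#' Run the whole pipeline on a cohort
#'
#' Extraction, profiling, allele calling, classification and cohort
#' aggregation, with per-stage accounting. Deterministic given config and
#' inputs.
#'
#' @param reads Tibble with `sample`, `read_id`, `sequence`; or a path to a
#'   multiplexed FASTQ accompanied by a `read_samples.tsv` (as written by
#'   [write_cohort()]) mapping `read_id` to `sample`.
#' @param manifest Tibble with `sample`, `group` (or path to such a TSV).
#' @param template A [locus_template()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, `calls.tsv`,
#'   `cohort_table.tsv`, `waterfall.tsv` and `log.tsv` are written there.
#' @return A list of class `pipeline_result`: `calls`, `cohort_table`,
#'   `waterfall` (token export of every sample's sized reads), `log`
#'   (per-stage counts), `config`.
#' @export
run_pipeline <- function(reads, manifest, template = locus_template(),
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(reads) && length(reads) == 1L) {
    fq <- read_fastq(reads)
    map_path <- file.path(dirname(reads), "read_samples.tsv")
    if (!file.exists(map_path)) {
      stop("multiplexed FASTQ input needs ", map_path, call. = FALSE)
    }
    map <- readr::read_tsv(map_path, show_col_types = FALSE)
    reads <- dplyr::inner_join(map, fq, by = "read_id")
  }
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  reads <- tibble::as_tibble(reads)
  manifest <- tibble::as_tibble(manifest)

  calls <- call_cohort(reads, manifest, template, config)
  cohort <- frequency_table(calls, config$thresholds, groups = unique(manifest$group))

  # waterfall export across all samples (sized reads only)
  wf <- list()
  by_sample <- split(reads, reads$sample)
  for (s in names(by_sample)) {
    ext <- extract_repeat_reads(by_sample[[s]], template, config$max_mismatches)
    prof <- profile_reads(ext, template)
    w <- waterfall_matrix(prof)
    if (nrow(w) > 0L) {
      w$sample <- s
      wf[[length(wf) + 1L]] <- w
    }
  }
  waterfall <- if (length(wf) > 0L) {
    dplyr::bind_rows(wf)
  } else {
    tibble::tibble(
      read_id = character(0), read_rank = integer(0), start = integer(0),
      end = integer(0), motif = character(0), sample = character(0)
    )
  }

  log <- tibble::tibble(
    stage = c("input_reads", "accepted", "sized", "selected", "alleles", "calls"),
    n = c(
      nrow(reads), sum(calls$n_accepted), sum(calls$n_sized),
      sum(calls$n_selected), sum(calls$n_alleles), nrow(calls)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
    readr::write_tsv(cohort, file.path(out_dir, "cohort_table.tsv"))
    readr::write_tsv(waterfall, file.path(out_dir, "waterfall.tsv"))
    readr::write_tsv(log, file.path(out_dir, "log.tsv"))
  }
  structure(
    list(
      calls = calls, cohort_table = cohort, waterfall = waterfall,
      log = log, config = config
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$log)
  invisible(x)
}
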