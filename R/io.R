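#' Read a 4-line FASTQ file
#'
#' Strict 4-line dialect with per-record validation; malformed records are
#' reported with their line number.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble: `read_id` (header without `@`), `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ: ", n, " lines is not a multiple of 4 in ", path,
      call. = FALSE
    )
  }
  if (n == 0L) {
    return(tibble::tibble(
      read_id = character(0), sequence = character(0), quality = character(0)
    ))
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record at line ", idx[bad[1]], ": header must start with '@'",
      call. = FALSE
    )
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record at line ", idx[bad[1]] + 2L, ": separator must start with '+'",
      call. = FALSE
    )
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record at line ", idx[bad[1]],
      ": sequence and quality lengths differ",
      call. = FALSE
    )
  }
  tibble::tibble(read_id = substring(hdr, 2L), sequence = seqs, quality = qual)
}

#' Read a FASTA file
#'
#' Wrapped sequence lines are reassembled (via Biostrings).
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A tibble: `read_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble::tibble(read_id = unname(names(s)), sequence = unname(as.character(s)))
}

#' Read sequences with format auto-detection
#'
#' The first non-empty character decides: `>` FASTA, `@` FASTQ.
#'
#' @param path Path to an uncompressed FASTA or FASTQ file.
#' @return A tibble with at least `read_id`, `sequence`.
#' @export
read_sequences <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(tibble::tibble(read_id = character(0), sequence = character(0)))
  }
  ch <- substring(trimws(first), 1L, 1L)
  if (ch == ">") {
    read_fasta(path)
  } else if (ch == "@") {
    read_fastq(path)
  } else {
    stop("cannot detect format of ", path, " (first character '", ch, "')",
      call. = FALSE
    )
  }
}

#' Write reads as FASTQ or FASTA
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`
#'   (defaulting to a constant `"I"` per base).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- tibble::as_tibble(reads)
  qual <- if ("quality" %in% names(reads)) {
    reads$quality
  } else {
    strrep("I", nchar(reads$sequence))
  }
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), reads$sequence, "+", qual
  ))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) {
  reads <- tibble::as_tibble(reads)
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- reads$read_id
  Biostrings::writeXStringSet(s, path, format = "fasta")
  invisible(path)
}

#' Persist a simulated cohort
#'
#' Writes one multiplexed FASTQ (sample membership is carried in a sidecar
#' TSV, never parsed from read ids) and the ground-truth table.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reads = file.path(dir, "reads.fastq"),
    read_samples = file.path(dir, "read_samples.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fastq(sim$reads, paths["reads"])
  readr::write_tsv(sim$reads[, c("read_id", "sample")], paths["read_samples"])
  readr::write_tsv(sim$truth, paths["truth"])
  paths
}
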