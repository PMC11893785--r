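#' Anchor-based recognition of locus-spanning reads
#'
#' A read spans the repeat locus if, in one orientation, it contains at
#' least one of the three upstream anchor sequences and at least one of the
#' three downstream anchor sequences, with every upstream match ending
#' before every downstream match starts (the order check rejects chimeric
#' reads). Both the read and its reverse complement are searched; the
#' accepted orientation is returned locus-forward. Reads whose two
#' orientations both satisfy the criterion are rejected as ambiguous rather
#' than guessed.
#'
#' Matching is exact by default (`max_mismatches = 0`), relying on the three
#' alternative anchors per side to tolerate sequencing errors; a
#' Hamming-distance tolerance is available. `N` bases never match.
#'
#' @param read_id Read identifier (opaque; never parsed).
#' @param sequence Nucleotide string over A,C,G,T,N (uppercased on entry).
#' @param template A [locus_template()].
#' @param max_mismatches Maximum Hamming distance per anchor match.
#' @return A list: `accepted` (logical); when accepted, `read` (one-row
#'   tibble with `read_id`, `sequence` in locus-forward orientation,
#'   `was_reverse_complemented`, and list-columns `up_hits`, `down_hits` of
#'   per-anchor match tables); when rejected, `reason` (one of `"empty"`,
#'   `"no_anchor"`, `"no_upstream_anchor"`, `"no_downstream_anchor"`,
#'   `"anchors_out_of_order"`, `"ambiguous_orientation"`).
#' @export
find_anchors <- function(read_id, sequence, template, max_mismatches = 0L) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    return(list(accepted = FALSE, reason = "empty"))
  }
  orient <- list(
    fwd = sequence,
    rev = reverse_complement(sequence)
  )
  scan <- lapply(orient, function(s) {
    up <- anchor_hits(s, template$up_anchors, max_mismatches)
    down <- anchor_hits(s, template$down_anchors, max_mismatches)
    ok_sides <- nrow(up) > 0L && nrow(down) > 0L
    ordered <- ok_sides && max(up$end) < min(down$start)
    list(up = up, down = down, ok = ok_sides && ordered)
  })
  ok <- vapply(scan, function(x) x$ok, logical(1))
  if (sum(ok) == 2L) {
    return(list(accepted = FALSE, reason = "ambiguous_orientation"))
  }
  if (sum(ok) == 0L) {
    # categorize from the orientation with the most anchor evidence
    sides <- vapply(scan, function(x) (nrow(x$up) > 0L) + (nrow(x$down) > 0L), integer(1))
    hits <- vapply(scan, function(x) nrow(x$up) + nrow(x$down), integer(1))
    best <- scan[[order(-sides, -hits)[1]]]
    reason <- if (nrow(best$up) == 0L && nrow(best$down) == 0L) {
      "no_anchor"
    } else if (nrow(best$up) == 0L) {
      "no_upstream_anchor"
    } else if (nrow(best$down) == 0L) {
      "no_downstream_anchor"
    } else {
      "anchors_out_of_order"
    }
    return(list(accepted = FALSE, reason = reason))
  }
  which_ok <- names(ok)[ok]
  hit <- scan[[which_ok]]
  list(
    accepted = TRUE,
    read = tibble::tibble(
      read_id = read_id,
      sequence = orient[[which_ok]],
      was_reverse_complemented = which_ok == "rev",
      up_hits = list(hit$up),
      down_hits = list(hit$down)
    )
  )
}

# all Hamming-tolerant matches of a set of anchors in one sequence;
# 1-based inclusive coordinates; anchor column is the index 1..3
anchor_hits <- function(sequence, anchors, max_mismatches = 0L) {
  out <- vector("list", length(anchors))
  for (i in seq_along(anchors)) {
    if (max_mismatches == 0L) {
      m <- locate_fixed_all(sequence, anchors[i])
      if (nrow(m) > 0L) {
        out[[i]] <- tibble::tibble(anchor = i, start = m[, 1], end = m[, 2])
      }
    } else {
      m <- Biostrings::matchPattern(
        anchors[i], Biostrings::DNAString(sequence),
        max.mismatch = max_mismatches, with.indels = FALSE, fixed = TRUE
      )
      if (length(m) > 0L) {
        out[[i]] <- tibble::tibble(
          anchor = i,
          start = Biostrings::start(m), end = Biostrings::end(m)
        )
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    tibble::tibble(anchor = integer(0), start = integer(0), end = integer(0))
  } else {
    dplyr::bind_rows(out)
  }
}

#' Extract locus-spanning reads from a read set
#'
#' Applies [find_anchors()] to every record and tallies rejections by
#' category; every input read is accounted for exactly once.
#'
#' @param reads A tibble with columns `read_id`, `sequence` (e.g. from
#'   [read_fastq()] or [simulate_reads()]), or a path to a FASTQ/FASTA file.
#' @param template A [locus_template()].
#' @param max_mismatches Per-anchor Hamming tolerance (default exact).
#' @return A list of class `extraction` with `anchored` (tibble of accepted,
#'   orientation-normalized reads) and `summary` (tibble `category`, `n`,
#'   with `accepted` plus one row per rejection reason).
#' @export
extract_repeat_reads <- function(reads, template = locus_template(),
                                 max_mismatches = 0L) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- read_sequences(reads)
  }
  reads <- tibble::as_tibble(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  res <- purrr::map2(
    reads$read_id, reads$sequence,
    function(id, s) find_anchors(id, s, template, max_mismatches)
  )
  accepted <- purrr::map_lgl(res, "accepted")
  anchored <- if (any(accepted)) {
    dplyr::bind_rows(purrr::map(res[accepted], "read"))
  } else {
    tibble::tibble(
      read_id = character(0), sequence = character(0),
      was_reverse_complemented = logical(0),
      up_hits = list(), down_hits = list()
    )
  }
  reasons <- purrr::map_chr(res[!accepted], "reason")
  categories <- c(
    "accepted", "empty", "no_anchor", "no_upstream_anchor",
    "no_downstream_anchor", "anchors_out_of_order", "ambiguous_orientation"
  )
  summary <- tibble::tibble(
    category = categories,
    n = unname(c(
      sum(accepted),
      vapply(categories[-1], function(k) sum(reasons == k), integer(1))
    ))
  )
  structure(list(anchored = anchored, summary = summary), class = "extraction")
}
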