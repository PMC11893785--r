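#' Locate the flank/repeat junction 20-mers in a read
#'
#' Repeat sizing is junction-based: read errors inside a low-complexity
#' tract make base-level alignment unreliable, so the tract is delimited by
#' exact matches of two 20-mers spanning the flank/repeat boundaries. On
#' multiple matches the last upstream and first downstream junction are
#' taken, maximizing the enclosed tract against spurious internal matches.
#'
#' @param sequence Orientation-normalized read sequence.
#' @param template A [locus_template()].
#' @return A list: `ok` (logical); on success `junction_up_end` (0-based
#'   exclusive end of the upstream junction match) and `junction_down_start`
#'   (0-based start of the downstream junction match); on failure `reason`
#'   (`"no_upstream_junction"`, `"no_downstream_junction"`, or
#'   `"inverted_junctions"`).
#' @export
locate_junctions <- function(sequence, template) {
  up <- locate_fixed_all(sequence, template$junction_up)
  down <- locate_fixed_all(sequence, template$junction_down)
  if (nrow(up) == 0L) {
    return(list(ok = FALSE, reason = "no_upstream_junction"))
  }
  if (nrow(down) == 0L) {
    return(list(ok = FALSE, reason = "no_downstream_junction"))
  }
  jue <- up[nrow(up), 2]        # 1-based inclusive end == 0-based exclusive end
  jds <- down[1, 1] - 1L        # 0-based start
  if (jds < jue) {
    return(list(ok = FALSE, reason = "inverted_junctions"))
  }
  list(ok = TRUE, junction_up_end = as.integer(jue), junction_down_start = as.integer(jds))
}

#' Repeat-unit count from junction coordinates
#'
#' The distance between the junction points, in trinucleotide units, plus
#' the three units consumed by the junction 20-mers themselves (one GAA
#' inside the upstream junction, two inside the downstream junction under
#' the template convention). Rounding is nearest integer, ties to even, so
#' indel errors that shift the gap off a multiple of three still size to the
#' nearest unit.
#'
#' @param junction_up_end 0-based exclusive end of the upstream junction.
#' @param junction_down_start 0-based start of the downstream junction.
#' @return Integer unit count (vectorized).
#' @examples
#' count_units(82, 82 + 798) # 269
#' @export
count_units <- function(junction_up_end, junction_down_start) {
  gap <- junction_down_start - junction_up_end
  if (any(gap < 0)) stop("negative junction gap", call. = FALSE)
  as.integer(round(gap / 3) + 3L)
}

#' Decompose a repeat tract into motif tokens
#'
#' Greedy left-to-right longest-match over the six-motif lexicon (ties
#' between the two 9-nt motifs broken by lexicon order, (GCA)2GAA first).
#' Positions matching no motif emit single-nucleotide `NOISE` tokens. Token
#' spans tile the tract exactly, with no gaps or overlaps.
#'
#' @param sequence The tract substring (junction-inclusive; see
#'   [profile_read()]).
#' @param template A [locus_template()].
#' @return A tibble with columns `motif` (lexicon string or `"NOISE"`),
#'   `start`, `end` (0-based half-open, tract-relative).
#' @export
tokenize_tract <- function(sequence, template = locus_template()) {
  d <- .tokenize_greedy(sequence, template$motif_lexicon)
  tibble::tibble(
    motif = c("NOISE", template$motif_lexicon)[d$motif_index + 1L],
    start = d$start,
    end = d$end
  )
}

#' Terminal and longest pure-GAA runs of a token list
#'
#' A run is a maximal stretch of GAA tokens in which isolated noise of at
#' most two consecutive nucleotides does not break the run (sequencing
#' mismatches inside genuinely pure tracts are common); any other motif
#' token, or three or more consecutive noise nucleotides, ends it. Runs are
#' measured in units (noise nucleotides inside a run contribute nothing).
#'
#' @param tokens A token tibble from [tokenize_tract()].
#' @return A list with `upstream_run_units` (units of the run anchored at
#'   the tract start, else 0), `downstream_run_units` (anchored at the tract
#'   end, else 0), and `longest_run_units` (maximum anywhere).
#' @export
terminal_runs <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0L) {
    return(list(
      upstream_run_units = 0L, downstream_run_units = 0L,
      longest_run_units = 0L
    ))
  }
  type <- ifelse(tokens$motif == "GAA", "G", ifelse(tokens$motif == "NOISE", "N", "M"))
  # break at motif tokens and at >=3 consecutive noise nt
  brk <- type == "M"
  r <- rle(type)
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$values)) {
    if (r$values[i] == "N" && r$lengths[i] >= 3L) {
      brk[pos[i]:(pos[i + 1L] - 1L)] <- TRUE
    }
  }
  seg <- cumsum(c(TRUE, diff(brk) != 0L))
  units <- integer(0)
  starts_at_0 <- logical(0)
  ends_at_n <- logical(0)
  for (s in split(seq_len(n), seg)) {
    if (any(brk[s])) next
    g <- sum(type[s] == "G")
    if (g == 0L) next
    units <- c(units, g)
    starts_at_0 <- c(starts_at_0, s[1] == 1L)
    ends_at_n <- c(ends_at_n, s[length(s)] == n)
  }
  list(
    upstream_run_units = if (length(units) > 0L && starts_at_0[1]) units[1] else 0L,
    downstream_run_units = if (length(units) > 0L && ends_at_n[length(units)]) units[length(units)] else 0L,
    longest_run_units = if (length(units) > 0L) max(units) else 0L
  )
}

#' Profile a single locus-spanning read
#'
#' Locates the junction 20-mers, sizes the repeat, tokenizes the
#' junction-inclusive tract (spanning from three nucleotides before the
#' upstream junction end to six nucleotides after the downstream junction
#' start, so the tract is exactly `3 * unit_count` nt for error-free pure
#' reads), and measures purity and terminal runs.
#'
#' @param sequence Orientation-normalized read sequence.
#' @param template A [locus_template()].
#' @return A list with junction coordinates, `unit_count`, `tract_length`,
#'   `tokens` (tibble), `purity` (GAA nt over all motif nt), noise
#'   fraction and run lengths; or `list(ok = FALSE, reason = ...)`.
#' @export
profile_read <- function(sequence, template = locus_template()) {
  j <- locate_junctions(sequence, template)
  if (!j$ok) {
    return(j)
  }
  tract_start <- j$junction_up_end - 3L # 0-based
  tract_end <- j$junction_down_start + 6L
  tract <- substring(sequence, tract_start + 1L, tract_end)
  tokens <- tokenize_tract(tract, template)
  widths <- tokens$end - tokens$start
  motif_nt <- sum(widths[tokens$motif != "NOISE"])
  gaa_nt <- sum(widths[tokens$motif == "GAA"])
  noise_nt <- sum(widths[tokens$motif == "NOISE"])
  runs <- terminal_runs(tokens)
  c(
    list(
      ok = TRUE,
      junction_up_end = j$junction_up_end,
      junction_down_start = j$junction_down_start,
      unit_count = count_units(j$junction_up_end, j$junction_down_start),
      tract_length = nchar(tract),
      tokens = tokens,
      purity = if (motif_nt > 0L) gaa_nt / motif_nt else NA_real_,
      noise_fraction = if (nchar(tract) > 0L) noise_nt / nchar(tract) else 0
    ),
    runs
  )
}

#' Profile every anchored read of a sample
#'
#' @param anchored An `extraction` object from [extract_repeat_reads()], or
#'   its `anchored` tibble.
#' @param template A [locus_template()].
#' @return A tibble with one row per anchored read: `read_id`, junction
#'   coordinates, `unit_count`, `tract_length`, `purity`, `noise_fraction`,
#'   run lengths, `snp_base` (read base at the template-aligned SNP site,
#'   localized by offset from the nearest upstream anchor match), `tokens`
#'   (list-column), `sized` (logical) and `fail_reason` for reads whose
#'   junctions were not found.
#' @export
profile_reads <- function(anchored, template = locus_template()) {
  if (inherits(anchored, "extraction")) anchored <- anchored$anchored
  empty <- tibble::tibble(
    read_id = character(0), junction_up_end = integer(0),
    junction_down_start = integer(0), unit_count = integer(0),
    tract_length = integer(0), purity = double(0), noise_fraction = double(0),
    upstream_run_units = integer(0), downstream_run_units = integer(0),
    longest_run_units = integer(0), snp_base = character(0),
    tokens = list(), sized = logical(0), fail_reason = character(0)
  )
  if (nrow(anchored) == 0L) {
    return(empty)
  }
  rows <- purrr::pmap(
    list(anchored$read_id, anchored$sequence, anchored$up_hits),
    function(id, s, up_hits) {
      p <- profile_read(s, template)
      snp <- snp_base_from_read(s, up_hits, template)
      if (!p$ok) {
        return(tibble::tibble(
          read_id = id, junction_up_end = NA_integer_,
          junction_down_start = NA_integer_, unit_count = NA_integer_,
          tract_length = NA_integer_, purity = NA_real_,
          noise_fraction = NA_real_, upstream_run_units = NA_integer_,
          downstream_run_units = NA_integer_, longest_run_units = NA_integer_,
          snp_base = snp, tokens = list(NULL), sized = FALSE,
          fail_reason = p$reason
        ))
      }
      tibble::tibble(
        read_id = id, junction_up_end = p$junction_up_end,
        junction_down_start = p$junction_down_start,
        unit_count = p$unit_count, tract_length = p$tract_length,
        purity = p$purity, noise_fraction = p$noise_fraction,
        upstream_run_units = p$upstream_run_units,
        downstream_run_units = p$downstream_run_units,
        longest_run_units = p$longest_run_units, snp_base = snp,
        tokens = list(p$tokens), sized = TRUE, fail_reason = NA_character_
      )
    }
  )
  dplyr::bind_rows(rows)
}

# read base at the SNP site, localized by offset from the upstream anchor
# match nearest to the site (anchor-relative, no global alignment); NA when
# no anchor hit or the position falls outside the read
snp_base_from_read <- function(sequence, up_hits, template) {
  if (is.null(up_hits) || nrow(up_hits) == 0L) {
    return(NA_character_)
  }
  offs <- template$up_anchor_offsets[up_hits$anchor]
  dist <- abs(template$snp_offset - offs)
  best <- which.min(dist)
  pos <- up_hits$start[best] + (template$snp_offset - offs[best]) # 1-based
  if (pos < 1L || pos > nchar(sequence)) {
    return(NA_character_)
  }
  b <- substring(sequence, pos, pos)
  if (b %in% c("A", "C", "G", "T")) b else NA_character_
}

#' Select the uniform-length read population
#'
#' Amplicon read sets occasionally show a broad tract-length distribution
#' (shattered or artifactual reads); sizing uses the dense cluster of
#' near-identical lengths. Sorted tract lengths are first split into
#' candidate allele populations at inter-read gaps of at least
#' `3 * gap_units` nt; within each population a window of width
#' `max(window_min_nt, window_frac * median length)` slides over the
#' lengths and the window holding the most reads wins (ties: lower length
#' variance, then shorter median, then smaller lower edge). Populations
#' whose best window holds fewer than `min_reads` reads are discarded.
#' Selection depends only on the multiset of lengths, not on input order.
#'
#' @param profiles A profile tibble from [profile_reads()] (unsized rows
#'   are dropped).
#' @param window_min_nt,window_frac Window rule (defaults 12 nt, 1%).
#' @param gap_units Population split threshold in repeat units.
#' @param min_reads Minimum reads per retained population.
#' @return A list: `selected` (profile tibble), `n_discarded`.
#' @export
select_uniform_region <- function(profiles, window_min_nt = 12, window_frac = 0.01,
                                  gap_units = 10, min_reads = 3L) {
  profiles <- profiles[profiles$sized %in% TRUE, , drop = FALSE]
  n_in <- nrow(profiles)
  if (n_in == 0L) {
    return(list(selected = profiles, n_discarded = 0L))
  }
  ord <- order(profiles$tract_length, profiles$read_id)
  lens <- profiles$tract_length[ord]
  pop <- cumsum(c(1L, diff(lens) >= 3 * gap_units))
  keep_idx <- integer(0)
  for (p in unique(pop)) {
    idx <- ord[pop == p]
    pl <- profiles$tract_length[idx]
    w <- max(window_min_nt, window_frac * stats::median(pl))
    starts <- sort(unique(pl))
    best <- NULL
    for (L in starts) {
      inside <- idx[pl >= L & pl <= L + w]
      cand <- list(
        n = length(inside),
        var = if (length(inside) > 1L) stats::var(profiles$tract_length[inside]) else 0,
        med = stats::median(profiles$tract_length[inside]),
        L = L, inside = inside
      )
      if (is.null(best) ||
        cand$n > best$n ||
        (cand$n == best$n && cand$var < best$var) ||
        (cand$n == best$n && cand$var == best$var && cand$med < best$med)) {
        best <- cand
      }
    }
    if (best$n >= min_reads) keep_idx <- c(keep_idx, best$inside)
  }
  selected <- profiles[sort(keep_idx), , drop = FALSE]
  list(selected = selected, n_discarded = n_in - nrow(selected))
}

#' Cluster selected reads into diploid allele calls
#'
#' Unit counts are sorted and split at the largest inter-read gap when that
#' gap reaches `split_gap_units` (supporting compound heterozygotes whose
#' two products both amplify), else all reads form one allele. Clusters
#' smaller than `min_reads` are dropped with a warning count. Allele
#' summaries are medians across the cluster's reads; the per-allele SNP
#' base requires coverage of at least 3 informative reads and an 80%
#' majority, else `"unknown"`.
#'
#' @param profiles Selected profile tibble (see [select_uniform_region()]).
#' @param split_gap_units Minimum unit gap separating two alleles.
#' @param min_reads Minimum reads per reported allele.
#' @return A list: `alleles` (tibble with `allele_index`, `n_reads`,
#'   `unit_count_median`, `unit_min`, `unit_max`, `purity`, run medians,
#'   `snp_base`), `n_dropped_reads`.
#' @export
cluster_alleles <- function(profiles, split_gap_units = 10, min_reads = 3L) {
  profiles <- profiles[profiles$sized %in% TRUE, , drop = FALSE]
  empty <- tibble::tibble(
    allele_index = integer(0), n_reads = integer(0),
    unit_count_median = double(0), unit_min = integer(0), unit_max = integer(0),
    purity = double(0), upstream_run_units = double(0),
    downstream_run_units = double(0), longest_run_units = double(0),
    snp_base = character(0)
  )
  if (nrow(profiles) == 0L) {
    return(list(alleles = empty, n_dropped_reads = 0L))
  }
  ord <- order(profiles$unit_count, profiles$read_id)
  u <- profiles$unit_count[ord]
  cluster <- rep(1L, length(u))
  if (length(u) > 1L) {
    gaps <- diff(u)
    gmax <- which.max(gaps)
    if (gaps[gmax] >= split_gap_units) {
      cluster[(gmax + 1L):length(u)] <- 2L
    }
  }
  calls <- list()
  dropped <- 0L
  for (k in unique(cluster)) {
    idx <- ord[cluster == k]
    if (length(idx) < min_reads) {
      dropped <- dropped + length(idx)
      next
    }
    cl <- profiles[idx, ]
    calls[[length(calls) + 1L]] <- tibble::tibble(
      n_reads = nrow(cl),
      unit_count_median = stats::median(cl$unit_count),
      unit_min = min(cl$unit_count), unit_max = max(cl$unit_count),
      purity = stats::median(cl$purity),
      upstream_run_units = stats::median(cl$upstream_run_units),
      downstream_run_units = stats::median(cl$downstream_run_units),
      longest_run_units = stats::median(cl$longest_run_units),
      snp_base = snp_majority(cl$snp_base)
    )
  }
  if (dropped > 0L) {
    warning(dropped, " read(s) in cluster(s) below min_reads dropped", call. = FALSE)
  }
  if (length(calls) == 0L) {
    return(list(alleles = empty, n_dropped_reads = dropped))
  }
  alleles <- dplyr::bind_rows(calls)
  alleles <- alleles[order(alleles$unit_count_median), , drop = FALSE]
  alleles <- dplyr::bind_cols(
    tibble::tibble(allele_index = seq_len(nrow(alleles))), alleles
  )
  list(alleles = alleles, n_dropped_reads = dropped)
}

# majority base with >= 80% agreement and coverage >= 3, else "unknown"
snp_majority <- function(bases, min_cov = 3L, min_frac = 0.8) {
  bases <- bases[!is.na(bases)]
  if (length(bases) < min_cov) {
    return("unknown")
  }
  tab <- sort(table(bases), decreasing = TRUE)
  if (tab[1] / length(bases) < min_frac) {
    return("unknown")
  }
  names(tab)[1]
}

#' Waterfall export of read decompositions
#'
#' Lossless long-format export of every selected read's motif tokens, with
#' reads ordered by ascending tract length (stable by read id) as they
#' appear in a waterfall plot.
#'
#' @param profiles A profile tibble from [profile_reads()].
#' @return A tibble: `read_id`, `read_rank`, `start`, `end` (tract-relative,
#'   0-based half-open), `motif`.
#' @export
waterfall_matrix <- function(profiles) {
  profiles <- profiles[profiles$sized %in% TRUE, , drop = FALSE]
  if (nrow(profiles) == 0L) {
    return(tibble::tibble(
      read_id = character(0), read_rank = integer(0),
      start = integer(0), end = integer(0), motif = character(0)
    ))
  }
  ord <- order(profiles$tract_length, profiles$read_id)
  profiles <- profiles[ord, ]
  out <- purrr::map2(
    profiles$read_id, seq_len(nrow(profiles)),
    function(id, rank) {
      tok <- profiles$tokens[[rank]]
      tibble::tibble(
        read_id = id, read_rank = rank,
        start = tok$start, end = tok$end, motif = tok$motif
      )
    }
  )
  dplyr::bind_rows(out)
}
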