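#' HiFi-like per-base error model
#'
#' Substitutions, insertions and deletions are applied independently and
#' uniformly per base; there is no homopolymer weighting, which is adequate
#' at the low error rates typical of circular-consensus reads.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in \[0, 0.1\].
#' @param seed Optional integer; when set, `simulate_reads()` seeds the RNG
#'   with it so the same reads are produced on every call.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0, ins_rate = 0, del_rate = 0, seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 0.1)) {
    stop("error rates must lie in [0, 0.1]", call. = FALSE)
  }
  structure(
    list(
      sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "error_model"
  )
}

BASES <- c("A", "C", "G", "T")

# apply one read's worth of errors; consumes RNG only when a rate is nonzero
apply_read_errors <- function(seq, em) {
  if (em$sub_rate == 0 && em$ins_rate == 0 && em$del_rate == 0) {
    return(seq)
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  keep <- stats::runif(n) >= em$del_rate
  sub <- stats::runif(n) < em$sub_rate
  ins <- stats::runif(n) < em$ins_rate
  if (any(sub & keep)) {
    idx <- which(sub & keep)
    # substitute with a uniformly chosen different base
    ch[idx] <- vapply(
      ch[idx],
      function(b) sample(setdiff(BASES, b), 1L),
      character(1),
      USE.NAMES = FALSE
    )
  }
  out <- ch
  if (any(ins)) {
    ins_base <- character(n)
    ins_base[ins] <- sample(BASES, sum(ins), replace = TRUE)
    out <- ifelse(ins, paste0(ch, ins_base), ch)
  }
  paste(out[keep], collapse = "")
}

#' Simulate long reads from one allele sequence
#'
#' Each read is the full allele sequence with independent per-base errors
#' applied, then reverse-complemented with probability 1/2. Read ids encode
#' the allele label and strand after a `"|"` separator for truth tracking;
#' downstream stages never parse that metadata.
#'
#' @param allele_seq Nucleotide string (see [build_allele_sequence()]).
#' @param depth Number of reads (>= 0).
#' @param em An [error_model()]; if it carries a seed the RNG is seeded
#'   before simulation, making the output reproducible.
#' @param read_prefix Prefix for read ids (the part before `"|"`).
#' @param label Allele label recorded after `"|"`.
#' @return A tibble with columns `read_id`, `sequence`.
#' @examples
#' tpl <- locus_template()
#' seq <- build_allele_sequence(tpl, allele_config(list(c("GAA", 50))))
#' simulate_reads(seq, 3, error_model(seed = 1))
#' @export
simulate_reads <- function(allele_seq, depth, em = error_model(),
                           read_prefix = "read", label = "") {
  stopifnot(depth >= 0)
  if (!is.null(em$seed)) set.seed(em$seed)
  if (depth == 0L) {
    return(tibble::tibble(read_id = character(0), sequence = character(0)))
  }
  flip <- stats::runif(depth) < 0.5
  seqs <- vapply(seq_len(depth), function(i) apply_read_errors(allele_seq, em),
    character(1)
  )
  seqs[flip] <- reverse_complement(seqs[flip])
  tibble::tibble(
    read_id = sprintf(
      "%s_%04d|allele=%s;strand=%s", read_prefix, seq_len(depth),
      label, ifelse(flip, "-", "+")
    ),
    sequence = seqs
  )
}

#' Gel size selection of LR-PCR products
#'
#' Models the preparative agarose-gel step: products with mobilities of more
#' than 750 bp are excised for sequencing. A 200-unit tract plus the 150 bp
#' of flank is exactly 750 bp and is therefore excluded; 201 units (753 bp)
#' is the smallest included pure product.
#'
#' @param product_length_nt Non-negative integer product length(s) in nt.
#' @param gel_bp Cutoff in bp (default 750).
#' @return Logical vector: `TRUE` iff `product_length_nt > gel_bp`.
#' @examples
#' gel_select(3 * 200 + 150) # FALSE, boundary excluded
#' gel_select(3 * 201 + 150) # TRUE
#' @export
gel_select <- function(product_length_nt, gel_bp = 750) {
  stopifnot(all(product_length_nt >= 0))
  product_length_nt > gel_bp
}

#' Specify a synthetic cohort
#'
#' @param genotypes A data frame with columns `group`, `n` (individuals in
#'   the group; constant within a group), `allele1`, `allele2` (names into
#'   `alleles`), and either `count` (individuals carrying the genotype;
#'   counts sum to `n` per group) or `freq` (frequencies summing to 1).
#' @param alleles Named list of [allele_config()] objects.
#' @param depth_range Integer `(min, max)` reads simulated per amplified
#'   allele; the default (20, 200) is a desk-scale reduction of the
#'   per-individual read counts seen in amplicon HiFi runs.
#' @param seed Integer seed governing all randomness in [simulate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(genotypes, alleles, depth_range = c(20L, 200L),
                        seed = 1L) {
  genotypes <- tibble::as_tibble(genotypes)
  stopifnot(all(c("group", "n", "allele1", "allele2") %in% names(genotypes)))
  if (!("count" %in% names(genotypes)) && !("freq" %in% names(genotypes))) {
    stop("genotypes needs a 'count' or 'freq' column", call. = FALSE)
  }
  missing_alleles <- setdiff(
    unique(c(genotypes$allele1, genotypes$allele2)), names(alleles)
  )
  if (length(missing_alleles) > 0L) {
    stop("genotypes reference unknown alleles: ",
      paste(missing_alleles, collapse = ", "),
      call. = FALSE
    )
  }
  for (g in split(genotypes, genotypes$group)) {
    if (length(unique(g$n)) != 1L) stop("'n' must be constant within a group", call. = FALSE)
    if ("count" %in% names(g)) {
      if (sum(g$count) != g$n[1]) {
        stop("genotype counts must sum to n in group '", g$group[1], "'", call. = FALSE)
      }
    } else if (abs(sum(g$freq) - 1) > 1e-8) {
      stop("genotype frequencies must sum to 1 in group '", g$group[1], "'", call. = FALSE)
    }
  }
  stopifnot(length(depth_range) == 2L, depth_range[1] >= 0, depth_range[2] >= depth_range[1])
  structure(
    list(
      genotypes = genotypes, alleles = alleles,
      depth_range = as.integer(depth_range), seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Simulate a diploid cohort of locus reads
#'
#' Generates, for every individual, reads from each of its two alleles. In
#' `"amplicon"` mode an allele contributes reads only if its product passes
#' [gel_select()] (or carries a `gel_override`), emulating preparative gel
#' excision of LR-PCR products; in `"wgs"` mode every allele contributes
#' reads (pre-extracted locus-spanning reads from PCR-free sequencing).
#'
#' All randomness flows from `spec$seed`. With `exact_counts = TRUE` (and a
#' `count` column in the cohort spec) genotypes are assigned deterministically by
#' quota; otherwise they are sampled from the `freq`/`count`-implied
#' frequencies. Per-allele depths are drawn uniformly from `depth_range`
#' unless `depth` fixes them.
#'
#' @param spec A [cohort_spec()].
#' @param template A [locus_template()].
#' @param mode `"amplicon"` or `"wgs"`.
#' @param exact_counts Assign genotypes by exact quota instead of sampling.
#' @param depth Optional fixed per-allele depth overriding `depth_range`.
#' @return A list of class `cohort_sim` with elements `reads` (tibble:
#'   `sample`, `read_id`, `sequence`), `truth` (one row per individual:
#'   sample, group, per-allele label/units/GAA units/longest run/SNP base/
#'   amplified flag, and `snp_genotype`), and `mode`.
#' @export
simulate_cohort <- function(spec, template = locus_template(),
                            mode = c("amplicon", "wgs"),
                            exact_counts = FALSE, depth = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  # per-allele cached properties
  seq_cache <- lapply(spec$alleles, function(cfg) build_allele_sequence(template, cfg))
  units <- vapply(spec$alleles, allele_units, integer(1))
  gaa <- vapply(spec$alleles, allele_gaa_units, integer(1))
  runs <- vapply(spec$alleles, allele_longest_run, integer(1))
  snp <- vapply(spec$alleles, function(a) a$snp_allele, character(1))
  override <- vapply(spec$alleles, function(a) a$gel_override, logical(1))
  amplifies <- function(name) {
    mode == "wgs" || gel_select(nchar(seq_cache[[name]])) || override[[name]]
  }

  truth <- list()
  reads <- list()
  for (grp in unique(spec$genotypes$group)) {
    g <- spec$genotypes[spec$genotypes$group == grp, ]
    n <- g$n[1]
    if (n == 0L) next
    if (exact_counts) {
      if (!("count" %in% names(g))) {
        stop("exact_counts requires a 'count' column", call. = FALSE)
      }
      assign_idx <- rep(seq_len(nrow(g)), times = g$count)
    } else {
      w <- if ("count" %in% names(g)) g$count else g$freq
      assign_idx <- sample(seq_len(nrow(g)), n, replace = TRUE, prob = w)
    }
    for (i in seq_len(n)) {
      row <- g[assign_idx[i], ]
      sample_id <- sprintf("%s_%04d", gsub("[^A-Za-z0-9]+", "-", grp), i)
      a1 <- row$allele1
      a2 <- row$allele2
      amp1 <- amplifies(a1)
      amp2 <- amplifies(a2)
      d1 <- if (!is.null(depth)) depth else sample(spec$depth_range[1]:spec$depth_range[2], 1L)
      d2 <- if (!is.null(depth)) depth else sample(spec$depth_range[1]:spec$depth_range[2], 1L)
      ind_reads <- list()
      if (amp1 && d1 > 0L) {
        ind_reads[[1]] <- simulate_reads(
          seq_cache[[a1]], d1, spec$error_model %||% error_model(),
          read_prefix = paste0(sample_id, ".a1"), label = a1
        )
      }
      if (amp2 && d2 > 0L) {
        ind_reads[[2]] <- simulate_reads(
          seq_cache[[a2]], d2, spec$error_model %||% error_model(),
          read_prefix = paste0(sample_id, ".a2"), label = a2
        )
      }
      if (length(ind_reads) > 0L) {
        r <- dplyr::bind_rows(ind_reads)
        r$sample <- sample_id
        reads[[length(reads) + 1L]] <- r
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample = sample_id, group = grp,
        allele1 = a1, allele1_units = units[[a1]], allele1_gaa = gaa[[a1]],
        allele1_run = runs[[a1]], allele1_snp = snp[[a1]], allele1_amplified = amp1,
        allele2 = a2, allele2_units = units[[a2]], allele2_gaa = gaa[[a2]],
        allele2_run = runs[[a2]], allele2_snp = snp[[a2]], allele2_amplified = amp2,
        snp_genotype = paste(sort(c(snp[[a1]], snp[[a2]]), decreasing = TRUE),
          collapse = "/"
        )
      )
    }
  }
  reads <- if (length(reads) > 0L) {
    dplyr::bind_rows(reads)[, c("sample", "read_id", "sequence")]
  } else {
    tibble::tibble(sample = character(0), read_id = character(0), sequence = character(0))
  }
  structure(
    list(reads = reads, truth = dplyr::bind_rows(truth), mode = mode),
    class = "cohort_sim"
  )
}

#' Set an error model on a cohort spec
#'
#' @param spec A [cohort_spec()].
#' @param em An [error_model()] applied to every simulated read (its own
#'   seed field is ignored; the cohort seed governs).
#' @return The modified spec.
#' @export
with_error_model <- function(spec, em) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(em, "error_model"))
  em$seed <- NULL
  spec$error_model <- em
  spec
}
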