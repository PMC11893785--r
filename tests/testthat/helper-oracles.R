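# Shared fixtures and independent oracles.

TPL <- locus_template()

pure_allele <- function(n, snp = "T") {
  allele_config(list(c("GAA", n)), snp, paste0("pure_", n))
}

# complex tract whose greedy tokenization reproduces the blocks exactly:
# terminal interrupt is (GCA)2GAA, which greedy cannot extend into GCA(GAA)4
complex_allele <- function(up, down, n_interrupt = 40, snp = "A") {
  allele_config(
    list(
      c("GAA", up), c("GCAGAA", n_interrupt), c("GCAGCAGAA", 1),
      c("GAA", down)
    ),
    snp, sprintf("cx_%d_%d", up, down)
  )
}

# minimal-NOISE tiling by dynamic programming over suffixes; ties broken by
# preferring the earliest lexicon motif (longest first), then noise. On
# error-free motif concatenations this equals greedy longest-match.
dp_tokenize <- function(seq, motifs = TPL$motif_lexicon) {
  n <- nchar(seq)
  if (n == 0L) {
    return(tibble::tibble(motif = character(0), start = integer(0), end = integer(0)))
  }
  lens <- nchar(motifs)
  cost <- c(rep(NA_real_, n), 0) # cost[i] = min noise nt tiling seq[i..n]
  choice <- integer(n) # 0 = noise, else motif index
  for (i in n:1) {
    best_cost <- cost[i + 1L] + 1
    best_choice <- 0L
    for (m in seq_along(motifs)) {
      j <- i + lens[m]
      if (j <= n + 1L && substring(seq, i, j - 1L) == motifs[m]) {
        if (cost[j] < best_cost) {
          best_cost <- cost[j]
          best_choice <- m
        }
      }
    }
    cost[i] <- best_cost
    choice[i] <- best_choice
  }
  out_motif <- character(0)
  out_start <- integer(0)
  out_end <- integer(0)
  i <- 1L
  while (i <= n) {
    if (choice[i] == 0L) {
      out_motif <- c(out_motif, "NOISE")
      out_start <- c(out_start, i - 1L)
      out_end <- c(out_end, i)
      i <- i + 1L
    } else {
      out_motif <- c(out_motif, motifs[choice[i]])
      out_start <- c(out_start, i - 1L)
      i <- i + lens[choice[i]]
      out_end <- c(out_end, i - 1L)
    }
  }
  tibble::tibble(motif = out_motif, start = out_start, end = out_end)
}

# random concatenation of <= max_blocks motif blocks
random_motif_concat <- function(max_blocks = 20L) {
  k <- sample(1:max_blocks, 1L)
  paste(sample(TPL$motif_lexicon, k, replace = TRUE), collapse = "")
}

# two-sided Fisher p by explicit hypergeometric enumeration (dhyper-based,
# an independent code path from the package's log-space implementation)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  x <- max(0, k - n2):min(k, m)
  dens <- stats::dhyper(x, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

# minimal profile rows for selection/clustering tests
fake_profiles <- function(unit_counts, read_ids = NULL, snp = "T",
                          purity = 1, runs = NULL) {
  n <- length(unit_counts)
  runs <- runs %||% unit_counts
  tibble::tibble(
    read_id = read_ids %||% sprintf("r%03d", seq_len(n)),
    junction_up_end = 82L, junction_down_start = 82L + 3L * (unit_counts - 3L),
    unit_count = as.integer(unit_counts),
    tract_length = 3L * as.integer(unit_counts),
    purity = purity, noise_fraction = 0,
    upstream_run_units = as.integer(runs), downstream_run_units = as.integer(runs),
    longest_run_units = as.integer(runs),
    snp_base = snp, tokens = replicate(n, NULL, simplify = FALSE),
    sized = TRUE, fail_reason = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
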