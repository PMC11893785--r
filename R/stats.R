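#' Cohort frequency table of expanded-repeat categories
#'
#' Aggregates per-individual calls into the per-group table of expanded
#' repeat categories: pure GAA expansions of >= 250 units, 200-249 units
#' and < 200 units, and complex configurations with embedded pure-GAA runs
#' of >= 100 or < 100 units. An individual with two expanded alleles is
#' counted once, under its highest-priority category (the order just
#' given); the reported unit value is the allele size for pure categories
#' and the longest embedded run for complex ones. The `lrpcr_positive` row
#' counts individuals contributing to any category and equals the category
#' sum by construction. Percentages are counts over group size, rounded
#' half-up to one decimal.
#'
#' @param calls Call tibble from [call_cohort()].
#' @param thresholds A [classification_thresholds()].
#' @param groups Optional expected group labels; calls with a group outside
#'   this set raise an error, and the output preserves this order.
#' @param min_units Optional floor (repeat units) an allele must reach to
#'   enter the table; the default `NULL` counts every called allele, which
#'   is the correct rule when the simulated/sequenced library was gel
#'   selected. For `"wgs"`-mode inputs, where wild-type alleles are also
#'   called, pass a floor such as `thresholds$gel_bp` converted to units.
#' @return A tibble of class `cohort_table`: `group`, `n`, `category`,
#'   `count`, `pct`, `unit_min`, `unit_max`.
#' @export
frequency_table <- function(calls, thresholds = classification_thresholds(),
                            groups = NULL, min_units = NULL) {
  calls <- tibble::as_tibble(calls)
  if (!is.null(groups)) {
    bad <- setdiff(unique(calls$group), groups)
    if (length(bad) > 0L) {
      stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    groups <- unique(calls$group)
  }
  categories <- c(
    "pure_ge250", "pure_200_249", "pure_lt200",
    "complex_run_ge100", "complex_run_lt100"
  )

  # long allele table: one row per called allele
  long <- dplyr::bind_rows(
    dplyr::transmute(calls,
      sample = .data$sample, group = .data$group,
      units = .data$allele1_units, run = .data$allele1_run,
      class = .data$allele1_class
    ),
    dplyr::transmute(calls,
      sample = .data$sample, group = .data$group,
      units = .data$allele2_units, run = .data$allele2_run,
      class = .data$allele2_class
    )
  )
  long <- long[!is.na(long$units), , drop = FALSE]
  if (!is.null(min_units)) long <- long[long$units >= min_units, , drop = FALSE]
  long$category <- character(nrow(long))
  long$value <- numeric(nrow(long))
  if (nrow(long) > 0L) {
    long$category <- ifelse(
      long$class == "PURE" & long$units >= thresholds$incomplete_min, "pure_ge250",
      ifelse(long$class == "PURE" & long$units >= thresholds$uncertain_min, "pure_200_249",
        ifelse(long$class == "PURE", "pure_lt200",
          ifelse(long$class == "COMPLEX_RUN_GE100", "complex_run_ge100",
            "complex_run_lt100"
          )
        )
      )
    )
    long$priority <- match(long$category, categories)
    long$value <- ifelse(long$class == "PURE", long$units, long$run)
    # one row per individual: its highest-priority allele
    long <- dplyr::slice_min(
      dplyr::group_by(long, .data$sample, .data$group),
      .data$priority,
      n = 1L, with_ties = FALSE
    )
    long <- dplyr::ungroup(long)
  }

  n_per_group <- dplyr::summarise(
    dplyr::group_by(calls, .data$group),
    n = dplyr::n(), .groups = "drop"
  )
  rows <- list()
  for (g in groups) {
    n <- n_per_group$n[n_per_group$group == g]
    sub <- long[long$group == g, , drop = FALSE]
    cat_rows <- purrr::map(categories, function(k) {
      v <- sub$value[sub$category == k]
      tibble::tibble(
        group = g, n = n, category = k, count = length(v),
        pct = round_half_up(100 * length(v) / n, 1L),
        unit_min = if (length(v) > 0L) min(v) else NA_real_,
        unit_max = if (length(v) > 0L) max(v) else NA_real_
      )
    })
    pos <- tibble::tibble(
      group = g, n = n, category = "lrpcr_positive", count = nrow(sub),
      pct = round_half_up(100 * nrow(sub) / n, 1L),
      unit_min = NA_real_, unit_max = NA_real_
    )
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(c(list(pos), cat_rows))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cohort_table", class(out))
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the point-probability ("small-p") method: conditioning on
#' both margins, the p-value is the sum of hypergeometric probabilities of
#' all tables whose point probability does not exceed that of the observed
#' table. Probabilities are computed in log space. The odds ratio is the
#' sample odds ratio ad/bc (infinite when bc = 0 and ad > 0).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (\code{rbind(c(a, b), c(c, d))}).
#' @return An object of class `fisher_exact`: list with `table`,
#'   `odds_ratio`, `p_two_sided`, `method`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' fisher_exact(6, 470, 1, 454)
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all-zero table", call. = FALSE)
  m <- a + b # row 1 total
  n2 <- c + d # row 2 total
  k <- a + c # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k)
  log_obs <- logp[x == a]
  p <- sum(exp(logp[logp <= log_obs + 1e-7]))
  p <- min(1, p)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * c)
  }
  structure(
    list(
      table = matrix(cells, 2L, 2L, byrow = TRUE),
      odds_ratio = or, p_two_sided = p,
      method = "Fisher's exact test (two-sided, point-probability method)"
    ),
    class = "fisher_exact"
  )
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("<fisher_exact> table [", paste(t(x$table), collapse = ", "), "]  OR =",
    format(x$odds_ratio, digits = 4), " p =", format(x$p_two_sided, digits = 4), "\n"
  )
  invisible(x)
}

#' Spearman rank correlation with exact small-sample p
#'
#' Correlation of midranks (ties handled by average ranks). For n <= 8 the
#' two-sided p is exact, from full enumeration of all n! rank permutations
#' (counting permutations with |rho| at least the observed, within 1e-9);
#' for larger n the large-sample normal approximation
#' z = rho * sqrt(n - 1) is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return An object of class `spearman_exact`: list with `rho`, `p`, `n`,
#'   `method`; `rho` is `NA` (with a warning) for constant input. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' spearman_exact(c(57, 60, 64, 66, 69, 71), c(361, 330, 312, 305, 300, 251))
#' @export
spearman_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: rho undefined", call. = FALSE)
    return(structure(
      list(rho = NA_real_, p = NA_real_, n = n, method = "undefined (constant input)"),
      class = "spearman_exact"
    ))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    method <- "exact (full permutation)"
  } else {
    z <- rho * sqrt(n - 1)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(
    list(rho = rho, p = p, n = n, method = method),
    class = "spearman_exact"
  )
}

#' @export
print.spearman_exact <- function(x, ...) {
  cat("<spearman_exact> rho =", format(x$rho, digits = 3),
    " p =", format(x$p, digits = 3), " n =", x$n, paste0("(", x$method, ")"), "\n"
  )
  invisible(x)
}

# all permutations of 1..n as a matrix, n! rows (n <= 8 in practice)
permutations_of <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Sizing bias between amplicon-based and PCR-free repeat sizes
#'
#' Amplicon (LR-PCR) long-read sizing tends to run short of PCR-free WGS
#' sizing of the same allele (PCR artifacts shorten the repeat). This
#' tabulates per-sample differences `wgs - lrpcr` and their range.
#'
#' @param lrpcr Tibble with `sample_id`, `lrpcr_units` (median units by
#'   amplicon sizing); alternatively a single tibble with both unit columns,
#'   in which case `wgs` is omitted.
#' @param wgs Tibble with `sample_id`, `wgs_units`.
#' @return A tibble of class `sizing_bias`: `sample_id`, `lrpcr_units`,
#'   `wgs_units`, `difference`, with a `summary` attribute holding the
#'   min/max difference.
#' @examples
#' sizing_bias(tibble::tibble(
#'   sample_id = c("msa", "ataxia"),
#'   lrpcr_units = c(269, 307), wgs_units = c(283, 318)
#' ))
#' @export
sizing_bias <- function(lrpcr, wgs = NULL) {
  lrpcr <- tibble::as_tibble(lrpcr)
  if (is.null(wgs)) {
    stopifnot(all(c("sample_id", "lrpcr_units", "wgs_units") %in% names(lrpcr)))
    out <- lrpcr
  } else {
    wgs <- tibble::as_tibble(wgs)
    unmatched <- union(
      setdiff(lrpcr$sample_id, wgs$sample_id),
      setdiff(wgs$sample_id, lrpcr$sample_id)
    )
    if (length(unmatched) > 0L) {
      stop("unmatched sample id(s): ", paste(unmatched, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::inner_join(lrpcr, wgs, by = "sample_id")
  }
  out$difference <- out$wgs_units - out$lrpcr_units
  attr(out, "summary") <- c(min = min(out$difference), max = max(out$difference))
  class(out) <- c("sizing_bias", class(out))
  out
}

#' SNP-by-configuration association table
#'
#' Tabulates called expanded alleles by configuration class (pure vs
#' complex) against the base observed at the upstream SNP site, and counts
#' discordant alleles: pure expansions carrying A plus complex
#' configurations carrying T. In cohorts where the A allele tracks complex
#' configurations and T tracks pure expansions, the discordance is zero.
#'
#' @param calls Call tibble from [call_cohort()].
#' @param min_units Optional unit floor for an allele to be tabulated.
#' @return A list: `table` (2x2 integer matrix, class x base), `discordant`
#'   (integer), `alleles` (the tabulated long allele tibble).
#' @export
snp_association <- function(calls, min_units = NULL) {
  calls <- tibble::as_tibble(calls)
  long <- dplyr::bind_rows(
    dplyr::transmute(calls,
      sample = .data$sample, units = .data$allele1_units,
      class = .data$allele1_class, snp = .data$allele1_snp
    ),
    dplyr::transmute(calls,
      sample = .data$sample, units = .data$allele2_units,
      class = .data$allele2_class, snp = .data$allele2_snp
    )
  )
  long <- long[!is.na(long$class) & long$snp %in% c("T", "A"), , drop = FALSE]
  if (!is.null(min_units)) long <- long[long$units >= min_units, , drop = FALSE]
  long$config <- ifelse(long$class == "PURE", "pure", "complex")
  tab <- matrix(0L, 2L, 2L, dimnames = list(c("pure", "complex"), c("T", "A")))
  if (nrow(long) > 0L) {
    t0 <- table(factor(long$config, c("pure", "complex")), factor(long$snp, c("T", "A")))
    tab[] <- as.integer(t0)
  }
  list(
    table = tab,
    discordant = tab["pure", "A"] + tab["complex", "T"],
    alleles = long
  )
}
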