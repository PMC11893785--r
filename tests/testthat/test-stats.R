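fake_call <- function(sample, group, units1 = NA, class1 = NA, run1 = NA,
                      snp1 = NA, units2 = NA, class2 = NA, run2 = NA,
                      snp2 = NA) {
  tibble::tibble(
    sample = sample, group = group,
    allele1_units = units1, allele1_class = class1, allele1_run = run1,
    allele1_snp = snp1,
    allele2_units = units2, allele2_class = class2, allele2_run = run2,
    allele2_snp = snp2
  )
}

test_that("frequency table counts individuals once, by category precedence", {
  calls <- dplyr::bind_rows(
    fake_call("s1", "g", 269, "PURE", 269, "T"),
    fake_call("s2", "g", 212, "PURE", 212, "T"),
    fake_call("s3", "g", 191, "PURE", 191, "T"),
    fake_call("s4", "g", 250, "COMPLEX_RUN_GE100", 134, "A"),
    fake_call("s5", "g", 230, "COMPLEX_RUN_LT100", 55, "A"),
    # compound het: pure >= 250 takes precedence over its complex allele
    fake_call("s6", "g", 312, "PURE", 312, "T", 260, "COMPLEX_RUN_GE100", 167, "A"),
    fake_call("s7", "g"), # no call
    fake_call("s8", "g")
  )
  tab <- frequency_table(calls)
  get <- function(k, col) tab[[col]][tab$category == k]
  expect_equal(get("lrpcr_positive", "count"), 6L)
  expect_equal(get("pure_ge250", "count"), 2L)
  expect_equal(get("pure_200_249", "count"), 1L)
  expect_equal(get("pure_lt200", "count"), 1L)
  expect_equal(get("complex_run_ge100", "count"), 1L)
  expect_equal(get("complex_run_lt100", "count"), 1L)
  # category counts sum to the positive count; percentages recompute
  expect_equal(
    sum(tab$count[tab$category != "lrpcr_positive"]),
    get("lrpcr_positive", "count")
  )
  expect_equal(tab$pct, floor(100 * tab$count / tab$n * 10 + 0.5) / 10,
    tolerance = 1e-9
  )
  # value ranges: pure categories report units, complex report runs
  expect_equal(get("pure_ge250", "unit_min"), 269)
  expect_equal(get("pure_ge250", "unit_max"), 312)
  expect_equal(get("complex_run_ge100", "unit_min"), 134)

  expect_error(frequency_table(calls, groups = "other"), "unknown group")

  empty <- frequency_table(fake_call(c("a", "b"), "g"))
  expect_true(all(empty$count == 0L))
})

test_that("the exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(0, 10, 0, 10)$p_two_sided, 1)
  expect_equal(fisher_exact(5, 0, 0, 5)$p_two_sided, 2 / choose(10, 5),
    tolerance = 1e-12
  )
  expect_equal(fisher_exact(5, 0, 0, 5)$odds_ratio, Inf)
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")

  # exhaustive over small tables
  for (a in 0:6) {
    for (b in 0:6) {
      for (c in 0:6) {
        for (d in 0:6) {
          if (a + b + c + d == 0) next
          expect_equal(
            fisher_exact(a, b, c, d)$p_two_sided,
            fisher_enum_p(a, b, c, d),
            tolerance = 1e-12
          )
        }
      }
    }
  }

  # spot check against the reference implementation on random tables
  set.seed(20)
  for (i in 1:50) {
    t <- sample(0:30, 4, replace = TRUE)
    if (sum(t) == 0) next
    expect_equal(
      fisher_exact(t[1], t[2], t[3], t[4])$p_two_sided,
      stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("spearman correlation is exact for small n and handles ties", {
  r <- spearman_exact(1:6, 6:1)
  expect_equal(r$rho, -1)

  # no-tie case agrees with the reference exact distribution
  set.seed(9)
  for (i in 1:10) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    ours <- spearman_exact(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }

  # hand-computed midrank example: x = 1..4, y = (10, 10, 20, 30)
  tied <- suppressWarnings(spearman_exact(1:4, c(10, 10, 20, 30)))
  expect_equal(tied$rho, 4.5 / sqrt(5 * 4.5), tolerance = 1e-12)

  # sign flip
  set.seed(10)
  x <- rnorm(7)
  y <- rnorm(7)
  a <- spearman_exact(x, y)
  b <- spearman_exact(x, -y)
  expect_equal(a$rho, -b$rho, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_gte(a$p, 0)
  expect_lte(a$p, 1)

  expect_warning(flat <- spearman_exact(rep(1, 5), 1:5), "constant")
  expect_true(is.na(flat$rho))
  expect_error(spearman_exact(1:2, 2:1), "at least 3")

  # large-n path returns a sane two-sided p
  big <- spearman_exact(1:20, c(2:20, 1))
  expect_equal(big$method, "normal approximation")
  expect_gte(big$p, 0)
  expect_lte(big$p, 1)
})

test_that("sizing bias is the per-sample WGS minus amplicon difference", {
  b <- sizing_bias(tibble::tibble(
    sample_id = c("msa", "ataxia", "same"),
    lrpcr_units = c(269, 307, 100),
    wgs_units = c(283, 318, 100)
  ))
  expect_equal(b$difference, c(14, 11, 0))
  expect_equal(unname(attr(b, "summary")), c(0, 14))

  expect_error(
    sizing_bias(
      tibble::tibble(sample_id = "a", lrpcr_units = 1),
      tibble::tibble(sample_id = "b", wgs_units = 2)
    ),
    "unmatched"
  )
})

test_that("SNP association tabulates configuration against the upstream allele", {
  calls <- dplyr::bind_rows(
    fake_call("s1", "g", 269, "PURE", 269, "T"),
    fake_call("s2", "g", 312, "PURE", 312, "T", 260, "COMPLEX_RUN_GE100", 167, "A"),
    fake_call("s3", "g", 230, "COMPLEX_RUN_LT100", 55, "A")
  )
  sa <- snp_association(calls)
  expect_equal(sa$table["pure", "T"], 2L)
  expect_equal(sa$table["complex", "A"], 2L)
  expect_equal(sa$discordant, 0L)

  flipped <- dplyr::bind_rows(calls, fake_call("s4", "g", 280, "PURE", 280, "A"))
  expect_equal(snp_association(flipped)$discordant, 1L)

  none <- snp_association(fake_call("s1", "g"))
  expect_true(all(none$table == 0L))
  expect_equal(none$discordant, 0L)
})

test_that("tidy and glance expose estimates in broom shape", {
  td <- generics::tidy(fisher_exact(6, 470, 1, 454))
  expect_equal(names(td), c("estimate", "p.value", "method"))
  expect_equal(td$estimate, (6 * 454) / (470 * 1), tolerance = 1e-12)
  ts <- generics::tidy(spearman_exact(1:5, c(2, 1, 4, 3, 5)))
  expect_equal(names(ts), c("estimate", "p.value", "n", "method"))
  expect_equal(generics::glance(fisher_exact(1, 2, 3, 4)), generics::tidy(fisher_exact(1, 2, 3, 4)))
})
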