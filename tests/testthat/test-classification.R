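test_that("penetrance bands partition sizes and are monotone", {
  expect_equal(penetrance_band(c(312, 269, 254, 245, 191)), c(
    "FULL", "INCOMPLETE", "INCOMPLETE", "UNCERTAIN", "BELOW"
  ))
  expect_equal(penetrance_band(c(299, 300, 249, 250, 199, 200, 0)), c(
    "INCOMPLETE", "FULL", "UNCERTAIN", "INCOMPLETE", "BELOW", "UNCERTAIN", "BELOW"
  ))
  expect_error(penetrance_band(-1), "non-negative")

  # partition + monotone over a dense grid
  bands <- penetrance_band(0:400)
  expect_true(all(bands %in% c("BELOW", "UNCERTAIN", "INCOMPLETE", "FULL")))
  rank <- match(bands, c("BELOW", "UNCERTAIN", "INCOMPLETE", "FULL"))
  expect_true(all(diff(rank) >= 0))
})

test_that("configuration classes follow purity then embedded-run length", {
  expect_equal(classify_configuration(1, 269), "PURE")
  expect_equal(classify_configuration(0.99, 10), "PURE")
  expect_equal(classify_configuration(0.7, 134), "COMPLEX_RUN_GE100")
  expect_equal(classify_configuration(0.7, 83), "COMPLEX_RUN_LT100")
  expect_equal(classify_configuration(0.7, 100), "COMPLEX_RUN_GE100")
})

test_that("RP-PCR prediction follows the strongest allele's GAA stretch", {
  al <- function(units, run, purity) {
    tibble::tibble(
      unit_count_median = units, longest_run_units = run, purity = purity
    )
  }
  expect_equal(predict_rp_pcr(al(191, 191, 1)), "positive")
  expect_equal(predict_rp_pcr(al(260, 140, 0.7)), "inconclusive")
  expect_equal(predict_rp_pcr(al(280, 167, 0.7)), "inconclusive")
  expect_equal(predict_rp_pcr(al(250, 83, 0.7)), "negative")
  expect_equal(predict_rp_pcr(al(16, 16, 1)), "negative")
  # best across alleles: short pure + long complex run
  both <- dplyr::bind_rows(al(16, 16, 1), al(280, 191, 0.7))
  expect_equal(predict_rp_pcr(both), "positive")
})

test_that("SNP genotyping needs coverage and a clear majority", {
  al <- function(...) tibble::tibble(snp_base = c(...))
  expect_equal(genotype_snp(al("T", "T")), "T/T")
  expect_equal(genotype_snp(al("T", "A")), "T/A")
  expect_equal(genotype_snp(al("A")), "A/A")
  expect_equal(genotype_snp(al("T", "unknown")), "unknown")
  expect_equal(genotype_snp(al()), "unknown")

  # majority rule applied per cluster: 2 informative reads are not enough
  p <- fake_profiles(rep(100L, 5L), snp = c("T", "T", NA, NA, NA))
  cl <- cluster_alleles(p)
  expect_equal(cl$alleles$snp_base, "unknown")
  p2 <- fake_profiles(rep(100L, 5L), snp = c("T", "T", "T", "T", "A"))
  expect_equal(cluster_alleles(p2)$alleles$snp_base, "T")
  p3 <- fake_profiles(rep(100L, 5L), snp = c("T", "T", "T", "A", "A"))
  expect_equal(cluster_alleles(p3)$alleles$snp_base, "unknown")
})

test_that("individual calls compose the pipeline end to end", {
  tpl <- TPL
  cfg <- pipeline_config()
  # MSA-like: wild-type short allele fails the gel, expanded 269 amplifies
  reads_msa <- simulate_reads(
    build_allele_sequence(tpl, pure_allele(269)), 20, error_model(seed = 8),
    "m", "pure_269"
  )
  call <- call_individual(reads_msa, "msa1", "msa", tpl, cfg)
  expect_equal(call$allele1_class, "PURE")
  expect_equal(call$allele1_band, "INCOMPLETE")
  expect_equal(call$allele1_units, 269)
  expect_equal(call$rp_prediction, "positive")
  expect_equal(call$snp_genotype, "T/T")
  expect_equal(call$flags, "")

  # healthy complex carrier with downstream run 140
  reads_h <- simulate_reads(
    build_allele_sequence(tpl, complex_allele(31, 140)), 20, error_model(seed = 9),
    "h", "cx"
  )
  call_h <- call_individual(reads_h, "h1", "healthy", tpl, cfg)
  expect_equal(call_h$allele1_class, "COMPLEX_RUN_GE100")
  expect_equal(call_h$allele1_run, 140)
  expect_equal(call_h$rp_prediction, "inconclusive")
  expect_equal(call_h$snp_genotype, "A/A")

  # compound heterozygote: two amplifying alleles of distinct size
  reads_both <- dplyr::bind_rows(
    simulate_reads(build_allele_sequence(tpl, pure_allele(312)), 15,
      error_model(seed = 10), "p", "pure_312"
    ),
    simulate_reads(build_allele_sequence(tpl, complex_allele(10, 167)), 15,
      error_model(seed = 11), "c", "cx"
    )
  )
  call_b <- call_individual(reads_both, "b1", "ataxia", tpl, cfg)
  expect_equal(call_b$n_alleles, 2L)
  expect_setequal(
    c(call_b$allele1_class, call_b$allele2_class),
    c("PURE", "COMPLEX_RUN_GE100")
  )
  expect_equal(call_b$rp_prediction, "positive")
  expect_equal(call_b$snp_genotype, "T/A")

  # no reads at all
  call_0 <- call_individual(
    tibble::tibble(read_id = character(0), sequence = character(0)),
    "w1", "healthy", tpl, cfg
  )
  expect_equal(call_0$flags, "no_locus_reads")
  expect_equal(call_0$n_alleles, 0L)
  expect_true(is.na(call_0$rp_prediction))
})

test_that("cohort calling requires a complete manifest", {
  tpl <- TPL
  reads <- simulate_reads(
    build_allele_sequence(tpl, pure_allele(260)), 5, error_model(seed = 1), "x", "x"
  )
  reads$sample <- "s1"
  manifest <- tibble::tibble(sample = "other", group = "g")
  expect_error(call_cohort(reads, manifest), "missing in manifest")
})
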