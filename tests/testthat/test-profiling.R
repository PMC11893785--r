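test_that("junction location and unit counting recover constructed sizes", {
  tpl <- TPL
  s <- build_allele_sequence(tpl, pure_allele(269))
  j <- locate_junctions(s, tpl)
  expect_true(j$ok)
  expect_equal(j$junction_down_start - j$junction_up_end, 3L * (269L - 3L))
  expect_equal(count_units(j$junction_up_end, j$junction_down_start), 269L)

  j3 <- locate_junctions(build_allele_sequence(tpl, pure_allele(3)), tpl)
  expect_equal(j3$junction_down_start - j3$junction_up_end, 0L)
  expect_equal(count_units(j3$junction_up_end, j3$junction_down_start), 3L)

  expect_equal(count_units(0L, 927L), 312L)
  expect_error(count_units(10L, 5L), "negative")

  # a substitution inside the upstream junction defeats exact search
  pos <- stringi::stri_locate_first_fixed(s, tpl$junction_up)[1] + 5L
  s_mut <- s
  substr(s_mut, pos, pos) <- if (substring(s, pos, pos) == "A") "C" else "A"
  jm <- locate_junctions(s_mut, tpl)
  expect_false(jm$ok)
  expect_equal(jm$reason, "no_upstream_junction")
})

test_that("sizing round-trips exactly for error-free pure alleles", {
  tpl <- TPL
  for (n in c(3L, 4L, 10L, 57L, 200L, 201L, 500L)) {
    s <- build_allele_sequence(tpl, pure_allele(n))
    p <- profile_read(s, tpl)
    expect_equal(p$unit_count, n)
    # string-count oracle: GAA occurrences in the constructed tract
    expect_equal(stringi::stri_count_fixed(strrep("GAA", n), "GAA"), n)
    expect_equal(p$tract_length, 3L * n)
    expect_equal(p$purity, 1)
  }
})

test_that("greedy tokenization tiles exactly and matches simple constructions", {
  tpl <- TPL
  t1 <- tokenize_tract(strrep("GAA", 10), tpl)
  expect_equal(nrow(t1), 10L)
  expect_true(all(t1$motif == "GAA"))

  t2 <- tokenize_tract(strrep("GCAGAA", 5), tpl)
  expect_equal(nrow(t2), 5L)
  expect_true(all(t2$motif == "GCAGAA"))

  t3 <- tokenize_tract(paste0(strrep("GCAGAAGAAGAAGAA", 2), strrep("GAA", 4)), tpl)
  expect_equal(t3$motif, c(rep("GCAGAAGAAGAAGAA", 2), rep("GAA", 4)))
  expect_identical(
    as.data.frame(t3),
    as.data.frame(dp_tokenize(paste0(strrep("GCAGAAGAAGAAGAA", 2), strrep("GAA", 4))))
  )

  # token spans partition arbitrary sequences
  set.seed(71)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(1:200, 1), replace = TRUE),
      collapse = ""
    )
    tok <- tokenize_tract(s, tpl)
    expect_equal(tok$start, c(0L, tok$end[-nrow(tok)]))
    expect_equal(tok$end[nrow(tok)], nchar(s))
  }
})

test_that("greedy equals the minimal-NOISE DP tiling on motif concatenations", {
  set.seed(13)
  for (i in 1:100) {
    s <- random_motif_concat(20L)
    g <- tokenize_tract(s, TPL)
    d <- dp_tokenize(s)
    expect_identical(as.data.frame(g), as.data.frame(d))
    expect_equal(sum(g$motif == "NOISE"), 0L)
  }
})

test_that("terminal runs tolerate short noise and stop at interrupts", {
  tpl <- TPL
  tok <- tokenize_tract(tract_sequence(complex_allele(34, 167)), tpl)
  r <- terminal_runs(tok)
  expect_equal(r$upstream_run_units, 34L)
  expect_equal(r$downstream_run_units, 167L)
  expect_equal(r$longest_run_units, 167L)

  r_pure <- terminal_runs(tokenize_tract(strrep("GAA", 100), tpl))
  expect_equal(
    unlist(r_pure),
    c(upstream_run_units = 100L, downstream_run_units = 100L, longest_run_units = 100L)
  )

  r_cx <- terminal_runs(tokenize_tract(strrep("GCAGAA", 50), tpl))
  expect_equal(unlist(r_cx), c(
    upstream_run_units = 0L, downstream_run_units = 0L, longest_run_units = 0L
  ))

  # <= 2 consecutive noise nt are transparent; 3 break the run
  two_n <- paste0(strrep("GAA", 5), "TT", strrep("GAA", 5))
  r2 <- terminal_runs(tokenize_tract(two_n, tpl))
  expect_equal(r2$longest_run_units, 10L)
  three_n <- paste0(strrep("GAA", 5), "TTT", strrep("GAA", 7))
  r3 <- terminal_runs(tokenize_tract(three_n, tpl))
  expect_equal(r3$longest_run_units, 7L)
  expect_equal(r3$upstream_run_units, 5L)
  expect_equal(r3$downstream_run_units, 7L)
})

test_that("uniform-length selection keeps the dense population and ignores order", {
  same <- fake_profiles(rep(100L, 30L))
  sel <- select_uniform_region(same)
  expect_equal(nrow(sel$selected), 30L)
  expect_equal(sel$n_discarded, 0L)

  # 28 reads near 807 nt plus 2 shattered reads at 300 nt
  mixed <- fake_profiles(c(rep(c(268L, 269L, 270L), c(9L, 10L, 9L)), 100L, 100L))
  sel2 <- select_uniform_region(mixed)
  expect_equal(nrow(sel2$selected), 28L)
  expect_equal(sel2$n_discarded, 2L)
  expect_true(all(sel2$selected$unit_count >= 268L))

  # permutation invariance
  set.seed(5)
  shuffled <- mixed[sample(nrow(mixed)), ]
  sel3 <- select_uniform_region(shuffled)
  expect_setequal(sel3$selected$read_id, sel2$selected$read_id)
})

test_that("allele clustering splits at large gaps and enforces minimum depth", {
  two <- fake_profiles(c(rep(312L, 10L), rep(150L, 8L)))
  cl <- cluster_alleles(two)
  expect_equal(nrow(cl$alleles), 2L)
  expect_equal(cl$alleles$unit_count_median, c(150, 312))
  expect_equal(cl$alleles$n_reads, c(8L, 10L))
  expect_true(all(
    cl$alleles$unit_min <= cl$alleles$unit_count_median &
      cl$alleles$unit_count_median <= cl$alleles$unit_max
  ))

  one <- cluster_alleles(fake_profiles(c(99L, 100L, 100L, 101L)))
  expect_equal(nrow(one$alleles), 1L)

  expect_warning(
    few <- cluster_alleles(fake_profiles(c(100L, 100L))),
    "below min_reads"
  )
  expect_equal(nrow(few$alleles), 0L)
  expect_equal(few$n_dropped_reads, 2L)
})

test_that("waterfall export is a lossless, length-ordered token dump", {
  tpl <- TPL
  reads <- dplyr::bind_rows(
    simulate_reads(build_allele_sequence(tpl, pure_allele(50)), 2, error_model(seed = 1), "s", "s"),
    simulate_reads(build_allele_sequence(tpl, complex_allele(10, 60)), 2, error_model(seed = 2), "l", "l")
  )
  prof <- profile_reads(extract_repeat_reads(reads, tpl), tpl)
  wf <- waterfall_matrix(prof)
  # ascending tract length, stable by read id
  ranks <- unique(wf[, c("read_id", "read_rank")])
  lens <- prof$tract_length[match(ranks$read_id, prof$read_id)]
  expect_true(all(diff(lens) >= 0))
  # tokens round-trip exactly
  for (i in seq_len(nrow(prof))) {
    sub <- wf[wf$read_id == prof$read_id[i], c("start", "end", "motif")]
    expect_identical(
      as.data.frame(sub, row.names = FALSE),
      as.data.frame(prof$tokens[[i]][, c("start", "end", "motif")])
    )
  }
})

test_that("per-read SNP base is read off anchor-aligned coordinates", {
  tpl <- TPL
  rT <- simulate_reads(build_allele_sequence(tpl, pure_allele(40, snp = "T")), 4,
    error_model(seed = 3), "t", "t"
  )
  rA <- simulate_reads(build_allele_sequence(tpl, pure_allele(40, snp = "A")), 4,
    error_model(seed = 4), "a", "a"
  )
  pT <- profile_reads(extract_repeat_reads(rT, tpl), tpl)
  pA <- profile_reads(extract_repeat_reads(rA, tpl), tpl)
  expect_true(all(pT$snp_base == "T"))
  expect_true(all(pA$snp_base == "A"))
})
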