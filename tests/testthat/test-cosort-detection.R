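test_that("marker census formulas", {
  all56 <- marker_universe()
  c1 <- marker_census(all56)
  expect_equal(c1$completeness_pct, 100)
  expect_equal(c1$contamination_pct, 0)

  c2 <- marker_census(rep(all56, 2))
  expect_equal(c2$completeness_pct, 100)
  expect_equal(c2$contamination_pct, 100)

  # 28 distinct markers, 2 of them twice
  ids <- c(all56[1:28], all56[1:2])
  c3 <- marker_census(ids)
  expect_equal(c3$completeness_pct, 50)
  expect_equal(c3$contamination_pct, 100 * 2 / 56)
  expect_identical(c3$duplicated, 2L)

  expect_warning(c4 <- marker_census(c(all56[1], "not_a_marker")), "outside")
  expect_identical(c4$found, 1L)
  c5 <- marker_census(character(0))
  expect_equal(c5$completeness_pct, 0)
  expect_equal(c5$contamination_pct, 0)
})

test_that("co-sort flags follow the contamination and 16S discordance rules", {
  cen <- data.frame(genome_id = "s1", contamination_pct = 12)
  f <- flag_cosorts(cen, NULL)
  expect_true(f$by_markers)
  expect_false(f$by_ssu)

  cen$contamination_pct <- 9.99
  expect_false(flag_cosorts(cen, NULL)$by_markers)
  cen$contamination_pct <- 10
  expect_true(flag_cosorts(cen, NULL)$by_markers)  # threshold is inclusive

  two_diff <- data.frame(length_nt = c(1400, 1400), phylum = c("A", "B"),
                         confidence = c(95, 95))
  expect_true(flag_cosorts(cen, two_diff)$by_ssu)
  two_same <- transform(two_diff, phylum = c("A", "A"))
  expect_false(flag_cosorts(cen, two_same)$by_ssu)
  short <- transform(two_diff, length_nt = c(1400, 900))
  expect_false(flag_cosorts(cen, short)$by_ssu)
  low_conf <- transform(two_diff, confidence = c(95, 60))
  expect_false(flag_cosorts(cen, low_conf)$by_ssu)
})

test_that("chi-square decomposition on hand-checkable tables", {
  h <- chisq_decomposition(matrix(10, 2, 2))
  expect_equal(h$statistic, 0)
  expect_true(all(h$pct_contribution == 0))

  d <- chisq_decomposition(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(d$statistic, 40)
  expect_identical(d$df, 1)
  expect_true(all(abs(d$pct_contribution - 25) < 1e-9))
  expect_true(all(d$expected == 10))

  expect_error(chisq_decomposition(matrix(c(1, 2, 3), 1, 3)))
  expect_error(chisq_decomposition(matrix(c(1, 1, 0, 0), 2, 2)), "margins")
  expect_error(chisq_decomposition(matrix(c(1.5, 1, 2, 1), 2, 2)))
})

test_that("decomposition of the cohort screen table matches chisq.test", {
  # marker-based screen counts: co-sorted vs single sorts per group
  tab <- matrix(c(5, 1, 5, 487, 80, 1681), ncol = 2,
                dimnames = list(c("Patescibacteria", "DPANN", "other"),
                                c("cosort", "single")))
  d <- chisq_decomposition(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(d$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(d$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(unclass(d$residuals), unclass(ct$residuals), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(d$pct_contribution), 100, tolerance = 1e-6)

  # and on random tables
  for (i in 1:50) {
    set.seed(i)
    o <- matrix(rpois(6, 30) + 1, 3, 2)
    d <- chisq_decomposition(o)
    ct <- suppressWarnings(stats::chisq.test(o, correct = FALSE))
    expect_equal(d$statistic, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(d$p_value, ct$p.value, tolerance = 1e-10)
    expect_equal(sum(d$pct_contribution), 100, tolerance = 1e-6)
    # residual identity: weighted row sums vanish
    expect_lt(max(abs(rowSums(sqrt(d$expected) * d$residuals))), 1e-9)
  }
})

test_that("marker detector separates planted admixtures from single sorts", {
  g1 <- synthesize_genome(small_profile(61, taxon_id = "g1", n_markers = 56,
                                        genome_length = 70000), seed = 61)
  g2 <- synthesize_genome(small_profile(62, taxon_id = "g2", n_markers = 56,
                                        genome_length = 70000), seed = 62)
  sens <- mean(vapply(1:60, function(i) {
    s <- sample_sag(list(g1, g2), completeness = runif(2, 0.5, 1),
                    n_fragments = 8, sag_id = sprintf("m%03d", i), seed = i)
    marker_census(s$annotations$marker_id, genome_id = s$sag_id)$contamination_pct >= 10
  }, NA))
  fpr <- mean(vapply(1:60, function(i) {
    s <- sample_sag(g1, completeness = runif(1, 0.06, 0.99),
                    n_fragments = 8, sag_id = sprintf("s%03d", i), seed = 900 + i)
    marker_census(s$annotations$marker_id, genome_id = s$sag_id)$contamination_pct >= 10
  }, NA))
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.02)
})

test_that("cosort_screen builds a coherent cohort table", {
  comm <- simulate_community(n_taxa = 4, n_sags = 12, cosort_rate = 0.5,
                             completeness_range = c(0.5, 0.9), seed = 77)
  sc <- cosort_screen(comm, detector = "by_markers")
  expect_identical(nrow(sc$flags), 12L)
  expect_identical(sum(sc$table), 12L)
  truth_admix <- comm$truth$admixture
  # markers can only fire on real admixtures in this generator
  expect_true(all(sc$flags$by_markers <= truth_admix[match(sc$flags$sag_id, comm$truth$sag_id)]))
})
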