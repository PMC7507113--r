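test_that("Smith-Waterman identities and symmetry", {
  r <- smith_waterman("ACDE", "ACDE")
  expect_equal(r$score, 24)  # BLOSUM62 diagonal: 4 + 9 + 6 + 5
  expect_identical(r$aln_len, 4L)

  for (i in 1:20) {
    set.seed(i)
    q <- rand_pep(sample(5:30, 1))
    s <- rand_pep(sample(5:30, 1))
    expect_equal(smith_waterman(q, s)$score, smith_waterman(s, q)$score)
  }
  expect_equal(smith_waterman("", "ACDE"), list(score = 0, aln_len = 0L))
  expect_error(smith_waterman("ACDE", "ACDE", gap_open = 0))

  # identical sequences: local equals the sum of diagonal scores
  b <- blosum62()
  for (i in 1:10) {
    set.seed(40 + i)
    q <- rand_pep(25)
    aa <- strsplit(q, "")[[1]]
    expect_equal(smith_waterman(q, q)$score, sum(b[cbind(aa, aa)]))
    expect_gte(smith_waterman(q, rand_pep(25))$score, 0)
  }
})

test_that("Smith-Waterman matches the exhaustive matching oracle on tiny peptides", {
  b <- blosum62()
  for (i in 1:60) {
    set.seed(i)
    q <- rand_pep(sample(3:8, 1))
    s <- rand_pep(sample(3:8, 1))
    expect_equal(smith_waterman(q, s)$score, sw_enum_oracle(q, s, b),
                 info = paste(q, s))
  }
})

test_that("Smith-Waterman scores match Biostrings on longer peptides", {
  for (i in 1:40) {
    set.seed(200 + i)
    q <- rand_pep(sample(10:60, 1))
    s <- rand_pep(sample(10:60, 1))
    got <- smith_waterman(q, s)$score
    want <- sw_biostrings(q, s)
    # pairwiseAlignment floors local scores at the best single pair
    expect_equal(got, max(want, 0), info = paste(q, s))
  }
})

test_that("Karlin-Altschul e-values scale as the closed form requires", {
  e1 <- karlin_evalue(100, 300, 1000)
  expect_equal(karlin_evalue(100, 300, 2000), 2 * e1)
  expect_lt(karlin_evalue(1e6, 300, 1000), 1e-300)
  expect_equal(karlin_evalue(100, 300, 1000) / karlin_evalue(110, 300, 1000),
               exp(0.267 * 10))
  expect_error(karlin_evalue(10, 0, 100))
  expect_error(karlin_evalue(10, 10, 100, K = -1))
})

test_that("oxygen-reductase detection: self-hits, decoys, and the tree filter", {
  refs <- o2red_reference()
  prot <- c(hco = refs$seq[refs$family == "HCO_A"][1],
            bd_short = substr(refs$seq[refs$family == "bd"][1], 1, 380))
  res <- detect_o2red(prot)
  expect_setequal(res$hits$protein_id, c("hco", "bd_short"))
  expect_identical(res$hits$family[res$hits$protein_id == "hco"], "HCO_A")
  expect_identical(res$hits$affinity[res$hits$protein_id == "hco"], "low")
  # 380 aa hit stays in the hit list but is not tree-eligible
  expect_false(res$hits$tree_eligible[res$hits$protein_id == "bd_short"])
  expect_true(res$hits$tree_eligible[res$hits$protein_id == "hco"])
  expect_identical(names(res$tree_eligible), "hco")

  set.seed(3)
  decoys <- stats::setNames(vapply(1:30, function(i) rand_pep(300), ""),
                            sprintf("d%02d", 1:30))
  dres <- detect_o2red(decoys)
  expect_lt(nrow(dres$hits) / 30, 0.01)
  expect_error(detect_o2red(prot, refdb = refs[0, ]))
})

test_that("the KO acceptance rule is a 50%-of-threshold rule and scale-invariant", {
  raw <- data.frame(protein_id = c("a", "b", "c", "d"),
                    ko_id = "K00330",
                    ko_score = c(50, 49.99, 200, 10),
                    ko_threshold = c(100, 100, 100, NA))
  expect_warning(out <- apply_ko_rule(raw), "threshold")
  expect_identical(out$accepted, c(TRUE, FALSE, TRUE))

  ok <- raw[1:3, ]
  scaled <- transform(ok, ko_score = ko_score * 7, ko_threshold = ko_threshold * 7)
  expect_identical(apply_ko_rule(ok)$accepted, apply_ko_rule(scaled)$accepted)
})

test_that("ETC profiles count complexes and oxidoreductase fractions", {
  hits <- data.frame(ko_id = c("K02274", "K02275"), accepted = c(TRUE, TRUE))
  p <- etc_profile(hits, protein_count = 100, ec1_count = 5, genome_id = "g")
  expect_identical(p$complex_IV, 2L)
  expect_identical(p$n_complexes, 1L)
  expect_false(p$complete_etc)
  expect_equal(p$ec1_fraction, 5)
  expect_error(etc_profile(hits, protein_count = 0, ec1_count = 0))
})

test_that("respiratory contrast between generator styles is recovered", {
  profs <- list()
  groups <- character(0)
  for (i in 1:12) {
    style <- if (i %% 2) "patesci_like" else "standard"
    ph <- if (i %% 2) "Patescibacteria" else "Other-Bacteria"
    g <- synthesize_genome(make_taxon_profile(ph, style, seed = 300 + i,
                                              taxon_id = sprintf("e%02d", i)),
                           seed = 300 + i)
    profs[[i]] <- energy_scan(g$annotations, by = "genome_id")
    groups <- c(groups, style)
  }
  profs <- do.call(rbind, profs)
  es <- energy_summary(profs, groups)
  expect_equal(es$pct_complete_etc[es$group == "patesci_like"], 0)
  expect_gte(es$pct_complete_etc[es$group == "standard"], 90)
  expect_lt(es$mean_ec1_fraction[es$group == "patesci_like"],
            es$mean_ec1_fraction[es$group == "standard"])
})

test_that("EC1 fractions separate styles under a rank-sum test", {
  # annotation-level cohorts at the generative rates 0.01 vs 0.05
  rej <- vapply(1:30, function(r) {
    set.seed(1000 + r)
    n <- 30
    lo <- 100 * rbinom(n, 200, 0.01) / 200
    hi <- 100 * rbinom(n, 200, 0.05) / 200
    stats::wilcox.test(lo, hi, exact = FALSE)$p.value < 0.01
  }, NA)
  expect_gte(mean(rej), 0.9)
})
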