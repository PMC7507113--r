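test_that("taxon profiles are deterministic and honor style presets", {
  p1 <- make_taxon_profile("Patescibacteria", "patesci_like", seed = 7)
  p2 <- make_taxon_profile("Patescibacteria", "patesci_like", seed = 7)
  expect_identical(p1, p2)
  expect_length(p1$etc_complement, 0)
  expect_length(p1$o2red_genes, 0)
  expect_true(p1$genetic_code %in% c(11L, 25L))
  expect_equal(sum(p1$cog_distribution), 1, tolerance = 1e-12)
  expect_gte(nchar(p1$ssu_ref), 1200)

  s <- make_taxon_profile("Other-Bacteria", "standard", seed = 7)
  expect_setequal(s$etc_complement, c("I", "II", "III", "IV"))
  expect_identical(s$genetic_code, 11L)

  expect_error(make_taxon_profile("X", "no_such_style", seed = 1))
})

test_that("profile coding densities center on the configured style mean", {
  dens <- vapply(1:100, function(i) {
    make_taxon_profile("Other-Bacteria", "standard", seed = i)$target_coding_density
  }, 0)
  expect_lt(abs(mean(dens) - 0.90), 0.02)
})

test_that("16S evolution preserves length and hits the requested divergence", {
  ref <- phylum_reference_ssu("Other-Bacteria")
  expect_identical(evolve_ssu(ref, 0, seed = 1), ref)
  expect_identical(evolve_ssu(ref, 0.1, seed = 3), evolve_ssu(ref, 0.1, seed = 3))
  expect_error(evolve_ssu(ref, 0.5, seed = 1))

  s <- paste(rep("ACGT", 375), collapse = "")  # length 1500
  out <- evolve_ssu(s, 0.1, seed = 3)
  expect_identical(nchar(out), nchar(s))
  ham <- mean(strsplit(s, "")[[1]] != strsplit(out, "")[[1]])
  expect_gte(ham, 0.07)
  expect_lte(ham, 0.13)
})

test_that("synthesized genomes hit the target coding density and code semantics", {
  for (code in c(11L, 25L)) {
    p <- small_profile(40 + code, code = code)
    g <- synthesize_genome(p, seed = 40 + code)
    expect_identical(nchar(g$sequence), p$genome_length)
    cds <- g$gene_map[g$gene_map$type != "ssu", ]
    realized <- sum(cds$length_nt) / nchar(g$sequence)
    expect_lt(abs(realized - p$target_coding_density), 0.03)

    has_tga <- vapply(seq_len(nrow(cds)), function(i) {
      s <- substr(g$sequence, cds$start[i] + 1, cds$end[i])
      if (cds$strand[i] == "-") s <- sagcensus:::revcomp(s)
      cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      any(cod[-length(cod)] == "TGA")
    }, NA)
    if (code == 11L) {
      expect_identical(sum(has_tga), 0L)
    } else {
      expect_gte(mean(has_tga), 0.30)
    }
  }
})

test_that("full marker complement round-trips to 100% completeness", {
  p <- make_taxon_profile("Other-Bacteria", "standard", seed = 2, taxon_id = "rt",
                          overrides = list(etc_complement = character(0),
                                           o2red = character(0)))
  g <- synthesize_genome(p, seed = 2)
  cen <- marker_census(g$annotations$marker_id, genome_id = "rt")
  expect_equal(cen$completeness_pct, 100)
  expect_equal(cen$contamination_pct, 0)
})

test_that("genome synthesis fails when the genome cannot hold the complements", {
  p <- make_taxon_profile("Other-Bacteria", "standard", seed = 3,
                          overrides = list(genome_length = 20000))
  expect_error(synthesize_genome(p, seed = 3), "too small")
})

test_that("single-genome full-completeness SAG is the identity case", {
  p <- small_profile(11)
  g <- synthesize_genome(p, seed = 11)
  s <- sample_sag(g, 1.0, n_fragments = 1, sag_id = "full", seed = 1)
  expect_length(s$contigs, 1)
  expect_identical(unname(s$contigs[1]), g$sequence)
  expect_false(s$truth$admixture)
  expect_error(sample_sag(g, 0, sag_id = "zero", seed = 1))
})

test_that("SAG fragment coverage matches the requested completeness", {
  p <- small_profile(12, genome_length = 60000)
  g <- synthesize_genome(p, seed = 12)
  ratios <- vapply(1:30, function(i) {
    s <- sample_sag(g, 0.3, n_fragments = 5, sag_id = sprintf("s%02d", i), seed = i)
    expect_true(all(nchar(s$contigs) >= 2000))
    sum(nchar(s$contigs)) / nchar(g$sequence)
  }, 0)
  expect_true(all(ratios >= 0.25 & ratios <= 0.35))
})

test_that("two-source SAGs are admixtures with proportionate marker retention", {
  p1 <- small_profile(21, taxon_id = "m1", n_markers = 56, genome_length = 70000)
  p2 <- small_profile(22, taxon_id = "m2", n_markers = 56, genome_length = 70000)
  g1 <- synthesize_genome(p1, seed = 21)
  g2 <- synthesize_genome(p2, seed = 22)
  frac <- vapply(1:60, function(i) {
    s <- sample_sag(list(g1, g2), 0.6, n_fragments = 8,
                    sag_id = sprintf("mix%02d", i), seed = i)
    expect_true(s$truth$admixture)
    ann <- s$annotations
    m1 <- unique(ann$marker_id[ann$genome_id == "m1" & !is.na(ann$marker_id)])
    length(m1) / 56
  }, 0)
  # retained fraction tracks the requested completeness, shaved by the
  # whole-gene containment requirement at fragment edges
  # (expected shave ~ mean gene length / mean fragment length)
  expect_gt(mean(frac), 0.45)
  expect_lt(mean(frac), 0.65)
})

test_that("communities regenerate identically and write recoverable truth", {
  dir1 <- withr::local_tempdir()
  c1 <- simulate_community(n_taxa = 4, n_sags = 6, seed = 5, outdir = dir1)
  c2 <- simulate_community(n_taxa = 4, n_sags = 6, seed = 5)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$sags[["sag003"]]$contigs, c2$sags[["sag003"]]$contigs)

  truth <- sagcensus:::read_tsv(file.path(dir1, "truth.tsv"))
  expect_identical(truth$sag_id, c1$truth$sag_id)
  expect_identical(truth$admixture, c1$truth$admixture)
  fa <- Biostrings::readDNAStringSet(file.path(dir1, "contigs.fasta"))
  expect_equal(sum(lengths(fa)),
               sum(vapply(c1$sags, function(s) sum(nchar(s$contigs)), 0)))
})
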