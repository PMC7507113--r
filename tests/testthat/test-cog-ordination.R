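test_that("COG matrices are row-normalized percentages", {
  ann <- data.frame(genome_id = rep(c("g1", "g2"), c(20, 3)),
                    cog_category = c(rep(c("J", "K"), 10), rep("C", 3)))
  m <- build_cog_matrix(ann)
  expect_equal(m$J[m$genome_id == "g1"], 50)
  expect_equal(m$K[m$genome_id == "g1"], 50)
  expect_equal(m$C[m$genome_id == "g2"], 100)
  expect_equal(unname(rowSums(sagcensus:::cog_values(m))), c(100, 100))

  ann2 <- rbind(ann, data.frame(genome_id = "g3", cog_category = NA))
  expect_warning(m2 <- build_cog_matrix(ann2), "zero assigned")
  expect_false("g3" %in% m2$genome_id)

  expect_error(build_cog_matrix(data.frame(genome_id = "g", cog_category = "X")),
               "unknown COG")
})

test_that("ordination eligibility filters on completeness and 16S presence", {
  ann <- data.frame(genome_id = rep(c("g1", "g2", "g3"), each = 4),
                    cog_category = rep(c("J", "K", "L", "C"), 3))
  m <- build_cog_matrix(ann)
  census <- data.frame(genome_id = c("g1", "g2", "g3"),
                       completeness_pct = c(29.9, 30, 80))
  ssu <- data.frame(sag_id = c("g1", "g2"), length_nt = c(1400, 1200))
  f <- filter_genomes(m, census, ssu)
  # 29.9 drops, 30.0 with a 1200 nt 16S stays, 80% without 16S drops
  expect_identical(f$genome_id, "g2")
})

test_that("classical scaling reproduces distances and known configurations", {
  # all rows identical: no variance
  flat <- matrix(5, 4, 6)
  o <- suppressWarnings(ordinate_profiles(flat, n_axes = 2))
  expect_true(all(o$eigenvalues == 0))

  # equilateral configuration: first two eigenvalues equal d^2/2
  d <- 6
  X <- rbind(c(0, 0), c(d, 0), c(d / 2, d * sqrt(3) / 2))
  o3 <- ordinate_profiles(X, n_axes = 2)
  expect_equal(o3$eigenvalues, rep(d^2 / 2, 2), tolerance = 1e-9)
  expect_equal(as.numeric(dist(o3$coordinates)), rep(d, 3), tolerance = 1e-9)

  # Gower identity: full-rank coordinates reproduce input distances
  set.seed(42)
  M <- matrix(runif(15 * 6, 0, 50), 15, 6)
  of <- ordinate_profiles(M, n_axes = 6)
  expect_lt(max(abs(dist(M) - dist(of$coordinates))), 1e-6)
  # coordinates are centered, eigenvalues nonincreasing, trace preserved
  expect_lt(max(abs(colMeans(of$coordinates))), 1e-9)
  expect_true(all(diff(of$eigenvalues) <= 1e-9))
  expect_equal(sum(of$eigenvalues), sum(scale(M, scale = FALSE)^2),
               tolerance = 1e-6)
})

test_that("ordination agrees with cmdscale and prcomp", {
  set.seed(7)
  M <- matrix(runif(20 * 8, 0, 30), 20, 8)
  o <- ordinate_profiles(M, n_axes = 3)
  cs <- stats::cmdscale(dist(M), k = 3, eig = TRUE)
  expect_equal(o$eigenvalues, cs$eig[1:3], tolerance = 1e-8)
  expect_equal(abs(o$coordinates), abs(cs$points), tolerance = 1e-6,
               ignore_attr = TRUE)
  pc <- stats::prcomp(M)
  expect_equal(o$eigenvalues, pc$sdev[1:3]^2 * (nrow(M) - 1), tolerance = 1e-8)
})

test_that("rank-sum separation: exact enumeration and tie handling", {
  r <- group_separation(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 1 / 3)
  expect_identical(r$method, "exact enumeration")

  same <- group_separation(rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(same$p_value, 1)

  # exact p agrees with wilcox.test for untied small samples
  for (i in 1:20) {
    set.seed(i)
    x <- rnorm(6)
    y <- rnorm(5)
    mine <- sagcensus:::ranksum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }

  expect_warning(
    expect_error(group_separation(1:3, c("a", "a", "b")), "groups"),
    "singleton")
})

test_that("style contrast separates on PC1 with depleted categories loading away", {
  cats <- cog_categories()
  one_cohort <- function(seed) {
    set.seed(seed)
    rows <- lapply(1:40, function(i) {
      style <- if (i <= 20) "patesci_like" else "standard"
      pr <- make_taxon_profile(if (i <= 20) "Patescibacteria" else "Other-Bacteria",
                               style, seed = seed * 1000 + i)
      counts <- as.integer(rmultinom(1, 250, pr$cog_distribution))
      data.frame(genome_id = sprintf("g%02d", i),
                 cog_category = rep(cats, counts))
    })
    ann <- do.call(rbind, rows)
    m <- build_cog_matrix(ann)
    m$group <- rep(c("patesci", "standard"), each = 20)
    o <- ordinate_profiles(m, n_axes = 2)
    p <- group_separation(o, axis = 1)$p_value
    side_std <- mean(o$coordinates[m$group == "standard", 1]) -
      mean(o$coordinates[m$group == "patesci", 1])
    dep_load <- o$loadings[c("C", "E", "H", "P"), 1]
    list(p = p, aligned = all(sign(dep_load) == sign(side_std)))
  }
  res <- lapply(1:20, one_cohort)
  expect_gte(mean(vapply(res, `[[`, 0, "p") < 0.01), 0.95)
  # depleted categories load toward the non-depleted group's side
  expect_gte(mean(vapply(res, `[[`, NA, "aligned")), 0.95)
})

test_that("row permutation permutes coordinates identically", {
  set.seed(9)
  M <- matrix(runif(12 * 5), 12, 5)
  o1 <- ordinate_profiles(M, n_axes = 2)
  perm <- sample(12)
  o2 <- ordinate_profiles(M[perm, ], n_axes = 2)
  expect_equal(o2$coordinates, o1$coordinates[perm, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})
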