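toy4 <- function() {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  d["A", "B"] <- 0.1; d["C", "D"] <- 0.2; d["A", "C"] <- 0.7
  d["A", "D"] <- 0.8; d["B", "C"] <- 0.9; d["B", "D"] <- 0.6
  d + t(d)
}

test_that("ANOSIM R equals 1 at maximal separation and matches its definition", {
  # all between-group dissimilarities exceed all within-group ones:
  # within ranks {1,2}, between {3,4,5,6}, R = (4.5 - 1.5) / (4*3/4) = 1
  res <- anosim_test(toy4(), c(A = "g1", B = "g1", C = "g2", D = "g2"),
                     n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
})

test_that("ANOSIM R is centred on zero under random labelling", {
  set.seed(14)
  Rs <- replicate(1000, {
    d <- random_dissimilarity(8)
    g <- sample(rep(c("x", "y"), each = 4))
    names(g) <- rownames(d)
    anosim_test(d, g, n_perm = 0)$R
  })
  expect_lt(abs(mean(Rs)), 0.05)
  expect_true(all(Rs >= -1 & Rs <= 1))
})

test_that("ANOSIM is rank-based: invariant to monotone transforms", {
  set.seed(15)
  d <- random_dissimilarity(9)
  g <- setNames(sample(rep(c("x", "y", "z"), each = 3)), rownames(d))
  r0 <- anosim_test(d, g, n_perm = 49, seed = 2)$R
  expect_equal(anosim_test(d^2, g, n_perm = 49, seed = 2)$R, r0)
  expect_equal(anosim_test(exp(d) - 1, g, n_perm = 49, seed = 2)$R, r0)
})

test_that("ANOSIM agrees with vegan and is seed-reproducible", {
  library(vegan)
  set.seed(16)
  for (i in 1:5) {
    d <- random_dissimilarity(10)
    g <- setNames(sample(rep(c("x", "y"), each = 5)), rownames(d))
    ours <- anosim_test(d, g, n_perm = 99, seed = 3)
    ref <- vegan::anosim(as.dist(d), factor(g[rownames(d)]), permutations = 99)
    expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)
  }
  a1 <- anosim_test(d, g, n_perm = 199, seed = 42)
  a2 <- anosim_test(d, g, n_perm = 199, seed = 42)
  expect_identical(a1$null_R, a2$null_R)
  expect_identical(a1$p_value, a2$p_value)

  expect_error(anosim_test(d, g[-1]), class = "karstbeta_reference_error")
  g1 <- g; g1[] <- "x"; g1[1] <- "y"
  expect_error(anosim_test(d, g1), class = "karstbeta_value_error")
})

test_that("pairwise ANOSIM runs one test per group pair", {
  set.seed(17)
  d <- random_dissimilarity(12)
  g <- setNames(rep(c("slope", "shallow_upper", "deep_core"), each = 4), rownames(d))
  tab <- anosim_pairwise(d, g, n_perm = 49, seed = 5)
  expect_identical(nrow(tab), 3L)
  expect_setequal(paste(tab$group1, tab$group2),
                  c("deep_core shallow_upper", "deep_core slope", "shallow_upper slope"))
  expect_true(all(tab$R >= -1 & tab$R <= 1))
})

test_that("Mantel r is rank-invariant, symmetric, and matches vegan", {
  library(vegan)
  set.seed(18)
  d1 <- random_dissimilarity(8)
  mono <- d1^3 / (1 + d1)  # strictly monotone transform
  expect_equal(mantel_spearman(d1, mono, n_perm = 9, seed = 1)$r, 1)

  d2 <- random_dissimilarity(8)
  expect_equal(mantel_spearman(d1, d2, n_perm = 9, seed = 1)$r,
               mantel_spearman(d2, d1, n_perm = 9, seed = 1)$r)

  ref <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman", permutations = 99)
  expect_equal(mantel_spearman(d1, d2, n_perm = 99, seed = 1)$r,
               unname(ref$statistic), tolerance = 1e-12)

  m1 <- mantel_spearman(d1, d2, n_perm = 199, seed = 9)
  m2 <- mantel_spearman(d1, d2, n_perm = 199, seed = 9)
  expect_identical(m1$null_r, m2$null_r)

  expect_error(mantel_spearman(d1, d2[c(2:8, 1), c(2:8, 1)]),
               class = "karstbeta_reference_error")
  expect_error(mantel_spearman(d1[1:3, 1:3], d2[1:3, 1:3]),
               class = "karstbeta_value_error")
})

test_that("sampled Mantel p matches exhaustive enumeration on 4 units", {
  set.seed(19)
  for (i in 1:5) {
    d1 <- random_dissimilarity(4, LETTERS[1:4])
    d2 <- random_dissimilarity(4, LETTERS[1:4])
    p_exact <- oracle_mantel_exact_p(d1, d2)
    p_sim <- mantel_spearman(d1, d2, n_perm = 999, seed = i)$p_value
    # add-one sampled p estimates the exhaustive proportion
    expect_lt(abs(p_sim - p_exact), 0.1)
  }
})

test_that("UPGMA merges at half the average linkage and is ultrametric", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(d2)$heights, 0.5)

  d3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(sort(t3$heights), c(1, 2.5))  # merge (A,B) at 1, join C at mean(4,6)/2

  set.seed(20)
  for (i in 1:10) {
    d <- random_dissimilarity(7)
    tree <- upgma(d)
    coph <- cophenetic_matrix(tree)
    expect_equal(coph, oracle_avg_linkage_cophenetic(d), tolerance = 1e-9,
                 ignore_attr = TRUE)
    # ultrametric: every triple satisfies the two-largest-equal condition
    labs <- rownames(coph)
    for (tri in list(c(1, 2, 3), c(2, 5, 7), c(1, 4, 6))) {
      v <- sort(c(coph[tri[1], tri[2]], coph[tri[1], tri[3]], coph[tri[2], tri[3]]))
      expect_lte(v[2], v[3] + 1e-9)
      expect_equal(v[2], v[3], tolerance = 1e-9)
    }
    # relabelling permutes leaves but preserves heights
    ord <- sample.int(7)
    t_perm <- upgma(d[ord, ord])
    expect_equal(sort(t_perm$heights), sort(tree$heights), tolerance = 1e-12)
    expect_equal(cophenetic_matrix(t_perm)[labs, labs], coph, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
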