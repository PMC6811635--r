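pc <- function(a, b, c) structure(list(a = a, b = b, c = c), class = "pair_counts")

test_that("pairwise partition splits Jaccard into turnover and nestedness", {
  nested <- pairwise_partition(pc(3, 0, 4))
  expect_equal(nested$turnover, 0)
  expect_equal(nested$nestedness, nested$total)

  repl <- pairwise_partition(pc(0, 5, 5))
  expect_equal(repl$total, 1)
  expect_equal(repl$turnover, 1)
  expect_equal(repl$nestedness, 0)

  p <- pairwise_partition(pc(2, 1, 3))
  expect_equal(p$total, 4 / 6)
  expect_equal(p$turnover, 0.5)
  expect_equal(p$nestedness, 4 / 6 - 0.5)

  expect_error(pairwise_partition(pc(0, 0, 0)), class = "karstbeta_value_error")

  # additive components, bounded, for arbitrary counts
  set.seed(23)
  for (i in 1:300) {
    a <- sample(0:12, 1); b <- sample(0:12, 1); cc <- sample(0:12, 1)
    if (a + b + cc == 0) next
    q <- pairwise_partition(pc(a, b, cc))
    expect_equal(q$turnover + q$nestedness, q$total, tolerance = 1e-15)
    expect_gte(q$nestedness, 0)
    expect_lte(q$turnover, q$total)
    expect_lte(q$total, 1)
  }
})

test_that("multisite aggregates match pair enumeration", {
  m3 <- matrix(0L, 4, 3, dimnames = list(sprintf("sp%d", 1:4), c("S1", "S2", "S3")))
  m3[1:2, "S1"] <- 1L; m3[2:3, "S2"] <- 1L; m3[3:4, "S3"] <- 1L
  agg <- multisite_aggregates(m3)
  expect_identical(agg[c("S_T", "sum_Si", "sum_min", "sum_max")],
                   list(S_T = 4L, sum_Si = 6L, sum_min = 4L, sum_max = 4L))

  ident <- cbind(A = c(1L, 1L, 0L), B = c(1L, 1L, 0L), C = c(1L, 1L, 0L))
  rownames(ident) <- sprintf("sp%d", 1:3)
  ai <- multisite_aggregates(ident)
  expect_identical(ai$sum_min, 0L)
  expect_identical(ai$sum_max, 0L)
  expect_identical(ai$sum_Si, 3L * ai$S_T)

  set.seed(24)
  for (i in 1:20) {
    m <- random_incidence(12, 6)
    expect_identical(multisite_aggregates(m), oracle_aggregates(m))
    # two-site aggregates reduce to the pair's (b, c)
    p <- pair_counts(m[, 1], m[, 2])
    a2 <- multisite_aggregates(m, colnames(m)[1:2])
    expect_identical(a2$sum_min, min(p$b, p$c))
    expect_identical(a2$sum_max, max(p$b, p$c))
  }

  expect_error(multisite_aggregates(m3, "S1"), class = "karstbeta_value_error")
  expect_error(multisite_aggregates(m3, c("S1", "nope")),
               class = "karstbeta_reference_error")
  m3[, 1] <- 0L
  expect_error(multisite_aggregates(m3), "S1", class = "karstbeta_value_error")
})

test_that("multisite partition: worked example, two-site consistency, nestedness", {
  m3 <- matrix(0L, 4, 3, dimnames = list(sprintf("sp%d", 1:4), c("S1", "S2", "S3")))
  m3[1:2, "S1"] <- 1L; m3[2:3, "S2"] <- 1L; m3[3:4, "S3"] <- 1L
  part <- beta_partition(m3)
  expect_equal(part$total, 0.8)
  expect_equal(part$turnover, 0.8)
  expect_equal(part$nestedness, 0)

  # n = 2 reduces exactly to the pairwise partition
  set.seed(25)
  for (i in 1:20) {
    m <- random_incidence(10, 2)
    two <- beta_partition(m)
    pw <- pairwise_partition(pair_counts(m[, 1], m[, 2]))
    expect_identical(two$total, pw$total)
    expect_identical(two$turnover, pw$turnover)
  }

  # perfectly nested chain: zero turnover
  chain <- cbind(S1 = rep(1L, 6), S2 = c(1L, 1L, 1L, 1L, 0L, 0L),
                 S3 = c(1L, 1L, 0L, 0L, 0L, 0L))
  rownames(chain) <- sprintf("sp%d", 1:6)
  nest <- beta_partition(chain)
  expect_equal(nest$turnover, 0)
  expect_equal(nest$nestedness, nest$total)
  expect_gt(nest$total, 0)

  # degenerate: identical single-species sites
  degen <- cbind(A = c(1L, 0L), B = c(1L, 0L))
  rownames(degen) <- c("sp1", "sp2")
  expect_equal(beta_partition(degen)$total, 0)
})

test_that("partition agrees with vegan's multiple-site Jaccard decomposition", {
  library(vegan)
  set.seed(26)
  for (i in 1:20) {
    m <- random_incidence(15, sample(3:8, 1))
    ours <- beta_partition(m)
    ref <- vegan::nestedbetajac(t(m))
    expect_equal(ours$total, unname(ref["jaccard"]), tolerance = 1e-12)
    expect_equal(ours$turnover, unname(ref["turnover"]), tolerance = 1e-12)
    expect_equal(ours$nestedness, unname(ref["nestedness"]), tolerance = 1e-12)
    # site order never matters
    ord <- sample.int(ncol(m))
    perm <- beta_partition(m[, ord])
    expect_identical(perm$total, ours$total)
    expect_identical(perm$turnover, ours$turnover)
  }
})

test_that("componentwise averaging preserves additivity", {
  p1 <- karstbeta:::new_bd_partition(0.8, 0.8, 3L)
  p2 <- karstbeta:::new_bd_partition(0.4, 0.2, 3L)
  avg <- average_bd(list(p1, p2))
  expect_equal(avg$total, 0.6)
  expect_equal(avg$turnover, 0.5)
  expect_equal(avg$nestedness, 0.1)
  single <- average_bd(list(p1))
  expect_equal(single$total, p1$total)
  expect_error(average_bd(list()), class = "karstbeta_value_error")
})

test_that("vertical comparison sets pair each shallow unit with each deep cave", {
  dat <- generate_scenario(scenario_spec("bfn_random", seed = 31))
  sets <- build_vertical_sets(dat$units)
  settings <- vapply(sets, `[[`, character(1), "setting")
  vc <- sets[settings == "vertical_central"]
  expect_length(vc, 10)  # 5 shallow units x 2 deep caves
  expect_true(all(lengths(lapply(vc, `[[`, "unit_ids")) == 6))
  for (s in vc) {
    zones <- dat$units$zone[match(s$unit_ids, dat$units$unit_id)]
    expect_identical(sum(zones == "shallow_upper"), 1L)
    expect_identical(sum(zones == "deep_core"), 5L)
  }
  slope_set <- sets[settings == "vertical_slope"]
  expect_length(slope_set, 1)
  expect_length(slope_set[[1]]$unit_ids, 5)

  # single shallow unit and deep cave give a single set
  mini <- dat$units[dat$units$unit_id %in%
                      c("C1_0-50", "C1_50-100", "C1_100-200", "C1_200-330",
                        "C1_330-500", "C1_>500"), ]
  expect_length(build_vertical_sets(mini), 1)
  # deep cave with missing strata still yields a (warned) set
  incomplete <- dat$units[dat$units$unit_id != "C1_>500", ]
  expect_warning(sets2 <- build_vertical_sets(incomplete), "C1")
  expect_true(any(lengths(lapply(sets2, `[[`, "unit_ids")) == 5))
})

test_that("horizontal sets group by stratum across zones", {
  dat <- generate_scenario(scenario_spec("bfn_random", seed = 32))
  sets <- suppressWarnings(build_horizontal_sets(dat$units))
  labs <- vapply(sets, `[[`, character(1), "label")
  expect_identical(labs[1], "0-50")
  expect_length(sets[[1]]$unit_ids, 5)  # the five shallow entrance strata
  # slope caves appear in deeper strata via their explicit labels
  deep_sets <- sets[labs != "0-50"]
  zones_in_deep <- unlist(lapply(deep_sets, function(s) {
    dat$units$zone[match(s$unit_ids, dat$units$unit_id)]
  }))
  expect_true("slope" %in% zones_in_deep)
  # every deep stratum holds at least the two deep-cave units
  expect_true(all(lengths(lapply(deep_sets, `[[`, "unit_ids")) >= 2))

  single <- dat$units[dat$units$stratum != "0-50" | dat$units$unit_id == "C1_0-50", ]
  expect_warning(build_horizontal_sets(single), "single unit")
})
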