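test_that("seasonal pooling sums counts and rejects malformed samples", {
  samples <- data.frame(
    unit_id = c("U1", "U1", "U2"),
    season = c("spring_summer", "winter", "winter"),
    species_id = c("spX", "spX", "spY"),
    count = c(3L, 2L, 7L)
  )
  m <- pool_seasons(samples, c("spX", "spY"), c("U1", "U2"))
  expect_equal(m["spX", "U1"], 5)
  expect_equal(m["spY", "U2"], 7)
  expect_equal(m["spY", "U1"], 0)  # absent in both seasons

  dup <- rbind(samples, samples[1L, ])
  expect_error(pool_seasons(dup, c("spX", "spY"), c("U1", "U2")),
               "aggregate", class = "karstbeta_value_error")
  expect_error(pool_seasons(samples, c("spX", "spY"), "U1"),
               "U2", class = "karstbeta_reference_error")
  expect_error(pool_seasons(samples, "spX", c("U1", "U2")),
               "spY", class = "karstbeta_reference_error")
})

test_that("effort normalization follows count / (traps x length)", {
  m <- abundance_matrix(matrix(c(10, 0), 1, 2,
                               dimnames = list("spA", c("U1", "U2"))))
  units <- data.frame(unit_id = c("U1", "U2"), cave_code = "C1",
                      zone = "shallow_upper", depth_m = 10, x = 0, y = 0, z = 0,
                      n_traps = c(5, 5), passage_length_m = c(100, 100),
                      stratum = "0-50")
  norm <- normalize_abundance(m, units)
  expect_equal(norm["spA", "U1"], 0.02)  # 10 / (5 * 100)
  expect_equal(norm["spA", "U2"], 0)
  expect_true(attr(norm, "normalized"))

  units2 <- units; units2$n_traps <- units$n_traps * 2
  expect_equal(unclass(normalize_abundance(m, units2)), unclass(norm) / 2,
               ignore_attr = TRUE)

  expect_error(normalize_abundance(m, units[1L, ]),
               "U2", class = "karstbeta_reference_error")
})

test_that("normalization preserves the zero pattern (incidence invariance)", {
  set.seed(3)
  raw <- abundance_matrix(matrix(rpois(60, 1.2), 10, 6,
                                 dimnames = list(sprintf("sp%d", 1:10),
                                                 sprintf("U%d", 1:6))))
  units <- data.frame(unit_id = sprintf("U%d", 1:6), cave_code = "C1",
                      zone = "shallow_upper", depth_m = 10, x = 0, y = 0, z = 0,
                      n_traps = sample(5:20, 6), passage_length_m = runif(6, 30, 300),
                      stratum = "0-50")
  expect_identical(to_incidence(normalize_abundance(raw, units)),
                   to_incidence(raw))
})

test_that("obligate filtering removes non-obligate rows only", {
  m <- abundance_matrix(matrix(1, 3, 2, dimnames = list(c("a", "b", "c"),
                                                        c("U1", "U2"))))
  species <- data.frame(species_id = c("a", "b", "c"),
                        name = c("a", "b", "c"),
                        eco_class = c("obligate", "non_obligate", "obligate"))
  out <- filter_obligates(m, species)
  expect_identical(rownames(out), c("a", "c"))
  expect_identical(colnames(out), c("U1", "U2"))

  all_ob <- species; all_ob$eco_class <- "obligate"
  expect_equal(filter_obligates(m, all_ob), m, ignore_attr = TRUE)

  none <- species; none$eco_class <- "non_obligate"
  empty <- filter_obligates(m, none)
  expect_identical(nrow(empty), 0L)
  expect_error(jaccard_matrix(to_incidence(empty)), class = "karstbeta_value_error")

  expect_error(filter_obligates(m, species[1:2, ]),
               class = "karstbeta_reference_error")
})

test_that("incidence reduction is binary, idempotent, and can drop empty units", {
  m <- abundance_matrix(matrix(c(0.02, 0, 0, 0), 2, 2,
                               dimnames = list(c("a", "b"), c("U1", "U2"))))
  inc <- to_incidence(m)
  expect_identical(unname(inc[, "U1"]), c(1L, 0L))
  expect_identical(to_incidence(inc), inc)
  expect_warning(dropped <- to_incidence(m, drop_empty_units = TRUE), "U2")
  expect_identical(colnames(dropped), "U1")
  # retained empty unit is later rejected by Jaccard
  expect_error(jaccard_matrix(inc), "U2", class = "karstbeta_value_error")
})

test_that("stratum assignment partitions depth with half-open intervals", {
  expect_identical(assign_stratum(75), "50-100")
  expect_identical(assign_stratum(0), "0-50")
  expect_identical(assign_stratum(850), ">500")
  expect_identical(assign_stratum(50), "50-100")  # boundary goes up
  expect_identical(assign_stratum(500), ">500")
  expect_error(assign_stratum(-1), class = "karstbeta_value_error")

  # total function on [0, Inf): every depth maps to exactly one stratum and
  # the stratum brackets its depth
  breaks <- c(0, 50, 100, 200, 330, 500, Inf)
  set.seed(7)
  for (depth in c(runif(200, 0, 1200), 49.999, 99.999, 329.999, 2000)) {
    s <- assign_stratum(depth)
    k <- match(s, c("0-50", "50-100", "100-200", "200-330", "330-500", ">500"))
    expect_true(depth >= breaks[k] && depth < breaks[k + 1])
  }
  expect_identical(zone_of_stratum("0-50"), "shallow_upper")
  expect_identical(zone_of_stratum("330-500"), "deep_core")
})
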