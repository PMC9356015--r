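test_that("ortholog mapping drops ambiguous and unmapped ids", {
  tab <- data.frame(src = c("A", "B"), tgt = c("a", "b"))
  expect_setequal(map_orthologs(c("A", "B"), tab), c("a", "b"))
  amb <- data.frame(src = c("A", "A"), tgt = c("a", "a2"))
  expect_length(suppressMessages(map_orthologs("A", amb)), 0)
  # a literally duplicated row is not ambiguous
  dup <- data.frame(src = c("A", "A"), tgt = c("a", "a"))
  expect_identical(map_orthologs("A", dup), "a")
  expect_length(suppressMessages(map_orthologs("Z", tab)), 0)
  expect_length(map_orthologs(character(0), tab), 0)
})

test_that("set overlaps report exact pairwise and k-way cardinalities", {
  ov <- overlap_sets(list(a = c("1", "2", "3"), b = c("2", "3", "4"),
                          c = c("3", "4", "5")))
  expect_equal(ov$k_way, 1)
  expect_identical(ov$k_way_genes, "3")
  expect_equal(ov$pairwise$overlap, c(2, 1, 2))
  dis <- overlap_sets(list(c("1"), c("2"), c("3")))
  expect_equal(dis$k_way, 0)
  same <- overlap_sets(list(c("1", "2"), c("1", "2")))
  expect_equal(same$k_way, 2)
})

test_that("permutation overlap p is exact-enumeration-consistent and deterministic", {
  # universe 10, two sets of 5, observed 5: P = 1/choose(10,5) = 1/252
  r <- permutation_overlap_p(c(5, 5), observed = 5, universe_size = 10,
                             n_samplings = 100000, seed = 3)
  exact <- 1 / choose(10, 5)
  mc_se <- sqrt(exact * (1 - exact) / r$n_samplings)
  expect_lt(abs(r$p_empirical - exact), 3 * mc_se + 2 / r$n_samplings)
  # observed 0 is never significant
  r0 <- permutation_overlap_p(c(5, 5), observed = 0, universe_size = 10,
                              n_samplings = 1000, seed = 3)
  expect_equal(r0$p_empirical, 1)
  # determinism
  r2 <- permutation_overlap_p(c(5, 5), observed = 5, universe_size = 10,
                              n_samplings = 5000, seed = 3)
  r3 <- permutation_overlap_p(c(5, 5), observed = 5, universe_size = 10,
                              n_samplings = 5000, seed = 3)
  expect_identical(r2$count_ge, r3$count_ge)
  expect_error(permutation_overlap_p(c(50, 5), 1, universe_size = 10,
                                     n_samplings = 10), "universe")
})

test_that("Monte-Carlo p matches the hypergeometric tail across a grid", {
  grid <- list(
    list(a = 50, b = 80, u = 1000, obs = 8),
    list(a = 100, b = 100, u = 2000, obs = 9),
    list(a = 20, b = 30, u = 200, obs = 5)
  )
  for (g in grid) {
    exact <- hypergeometric_overlap_p(g$a, g$b, g$obs, g$u)
    r <- permutation_overlap_p(c(g$a, g$b), g$obs, universe_size = g$u,
                               n_samplings = 20000, seed = 7)
    mc_se <- sqrt(exact * (1 - exact) / r$n_samplings)
    expect_lt(abs(r$p_empirical - exact), 3 * mc_se + 2 / r$n_samplings)
  }
})

test_that("hypergeometric tail handles the boundary cases", {
  expect_equal(hypergeometric_overlap_p(5, 5, 0, 10), 1)
  expect_equal(hypergeometric_overlap_p(5, 5, 5, 10), 1 / choose(10, 5))
  # A is the whole universe: overlap is forced to |B|
  expect_equal(hypergeometric_overlap_p(10, 4, 4, 10), 1)
  # impossible overlap has probability zero
  expect_equal(hypergeometric_overlap_p(5, 5, 6, 10), 0)
})

test_that("empirical p is monotone non-increasing in observed", {
  ps <- vapply(0:6, function(obs) {
    permutation_overlap_p(c(30, 40), obs, universe_size = 500,
                          n_samplings = 5000, seed = 5)$p_empirical
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("sampling counts are conserved", {
  r <- permutation_overlap_p(c(30, 40), 3, universe_size = 500,
                             n_samplings = 5000, seed = 5)
  expect_lte(r$count_ge, r$n_samplings)
  expect_gte(r$count_ge, 0)
})

test_that("deletion-region exclusion is a plain set difference", {
  s <- sprintf("x%02d", 1:23)
  region <- sprintf("x%02d", c(1:4, 90:93))
  expect_length(exclude_region_genes(s, region), 19)
  expect_setequal(exclude_region_genes(s, character(0)), s)
  expect_length(exclude_region_genes(region[1:4], region), 0)
})

test_that("control split is reproducible and handles degenerate inputs", {
  cfg <- sim_config(n_genes = 300, n_case = c(x = 2, y = 2),
                    n_control = c(x = 6, y = 2), frac_de = 0,
                    ppi_n_edges = 10)
  g <- generate_counts(cfg, "x", seed = 71)
  ctrl <- count_matrix(g$counts$counts[, g$counts$group == "control"],
                       rep("control", 6))
  other <- list(mouse = sprintf("g%05d", 1:30))
  a <- control_split_overlap(ctrl, other, universe_size = 300,
                             n_samplings = 2000, seed = 4)
  b <- control_split_overlap(ctrl, other, universe_size = 300,
                             n_samplings = 2000, seed = 4)
  expect_identical(a$control_degs, b$control_degs)
  expect_identical(a$split, b$split)
  # duplicated identical samples: no variation -> empty DEG set + warning
  one <- g$counts$counts[, 1]
  dup <- matrix(rep(one, 4), ncol = 4,
                dimnames = list(names(one), sprintf("d%d", 1:4)))
  dm <- count_matrix(dup, rep("control", 4))
  expect_warning(
    r <- control_split_overlap(dm, other, universe_size = 300,
                               n_samplings = 500, seed = 4),
    "no variation"
  )
  expect_length(r$control_degs, 0)
  expect_equal(r$overlap$p_empirical, 1)
})

test_that("control-split overlap is null-calibrated on no-signal data", {
  ok <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 1000, n_case = c(x = 3, y = 10),
                      n_control = c(x = 4, y = 10), frac_de = 0,
                      ppi_n_edges = 10, seed = s)
    g <- generate_counts(cfg, "x", seed = s + 500)
    ctrl <- count_matrix(g$counts$counts[, g$counts$group == "control"],
                         rep("control", 4))
    ctrl <- filter_low_counts(ctrl)
    # an unrelated fixed "mouse DEG set" of realistic size
    other <- list(mouse = sprintf("g%05d", 101:200))
    r <- control_split_overlap(ctrl, other, universe_size = 1000,
                               n_samplings = 2000, seed = s)
    ok <- ok + (r$overlap$p_empirical > 0.05)
  }
  expect_gte(ok, 18)
})
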