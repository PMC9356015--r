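test_that("ranking orders by fold change with deterministic tie-break", {
  t <- data.frame(gene_id = c("a", "b", "c"),
                  log2_fold_change = c(2, -1, 0))
  expect_identical(rank_genes(t, "downward")$gene_ids, c("a", "c", "b"))
  expect_identical(rank_genes(t, "upward")$gene_ids, c("b", "c", "a"))
  tie <- data.frame(gene_id = c("b", "a"), log2_fold_change = c(1, 1))
  expect_identical(rank_genes(tie, "downward")$gene_ids, c("a", "b"))
  withna <- data.frame(gene_id = c("a", "b", "c"),
                       log2_fold_change = c(1, NA, 0))
  expect_message(r <- rank_genes(withna, "downward"), "excluded")
  expect_identical(r$gene_ids, c("a", "c"))
})

test_that("hand-worked running sum: N=5, members at ranks 1 and 3", {
  t <- data.frame(gene_id = letters[1:5], log2_fold_change = 5:1)
  r <- rank_genes(t, "downward")
  es <- enrichment_score(r, c("a", "c"))
  expect_equal(es$running_sum,
               c(0.5, 0.5 - 1/3, 0.5 - 1/3 + 0.5, 1/3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
  expect_equal(es$n_module, 2)
})

test_that("prefix placement attains the maximal score of exactly 1", {
  t <- data.frame(gene_id = sprintf("g%03d", 1:50),
                  log2_fold_change = 50:1)
  r <- rank_genes(t, "downward")
  es <- enrichment_score(r, sprintf("g%03d", 1:7))
  expect_identical(es$es, 1)
})

test_that("degenerate module sizes are rejected", {
  t <- data.frame(gene_id = letters[1:4], log2_fold_change = 4:1)
  r <- rank_genes(t, "downward")
  expect_error(enrichment_score(r, "zzz"), "no module gene")
  expect_error(enrichment_score(r, letters[1:4]), "entire ranked list")
})

test_that("running sum conserves to zero and ES stays in [0,1] on random instances", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      n <- sample(10:2000, 1)
      nf <- sample(seq_len(n - 1), 1)
      member <- rep(FALSE, n)
      member[sample.int(n, nf)] <- TRUE
      steps <- ifelse(member, 1 / nf, -1 / (n - nf))
      s <- cumsum(steps)
      expect_lt(abs(s[n]), 1e-9)
      expect_gte(max(s), 0)
      expect_lte(max(s), 1)
    }
  })
})

test_that("fast scorer agrees exactly with the naive oracle", {
  withr::with_seed(202, {
    for (i in 1:1000) {
      n <- sample(5:300, 1)
      nf <- sample(seq_len(n - 1), 1)
      ids <- sprintf("g%04d", seq_len(n))
      t <- data.frame(gene_id = ids,
                      log2_fold_change = seq(n, 1))
      r <- rank_genes(t, "downward")
      members <- sample(ids, nf)
      fast <- enrichment_score(r, members)
      naive <- es_naive(r$gene_ids %in% members)
      # agreement at machine precision (accumulation order differs)
      expect_equal(fast$es, naive$es, tolerance = 1e-12)
      expect_equal(max(abs(fast$running_sum - naive$running_sum)), 0,
                   tolerance = 1e-12)
    }
  })
})

test_that("position-sampled null scores equal the cumulative-sum definition", {
  # the permutation null samples member positions instead of permuting
  # the list; both must give the same score for any fixed placement
  withr::with_seed(303, {
    for (i in 1:200) {
      n <- sample(10:500, 1)
      nf <- sample(seq_len(n - 1), 1)
      pos <- sort(sample.int(n, nf))
      member <- rep(FALSE, n)
      member[pos] <- TRUE
      expect_equal(degmods:::es_from_positions(pos, n, nf),
                   es_naive(member)$es, tolerance = 1e-12)
    }
  })
})

test_that("permutation z is deterministic and recovers a top-loaded module", {
  t <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                  log2_fold_change = seq(5, -5, length.out = 1000))
  r <- rank_genes(t, "downward")
  top <- sprintf("g%04d", 1:10)
  z1 <- permutation_z(r, top, n_perm = 1000, seed = 11)
  z2 <- permutation_z(r, top, n_perm = 1000, seed = 11)
  expect_identical(z1[c("z", "mu", "sigma")], z2[c("z", "mu", "sigma")])
  expect_identical(z1$es, 1)
  expect_gt(z1$z, 2)
})

test_that("null z-scores are self-consistent for random modules", {
  # a module placed uniformly at random has a z whose average over
  # replicates matches the permutation-null mean (~0)
  t <- data.frame(gene_id = sprintf("g%04d", 1:400),
                  log2_fold_change = seq(4, -4, length.out = 400))
  r <- rank_genes(t, "downward")
  zs <- withr::with_seed(42, {
    vapply(1:200, function(i) {
      mod <- sample(r$gene_ids, 15)
      permutation_z(r, mod, n_perm = 250, seed = i)$z
    }, numeric(1))
  })
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("classification applies the two-sided z gate", {
  expect_identical(classify_module(2.5, -1.0), "activated")
  expect_identical(classify_module(-0.3, 3.1), "inactivated")
  expect_identical(classify_module(2.5, 0.5), "neither")
  expect_identical(classify_module(1.9, -1.0), "neither")
  expect_identical(classify_module(NA_real_, 1), "degenerate")
  # mutual exclusivity is structural: both gates cannot fire at once
  withr::with_seed(17, {
    za <- runif(200, -4, 4)
    zi <- runif(200, -4, 4)
    both <- (za > 2 & zi < 0) & (zi > 2 & za < 0)
    expect_false(any(both))
  })
})

test_that("score_all_modules recovers planted direction on shifted data", {
  withr::with_seed(9, {
    n <- 2000
    ids <- sprintf("g%04d", 1:n)
    lfc <- rnorm(n, 0, 0.5)
    up <- sample(ids, 25)
    down <- sample(setdiff(ids, up), 25)
    null_mod <- sample(setdiff(ids, c(up, down)), 25)
    lfc[match(up, ids)] <- lfc[match(up, ids)] + 1.5
    lfc[match(down, ids)] <- lfc[match(down, ids)] - 1.5
    t <- data.frame(gene_id = ids, log2_fold_change = lfc)
    res <- score_all_modules(t, list(up = up, down = down, null = null_mod),
                             n_perm = 500, seed = 13)
    expect_identical(res$status[res$term_id == "up"], "activated")
    expect_identical(res$status[res$term_id == "down"], "inactivated")
    expect_identical(res$status[res$term_id == "null"], "neither")
  })
})

test_that("score_all_modules skips unknown modules without aborting", {
  t <- data.frame(gene_id = sprintf("g%04d", 1:100),
                  log2_fold_change = seq(2, -2, length.out = 100))
  expect_warning(
    res <- score_all_modules(t, list(ok = sprintf("g%04d", 1:5),
                                     gone = c("zz1", "zz2")),
                             n_perm = 100, seed = 2),
    "skipped"
  )
  expect_identical(res$term_id, "ok")
})
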