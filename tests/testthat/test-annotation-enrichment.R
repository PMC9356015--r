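# Synthetic eight-gene deletion-region fixture: four genes expressed in
# brain cortex above 1.5 TPM, two of those also high in blood, the
# remaining four low in cortex.
deletion_fixture <- function() {
  data.frame(
    gene_id = c("FAN1", "MTMR10", "KLF13", "OTUD7A",
                "TRPM1", "CHRNA7", "MIR211", "ARHGAP11B"),
    brain_cortex = c(12.0, 25.3, 18.1, 6.4, 0.3, 1.1, 0.0, 0.2),
    blood = c(0.8, 30.2, 22.6, 0.9, 0.1, 0.4, 0.0, 0.1),
    stringsAsFactors = FALSE
  )
}

test_that("dosage check partitions the eight-gene region into 4 expressed + 4 low", {
  expr <- deletion_fixture()
  dc <- dosage_check(expr$gene_id, expr)
  expect_setequal(dc$brain_cortex$expressed,
                  c("FAN1", "MTMR10", "KLF13", "OTUD7A"))
  expect_length(dc$brain_cortex$low, 4)
  expect_setequal(dc$blood$expressed, c("MTMR10", "KLF13"))
  # threshold 0 marks every positive gene expressed
  dc0 <- dosage_check(expr$gene_id, expr, threshold = 0)
  expect_length(dc0$brain_cortex$expressed, 7)  # MIR211 is exactly 0
  # a value exactly at the threshold is NOT expressed (strict >)
  at <- data.frame(gene_id = "X", brain_cortex = 1.5)
  expect_identical(dosage_check("X", at)$brain_cortex$low, "X")
  # absent region genes are reported, not dropped
  dcm <- dosage_check(c("FAN1", "NOPE"), expr)
  expect_identical(dcm$brain_cortex$missing, "NOPE")
})

test_that("brain-silent DEG selection is strict and tallies missing genes", {
  expr <- data.frame(gene_id = c("a", "b", "c"),
                     brain_cortex = c(0.2, 1.5, 3.0))
  sel <- suppressMessages(
    select_brain_silent_degs(c("a", "b", "c", "d"), expr)
  )
  expect_identical(as.character(sel), "a")
  expect_identical(attr(sel, "no_data"), "d")
})

test_that("flat stage profiles give Tukey p-values of 1", {
  m <- data.frame(gene_id = sprintf("g%d", 1:20),
                  prenatal = rep(c(1, 4), 10), infant = rep(c(1, 4), 10),
                  adult = rep(c(1, 4), 10))
  hsd <- stage_profile_test(m$gene_id, m)
  expect_equal(hsd$p_adj, rep(1, 3), tolerance = 1e-10)
  expect_equal(hsd$diff, rep(0, 3))
})

test_that("well-separated stages are detected below 0.001", {
  withr::with_seed(77, {
    m <- data.frame(gene_id = sprintf("g%d", 1:50),
                    prenatal = rnorm(50, 10, 1),
                    adult = rnorm(50, 0, 1))
    hsd <- stage_profile_test(m$gene_id, m)
    row <- hsd[hsd$stage_a == "adult" & hsd$stage_b == "prenatal", ]
    expect_lt(row$p_adj, 0.001)
    expect_lt(row$diff, 0)
  })
})

test_that("stage test agrees with an independent studentized-range oracle", {
  withr::with_seed(78, {
    for (i in 1:20) {
      k <- sample(3:5, 1)
      ng <- sample(5:30, 1)
      vals <- matrix(rnorm(ng * k, mean = sample(0:3, k, TRUE)), ncol = k)
      m <- data.frame(gene_id = sprintf("g%d", seq_len(ng)), vals)
      names(m) <- c("gene_id", sprintf("st%d", seq_len(k)))
      hsd <- stage_profile_test(m$gene_id, m)
      long <- data.frame(
        value = unlist(m[-1], use.names = FALSE),
        stage = rep(sprintf("st%d", seq_len(k)), each = ng)
      )
      oracle <- tukey_manual(long$value, long$stage)
      key <- paste(hsd$stage_a, hsd$stage_b)
      okey <- paste(oracle$a, oracle$b)
      expect_setequal(key, okey)
      expect_equal(hsd$p_adj[match(okey, key)], oracle$p,
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  })
})

test_that("Tukey-adjusted p is never below the matching two-group p", {
  withr::with_seed(79, {
    for (i in 1:100) {
      k <- sample(3:5, 1)
      ng <- 10
      m <- data.frame(gene_id = sprintf("g%d", 1:ng),
                      matrix(rnorm(ng * k), ncol = k))
      names(m) <- c("gene_id", sprintf("st%d", seq_len(k)))
      hsd <- stage_profile_test(m$gene_id, m)
      # unadjusted pairwise p from the same pooled error term
      long <- data.frame(value = unlist(m[-1], use.names = FALSE),
                         stage = factor(rep(sprintf("st%d", 1:k), each = ng)))
      fit <- stats::aov(value ~ stage, long)
      mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
      se <- sqrt(2 * mse / ng)
      t_p <- 2 * stats::pt(-abs(hsd$diff) / se, stats::df.residual(fit))
      expect_true(all(hsd$p_adj >= t_p - 1e-12))
    }
  })
})

test_that("prenatal-maximum selection is strict on threshold and ties", {
  m <- data.frame(
    gene_id = c("sel", "at_threshold", "tie", "adultmax"),
    prenatal = c(5, 1.5, 5, 2),
    infant = c(2, 0.5, 1, 2.5),
    adult = c(1, 0.2, 5, 6)
  )
  expect_identical(
    suppressMessages(select_prenatal_max(m$gene_id, m)), "sel")
  expect_message(select_prenatal_max(m$gene_id, m), "tied")
  expect_message(select_prenatal_max(c("sel", "unknown"), m), "without stage")
})

test_that("developmental chain recovers exactly the planted truth", {
  cfg <- small_config(seed = 12)
  sim <- simulate_study(cfg)
  true_degs <- sim$truth$true_deg_sets$human
  silent <- select_brain_silent_degs(true_degs, sim$tissue_expr)
  expect_setequal(silent, sim$truth$brain_silent_genes)
  pmax_genes <- select_prenatal_max(silent, sim$stage_expr)
  expect_setequal(pmax_genes, sim$truth$true_prenatal_max_genes)
})

test_that("binomial enrichment reproduces the closed-form toy case", {
  universe <- sprintf("u%02d", 1:20)
  ndd <- universe[1:5]           # p0 = 0.25
  degs <- universe[2:5]          # 4 DEGs, all in the NDD list
  r <- ndd_binomial_enrichment(degs, ndd, universe)
  expect_equal(r$overlap, 4)
  expect_equal(r$p0, 0.25)
  expect_equal(r$p_value, 0.25^4, tolerance = 1e-12)
  # zero overlap is never significant
  r0 <- ndd_binomial_enrichment(universe[6:8], ndd, universe)
  expect_equal(r0$p_value, 1)
  expect_error(ndd_binomial_enrichment("a", "a", character(0)), "universe")
})

test_that("binomial tail matches brute-force pmf summation", {
  withr::with_seed(80, {
    for (i in 1:200) {
      n <- sample(1:60, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.01, 0.99)
      tail_pkg <- if (k <= 0) 1 else pbinom(k - 1, n, p0, lower.tail = FALSE)
      tail_brute <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
      expect_equal(tail_pkg, tail_brute, tolerance = 1e-12)
    }
  })
})

test_that("binomial tail is monotone decreasing in the overlap count", {
  universe <- sprintf("u%03d", 1:100)
  ndd <- universe[1:20]
  ps <- vapply(0:10, function(k) {
    # DEG set of fixed size 12 with k members inside the NDD list
    degs <- c(universe[seq_len(k)], universe[21:(32 - k)])
    ndd_binomial_enrichment(degs, ndd, universe)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
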