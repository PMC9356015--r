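# Independent brute-force oracles, kept deliberately naive so they do
# not share code paths with the package implementations.

# Step-up BH from the definition: sort ascending, adj_(i) = min_{j>=i}
# p_(j) * m / j, capped at 1, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive running-sum enrichment score: explicit O(N) loop straight from
# the definition (score rises 1/Nf at members, falls 1/(N-Nf) else;
# ES = max over positions 1..N).
es_naive <- function(member) {
  n <- length(member)
  nf <- sum(member)
  s <- 0
  best <- -Inf
  path <- numeric(n)
  for (i in seq_len(n)) {
    s <- s + if (member[i]) 1 / nf else -1 / (n - nf)
    path[i] <- s
    best <- max(best, s)
  }
  list(es = best, running_sum = path)
}

# Tukey HSD pairwise adjusted p computed directly from group summaries
# via the studentized range distribution.
tukey_manual <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  means <- tapply(values, groups, mean)
  df_err <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df_err
  combs <- utils::combn(levels(groups), 2)
  data.frame(
    a = combs[2, ], b = combs[1, ],
    p = apply(combs, 2, function(ab) {
      se <- sqrt(mse / 2 * (1 / ns[ab[1]] + 1 / ns[ab[2]]))
      q <- abs(means[ab[1]] - means[ab[2]]) / se
      stats::ptukey(q, k, df_err, lower.tail = FALSE)
    }),
    stringsAsFactors = FALSE
  )
}

# A tiny deterministic count matrix for interface tests.
toy_counts <- function(n_genes = 6, n_case = 3, n_control = 3, seed = 7) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * (n_case + n_control), 40),
                     nrow = n_genes,
                     dimnames = list(
                       sprintf("g%02d", seq_len(n_genes)),
                       sprintf("s%02d", seq_len(n_case + n_control))
                     ))
    count_matrix(counts, c(rep("control", n_control), rep("case", n_case)))
  })
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 1000, ppi_n_edges = 1500, module_sizes = c(12, 12),
         n_prenatal_max = 8, n_ndd_genes = 60, n_background_terms = 10,
         background_term_size = 6),
    list(...)
  )
  do.call(sim_config, args)
}
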