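make_matrix <- function(values, groups) {
  samples <- paste0("S", seq_along(groups))
  dimnames(values) <- list(sprintf("p%02d", seq_len(nrow(values))), samples)
  abundance_matrix(values, stats::setNames(groups, samples))
}

test_that("quantifiability filter applies the >=2-of-4 per-group rule", {
  # p1: 1 of 4 in every group -> removed; p2: 2 of 4 in one group -> kept
  v <- matrix(NA_real_, nrow = 2, ncol = 8)
  v[1, c(1, 5)] <- 10          # one value in each group
  v[2, c(1, 2)] <- 10          # two values in group a only
  m <- make_matrix(v, rep(c("a", "b"), each = 4))
  f <- filter_quantifiable(m, min_reps = 2)
  expect_identical(rownames(f$values), "p02")
  # identity at min_reps 0, idempotent at 2
  expect_identical(filter_quantifiable(m, 0)$values, m$values)
  expect_identical(filter_quantifiable(f, 2)$values, f$values)
  expect_error(filter_quantifiable(m, 5), "exceeds")
})

test_that("identical groups give null calls and zero fold changes", {
  v <- matrix(rep(2^c(10, 12, 14), 8), nrow = 3)
  m <- make_matrix(v, rep(c("t", "c"), each = 4))
  d <- differential(m, "t", "c")
  expect_true(all(d$direction == "ns"))
  expect_true(all(d$log2fc == 0))
  expect_true(all(d$p == 1))
})

test_that("row-wise Welch statistics match stats::t.test, fdr matches BH", {
  set.seed(17)
  v <- 2^matrix(rnorm(25 * 8, 20, 2), nrow = 25)
  m <- make_matrix(v, rep(c("t", "c"), each = 4))
  d <- differential(m, "t", "c")
  lg <- log2(v)
  for (i in c(1, 9, 25)) {
    tt <- t.test(lg[i, 1:4], lg[i, 5:8])
    expect_equal(d$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(d$log2fc[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  expect_equal(d$fdr, p.adjust(d$p, "BH"))
  # direction invariant from the DapRecord contract
  expect_true(all(d$direction[d$fdr < 0.05 & d$log2fc > 0] == "up"))
  expect_true(all((d$fdr >= 0.05) == (d$direction == "ns")))
})

test_that("Benjamini-Hochberg step-up on a hand-worked p-vector", {
  # m = 4: max over j>=i of p_j * 4/j; all equal 0.04 here
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("groups with fewer than two samples are rejected", {
  v <- 2^matrix(rnorm(6 * 3, 20, 1), nrow = 6)
  m <- make_matrix(v, c("t", "c", "c"))
  expect_error(differential(m, "t", "c"), "at least 2")
  expect_error(differential(m, "t", "nope"), "not in design")
})

test_that("imputation is seeded and reproducible", {
  set.seed(2)
  v <- 2^matrix(rnorm(40 * 8, 20, 2), nrow = 40)
  v[sample(length(v), 30)] <- NA
  m <- make_matrix(v, rep(c("t", "c"), each = 4))
  d1 <- differential(m, "t", "c", seed = 5)
  d2 <- differential(m, "t", "c", seed = 5)
  d3 <- differential(m, "t", "c", seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1$p, d3$p))
})

test_that("true fold changes are recovered from fully observed data", {
  cfg <- generator_config(n_proteins = 600, length_range = c(60, 150),
                          n_dap_up = 40, n_dap_down = 40,
                          missing_rate = 0, seed = 23)
  sim <- gen_experiment(cfg)
  d <- differential(filter_quantifiable(sim$abundance), "HA", "control",
                    seed = 23)
  truth <- stats::setNames(sim$truth$role, sim$truth$protein_id)[d$protein_id]
  called <- d$direction != "ns"
  recall <- sum(d$direction == truth & truth != "null") / sum(truth != "null")
  precision <- mean(truth[called] == d$direction[called])
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("Fisher exact matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:60) {
    tb <- sample(0:12, 4, replace = TRUE)
    p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_enum_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
  }
})

test_that("identical up/down pI multisets give a null shift", {
  pis <- stats::setNames(c(5, 6, 7.5, 9, 5, 6, 7.5, 9), paste0("p", 1:8))
  daps <- data.frame(protein_id = paste0("p", 1:8),
                     direction = rep(c("up", "down"), each = 4))
  s <- acidity_shift(daps, pis, n_perm = 499, seed = 3)
  expect_equal(s$delta_median_pi, 0)
  expect_equal(s$perm_p, 1)
})

test_that("the 2x2 worked case: counts and exact p from the pI table", {
  pis <- stats::setNames(c(5, 5.5, 6, 9, 6.5, 8, 9.5, 10), paste0("p", 1:8))
  daps <- data.frame(protein_id = paste0("p", 1:8),
                     direction = rep(c("up", "down"), each = 4))
  s <- acidity_shift(daps, pis, n_perm = 99, seed = 1)
  expect_equal(unname(s$counts), c(3, 1, 1, 3))
  expect_equal(s$fisher_p, 34 / 70, tolerance = 1e-12)
})

test_that("acidity_shift is invariant to ordering and relabeling", {
  set.seed(44)
  ids <- sprintf("q%03d", 1:60)
  pis <- stats::setNames(runif(60, 3, 11), ids)
  daps <- data.frame(protein_id = ids,
                     direction = rep(c("up", "down", "ns"), each = 20))
  s1 <- acidity_shift(daps, pis, n_perm = 299, seed = 9)
  perm <- sample(60)
  s2 <- acidity_shift(daps[perm, ], pis, n_perm = 299, seed = 9)
  relab <- stats::setNames(sprintf("r%03d", 1:60), ids)
  daps3 <- transform(daps, protein_id = unname(relab[protein_id]))
  pis3 <- stats::setNames(pis, unname(relab[names(pis)]))
  s3 <- acidity_shift(daps3, pis3, n_perm = 299, seed = 9)
  for (s in list(s2, s3)) {
    expect_equal(s$counts, s1$counts)
    expect_equal(s$delta_median_pi, s1$delta_median_pi)
    expect_equal(s$fisher_p, s1$fisher_p)
    expect_equal(s$perm_p, s1$perm_p)
  }
})

test_that("empty direction sets and missing pIs are rejected", {
  pis <- stats::setNames(c(5, 9), c("a", "b"))
  expect_error(acidity_shift(data.frame(protein_id = c("a", "b"),
                                        direction = c("up", "ns")),
                             pis), "each direction")
  expect_error(acidity_shift(data.frame(protein_id = c("a", "c"),
                                        direction = c("up", "down")),
                             pis), "no pI")
})
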