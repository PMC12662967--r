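demo_matrix <- function() {
  v <- rbind(c(2, 4, 6, 8), c(4, 8, NA, 16), c(NA, NA, 1, 2))
  dimnames(v) <- list(c("p1", "p2", "p3"), paste0("S", 1:4))
  abundance_matrix(v, stats::setNames(rep(c("a", "b"), each = 2),
                                      paste0("S", 1:4)))
}

test_that("set abundance summarizes per sample and propagates missingness", {
  m <- demo_matrix()
  expect_equal(unname(set_abundance(m, c("p1", "p2"))),
               c(3, 6, 6, 12))
  expect_true(is.na(set_abundance(m, "p3")[["S1"]]))
  full <- set_abundance(m, c("p1", "p2"))[c("S1", "S2", "S4")]
  expect_equal(unname(set_abundance(m, c("p1", "p2"),
                                    "sum")[c("S1", "S2", "S4")]),
               unname(full) * 2)
  expect_error(set_abundance(m, character(0)), "empty")
  expect_error(set_abundance(m, "nope"), "not in matrix")
})

test_that("perfectly monotone pairs give rho of +1 and -1", {
  chem <- data.frame(sample_id = paste0("S", 1:4),
                     TA = c(10, 20, 30, 40), pH = c(8, 6, 4, 2),
                     temp = 26, sal = 33)
  av <- list(up = stats::setNames(c(1, 2, 3, 4), paste0("S", 1:4)))
  g <- correlate_grid(av, chem, parameters = c("alkalinity", "pH"))
  expect_equal(g$rho[g$parameter == "alkalinity"], 1)
  expect_equal(g$rho[g$parameter == "pH"], -1)
})

test_that("spearman rho equals the direct rank-formula oracle", {
  set.seed(13)
  x <- stats::setNames(rnorm(5), paste0("S", 1:5))
  y <- rnorm(5)
  chem <- data.frame(sample_id = paste0("S", 1:5), param = y)
  g <- correlate_grid(list(s = x), chem, parameters = "param")
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(g$rho, oracle, tolerance = 1e-12)
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(19)
  x <- stats::setNames(runif(8, 1, 5), paste0("S", 1:8))
  y <- runif(8, 1, 5)
  chem1 <- data.frame(sample_id = names(x), param = y)
  chem2 <- data.frame(sample_id = names(x), param = exp(2 * y))
  g1 <- correlate_grid(list(s = x), chem1, parameters = "param")
  g2 <- correlate_grid(list(s = exp(x)), chem2, parameters = "param")
  expect_equal(g1$rho, g2$rho, tolerance = 1e-12)
})

test_that("grid-wide BH adjustment dominates raw p and is rank-monotone", {
  set.seed(29)
  av <- lapply(1:4, function(i) stats::setNames(rnorm(10), paste0("S", 1:10)))
  names(av) <- paste0("set", 1:4)
  chem <- data.frame(sample_id = paste0("S", 1:10),
                     TA = rnorm(10), pH = rnorm(10), temp = 26, sal = 33)
  g <- correlate_grid(av, chem, parameters = c("alkalinity", "pH"))
  expect_true(all(g$fdr >= g$p))
  o <- order(g$p)
  expect_true(all(diff(g$fdr[o]) >= -1e-12))
})

test_that("constant vectors yield a warning and a missing rho", {
  chem <- data.frame(sample_id = paste0("S", 1:4), param = c(1, 2, 3, 4))
  av <- list(flat = stats::setNames(rep(5, 4), paste0("S", 1:4)))
  expect_warning(g <- correlate_grid(av, chem, parameters = "param"),
                 "constant")
  expect_true(is.na(g$rho))
})

test_that("fewer than three complete pairs is an error", {
  chem <- data.frame(sample_id = paste0("S", 1:4), param = c(1, 2, NA, NA))
  av <- list(s = stats::setNames(c(1, 2, 3, NA), paste0("S", 1:4)))
  expect_error(correlate_grid(av, chem, parameters = "param"), "fewer than 3")
})

test_that("alkalinity-coupled generator data recovers the correlation signs", {
  cfg <- generator_config(n_proteins = 400, length_range = c(60, 120),
                          n_dap_up = 0, n_dap_down = 0, missing_rate = 0,
                          alk_coupling = 0.5, seed = 37)
  sim <- gen_experiment(cfg)
  acidic <- top_n_by_residue(sim$proteome, "D", 60)
  basic <- top_n_by_residue(sim$proteome, "K", 60)
  av <- list(D = set_abundance(sim$abundance, acidic),
             K = set_abundance(sim$abundance, basic))
  g <- correlate_grid(av, sim$chemistry)
  d_alk <- g[g$set_label == "D" & g$parameter == "alkalinity", ]
  k_alk <- g[g$set_label == "K" & g$parameter == "alkalinity", ]
  expect_gt(d_alk$rho, 0)
  expect_lt(d_alk$fdr, 0.05)
  expect_lt(k_alk$rho, 0)
})
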