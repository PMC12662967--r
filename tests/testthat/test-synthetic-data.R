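test_that("config invariants are enforced", {
  expect_error(generator_config(n_proteins = 10, n_dap_up = 8, n_dap_down = 8))
  expect_error(generator_config(missing_rate = 1))
  expect_error(generator_config(treatments = c(a = 1, b = 4)))
  expect_error(generator_config(baseline_class_weights = c(acidic = 1)),
               "class_weights")
  expect_error(generator_config(
    treatments = c(control = 2, odd = 2)), "chem_profile")
})

test_that("single-class composition forces pI to the matching side", {
  only <- function(cls) {
    w <- c(acidic = 0, basic = 0, nonpolar = 0, polar = 0)
    w[cls] <- 1
    generator_config(n_proteins = 25, length_range = c(30, 60),
                     n_dap_up = 0, n_dap_down = 0,
                     baseline_class_weights = w, seed = 9)
  }
  expect_true(all(proteome_pis(gen_proteome(only("acidic")))$pi < 7))
  expect_true(all(proteome_pis(gen_proteome(only("basic")))$pi > 7))
})

test_that("generation is deterministic under the seed", {
  cfg <- small_generator_config(seed = 5)
  p1 <- gen_proteome(cfg); p2 <- gen_proteome(cfg)
  expect_identical(p1, p2)
  p3 <- gen_proteome(small_generator_config(seed = 6))
  expect_false(identical(p1$seq, p3$seq))

  s1 <- gen_experiment(cfg, p1)
  s2 <- gen_experiment(cfg, p1)
  expect_identical(s1$abundance$values, s2$abundance$values)
  expect_identical(s1$chemistry, s2$chemistry)
  expect_identical(s1$truth, s2$truth)
})

test_that("missingness honors its rate and left-censoring mechanism", {
  cfg0 <- small_generator_config(seed = 7, missing_rate = 0)
  expect_false(anyNA(gen_experiment(cfg0)$abundance$values))

  cfg <- generator_config(n_proteins = 500, length_range = c(40, 80),
                          n_dap_up = 0, n_dap_down = 0,
                          missing_rate = 0.15, seed = 8)
  sim <- gen_experiment(cfg)
  v <- sim$abundance$values
  expect_equal(mean(is.na(v)), 0.15, tolerance = 0.02)
  # censoring is at low intensity: observed floor well above the
  # all-missing case is hard to read directly, so compare protein means
  prot_mean <- rowMeans(log2(v), na.rm = TRUE)
  na_count <- rowSums(is.na(v))
  heavy <- na_count >= 5 & is.finite(prot_mean)
  expect_lt(mean(prot_mean[heavy]), mean(prot_mean[na_count == 0]))
})

test_that("nonzero pI shift targets are matched within tolerance", {
  cfg <- generator_config(n_proteins = 900, length_range = c(60, 120),
                          n_dap_up = 60, n_dap_down = 60,
                          pi_shift_delta = -0.8, seed = 15)
  sim <- gen_experiment(cfg)
  tr <- sim$truth
  d <- mean(tr$pi[tr$role == "up"]) - mean(tr$pi[tr$role == "down"])
  expect_lt(abs(d - (-0.8)), 0.05)

  cfg2 <- generator_config(n_proteins = 900, length_range = c(60, 120),
                           n_dap_up = 60, n_dap_down = 60,
                           pi_shift_delta = 0.8, seed = 16)
  tr2 <- gen_experiment(cfg2)$truth
  d2 <- mean(tr2$pi[tr2$role == "up"]) - mean(tr2$pi[tr2$role == "down"])
  expect_lt(abs(d2 - 0.8), 0.05)
})

test_that("a null shift target gives exchangeable sets centred on zero", {
  # delta = 0 draws an unconstrained random split, so single draws
  # scatter with sd ~ 2*sqrt(2/n); the mean over seeds must vanish
  diffs <- vapply(1:12, function(s) {
    cfg <- generator_config(n_proteins = 400, length_range = c(40, 80),
                            n_dap_up = 40, n_dap_down = 40,
                            pi_shift_delta = 0, seed = 100 + s)
    tr <- gen_experiment(cfg)$truth
    mean(tr$pi[tr$role == "up"]) - mean(tr$pi[tr$role == "down"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.05)
})

test_that("unattainable shift targets fail with the attainable range", {
  cfg <- generator_config(n_proteins = 200, length_range = c(40, 80),
                          n_dap_up = 50, n_dap_down = 50,
                          pi_shift_delta = -9, seed = 3)
  expect_error(gen_experiment(cfg), "attainable range")
})

test_that("chemistry table mirrors the treatment profile with small jitter", {
  cfg <- small_generator_config(seed = 19)
  chem <- gen_experiment(cfg)$chemistry
  expect_equal(nrow(chem), sum(cfg$treatments))
  prof <- cfg$chem_profile
  for (g in names(cfg$treatments)) {
    rows <- chem[chem$group == g, ]
    expect_true(all(abs(rows$TA / prof$TA[prof$group == g] - 1) < 0.05))
    expect_true(all(abs(rows$pH - prof$pH[prof$group == g]) < 0.05))
  }
  expect_true(all(c("co2", "hco3", "co3", "dic", "buffer") %in% names(chem)))
})

test_that("truth table scores every injected assignment", {
  cfg <- small_generator_config(seed = 21)
  sim <- gen_experiment(cfg)
  expect_equal(sum(sim$truth$role == "up"), cfg$n_dap_up)
  expect_equal(sum(sim$truth$role == "down"), cfg$n_dap_down)
  expect_equal(sort(unique(sim$truth$true_lfc)),
               c(-cfg$lfc_effect, 0, cfg$lfc_effect))
  expect_identical(sim$truth$protein_id, sim$proteome$id)
})
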