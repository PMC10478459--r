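test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_lines = 10, lines_per_trial = c(20, 45)),
               "exceeds")
  expect_error(sim_config(allele_freq_range = c(0, 0.5)), "within")
  expect_error(sim_config(true_vc_phenotype = c(alpha = -1, g1 = 1, l1 = 1,
                                                ig1 = 1, il1 = 1, t1 = 1,
                                                e1 = 1)),
               "non-negative")
  expect_error(sim_config(years = character(0)), "at least one year")
})

test_that("minimal design: one line, one env, three replicates", {
  cfg <- sim_config(n_lines = 1, n_control_lines = 0,
                    lines_per_trial = c(1, 1), years = "Y1",
                    locations = "L1", seed = 3)
  d <- simulate_design(cfg)
  expect_equal(nrow(d), 3L)
  expect_equal(length(unique(d$trial)), 1L)
  expect_equal(length(unique(d$env)), 1L)
  expect_true(all(d$line_id == "L0001"))
})

test_that("design covers every line and nests trials in six environments", {
  cfg <- tiny_cfg(n_lines = 20, years = c("Y1", "Y2", "Y3"),
                  locations = c("A", "B"), lines_per_trial = c(5, 8),
                  seed = 9)
  d <- simulate_design(cfg)
  expect_setequal(unique(d$line_id), sprintf("L%04d", 1:20))
  envs <- unique(d$env)
  expect_equal(sort(envs),
               sort(as.vector(outer(c("A", "B"), c("Y1", "Y2", "Y3"),
                                    paste, sep = ":"))))
  ## each line appears the configured number of times per trial
  counts <- table(d$trial, d$line_id)
  expect_true(all(counts %in% c(0L, cfg$replicates_per_line)))
  ## each trial sits in exactly one environment; every plot has a batch
  expect_true(all(tapply(d$env, d$trial,
                         function(e) length(unique(e))) == 1L))
  expect_false(any(is.na(d$batch)))
  ## controls appear in every trial
  for (ctrl in sprintf("L%04d", seq_len(cfg$n_control_lines)))
    expect_true(all(tapply(d$line_id, d$trial, function(l) ctrl %in% l)))
})

test_that("the seed fully determines all generated data", {
  cfg <- tiny_cfg(seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$plots, d2$plots)
  expect_identical(d1$geno, d2$geno)
  expect_identical(d1$M_raw, d2$M_raw)
  expect_identical(d1$truth$breeding_values, d2$truth$breeding_values)
  d3 <- simulate_dataset(tiny_cfg(seed = 78))
  expect_false(identical(d1$plots$y, d3$plots$y))
})

test_that("genotype codes are 0/1/2 with frequencies near the draw", {
  cfg <- tiny_cfg(n_lines = 400, n_markers = 50,
                  allele_freq_range = c(0.5, 0.5), seed = 5)
  g <- simulate_genotypes(cfg)
  expect_true(all(g %in% 0:2))
  expect_equal(mean(g), 1, tolerance = 0.05)
  expect_error(simulate_genotypes(tiny_cfg(n_markers = 0)), "undefined")
})

test_that("feature generator honours the null model and design identities", {
  ## residual-only features: no between-line signal
  cfg0 <- tiny_cfg(n_features = 200,
                   true_vc_features = c(g2 = 0, l2 = 0, ig2 = 0, il2 = 0,
                                        t2 = 0, e2 = 1),
                   seed = 21)
  d <- simulate_design(cfg0)
  G <- compute_G(qc_markers(simulate_genotypes(cfg0)))
  f0 <- simulate_features(d, G, cfg0)
  line_means <- rowsum(f0$M, d$line_id) / as.vector(table(d$line_id))
  ## variance of line means is the within-line sampling noise, about 1/reps
  expect_lt(mean(apply(line_means, 2, var)), 0.6)

  ## no residual: plots sharing line, env and batch are identical
  cfg1 <- tiny_cfg(true_vc_features = c(g2 = 0.5, l2 = 0.3, ig2 = 0.2,
                                        il2 = 0.2, t2 = 0.2, e2 = 0),
                   seed = 22)
  d1 <- simulate_design(cfg1)
  f1 <- simulate_features(d1, G, cfg1)
  key <- paste(d1$line_id, d1$env, d1$batch)
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  grp <- split(dup, key[dup])
  grp <- grp[lengths(grp) > 1]
  expect_gt(length(grp), 0)
  for (g2 in grp[1:3])
    expect_equal(f1$M[g2[1], ], f1$M[g2[2], ])
})

test_that("genomic feature variance matches G-bar over many features", {
  cfg <- tiny_cfg(n_lines = 40, n_features = 1500,
                  lines_per_trial = c(15, 20),
                  true_vc_features = c(g2 = 0.4, l2 = 0, ig2 = 0, il2 = 0,
                                       t2 = 0, e2 = 0),
                  seed = 31)
  d <- simulate_design(cfg)
  G <- compute_G(qc_markers(simulate_genotypes(cfg)))
  f <- simulate_features(d, G, cfg)
  ## per line, the variance across features is G[l,l] * s2_g2;
  ## averaged over lines this is G_bar * s2_g2
  per_line <- f$M[!duplicated(d$line_id), , drop = FALSE]
  emp <- mean(apply(per_line, 1, var))
  expected <- mean(diag(G)) * 0.4
  se <- expected * sqrt(2 / cfg$n_features)
  expect_lt(abs(emp - expected), 4 * se)
})

test_that("breeding values obey the identity a = sum_j g_j2 alpha_j + g1", {
  dat <- simulate_dataset(tiny_cfg(seed = 41))
  recon <- drop(dat$truth$g_j2 %*% dat$truth$alpha) + dat$truth$g1
  expect_equal(unname(recon), unname(dat$truth$breeding_values),
               tolerance = 1e-12)
})

test_that("metabolomic share of phenotypic variance matches the config", {
  ## empirical var(M alpha) / var(y) across replicates approximates
  ## c_m^2 = q s2_alpha / s2_P1 (Q_bar = 1 by construction)
  cfg0 <- tiny_cfg(seed = 0)
  vcp <- cfg0$true_vc_phenotype
  s2u <- cfg0$n_features * vcp[["alpha"]]
  ratios <- vapply(1:25, function(i) {
    dat <- simulate_dataset(tiny_cfg(seed = 500 + i))
    var(dat$truth$u) / var(dat$plots$y)
  }, numeric(1))
  Gbar <- 1 # close to 1; exact value varies per replicate with the markers
  s2P <- s2u + Gbar * (vcp[["g1"]] + vcp[["ig1"]]) + vcp[["l1"]] +
    vcp[["il1"]] + vcp[["t1"]] + vcp[["e1"]]
  c2m <- s2u / s2P
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - c2m), 4 * se + 0.02)
})
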