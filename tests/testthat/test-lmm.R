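test_that("single-observation BLUP matches the closed form", {
  ## y = g + e, scalar G = 1, both variances 1: g_hat = (1+1)^-1 * 2 = 1
  K <- matrix(1, dimnames = list("A", "A"))
  term <- lmm_term("g", "K", map = "A", K = K)
  X <- matrix(nrow = 1, ncol = 0)
  sol <- blup_solve(2, X, list(g = term), c(g = 1, residual = 1))
  expect_equal(unname(sol$random$g), 1)
  ## shrinkage limit: zero genetic variance
  sol0 <- blup_solve(2, X, list(g = term), c(g = 0, residual = 1))
  expect_equal(unname(sol0$random$g), 0)
})

test_that("BLUP solutions match a dense mixed-model-equation oracle", {
  cfg <- tiny_cfg(n_lines = 10, n_markers = 60, n_features = 2,
                  lines_per_trial = c(4, 5), seed = 13)
  dat <- simulate_dataset(cfg)
  s2 <- c(g = 0.5, l = 0.2, ig = 0.3, il = 0.15, t = 0.1, residual = 0.4)
  des <- build_design(dat$plots, "y", dat$G)
  sol <- blup_solve(des$y, des$X, des$terms, s2)
  parts <- trial_model_parts(dat$plots, dat$G, s2)
  orc <- mme_oracle(parts$y, parts$X, parts$random, s2[["residual"]])
  ## fixed effects (same cell-means coding up to level order)
  expect_equal(sort(unname(sol$fixed)), sort(orc$b), tolerance = 1e-6)
  ## per-line genomic effects
  expect_equal(unname(sol$random$g), orc$u[[1]], tolerance = 1e-6)
  ## line effects (observed levels)
  l_or <- orc$u[[2]]
  expect_equal(unname(sol$random$l[rownames(dat$G)]), l_or,
               tolerance = 1e-6)
  ## G x E effects, stacked line-within-env
  expect_equal(as.vector(sol$random$ig), orc$u[[3]], tolerance = 1e-6)
  ## batch effects
  expect_equal(unname(sol$random$t[levels(factor(des$plots$batch))]),
               orc$u[[5]], tolerance = 1e-6)
})

test_that("REML recovers variance components on simulated data", {
  ## small but real recovery check (the full-scale one lives in the
  ## acceptance suite): residual-dominated data drives g to the floor
  cfg <- tiny_cfg(n_lines = 30, n_features = 2,
                  lines_per_trial = c(12, 15),
                  true_vc_phenotype = c(alpha = 0, g1 = 0, l1 = 0, ig1 = 0,
                                        il1 = 0, t1 = 0, e1 = 1),
                  seed = 55)
  dat <- simulate_dataset(cfg)
  fit <- fit_gblup(dat$plots, dat$G)
  expect_true(fit$converged)
  expect_lt(fit$vc[["g"]], 0.05)
  expect_equal(fit$vc[["residual"]], 1, tolerance = 0.35)
})

test_that("REML needs more observations than fixed-effect columns", {
  K <- diag(2); dimnames(K) <- list(c("A", "B"), c("A", "B"))
  term <- lmm_term("g", "K", map = c("A", "B"), K = K)
  expect_error(reml_fit(c(1, 2), diag(2), list(g = term)),
               "more observations")
})

test_that("restricted likelihood is invariant to the fixed-effect coding", {
  cfg <- tiny_cfg(n_lines = 16, n_features = 2, lines_per_trial = c(6, 7),
                  seed = 19)
  dat <- simulate_dataset(cfg)
  des <- build_design(dat$plots, "y", dat$G)
  vc <- c(g = 0.4, l = 0.2, ig = 0.2, il = 0.1, t = 0.1, residual = 0.5)
  ll_cell <- mgblup:::.reml_eval(unname(vc), des$y, des$X,
                                 lapply(des$terms, mgblup:::term_V))$loglik
  ## treatment coding spans the same column space
  cell <- factor(colnames(des$X)[apply(des$X, 1, which.max)])
  Xtrt <- model.matrix(~cell)
  ll_trt <- mgblup:::.reml_eval(unname(vc), des$y, Xtrt,
                                lapply(des$terms, mgblup:::term_V))$loglik
  expect_equal(ll_cell, ll_trt, tolerance = 1e-8)
})

test_that("scaling the response scales every variance component by c^2", {
  cfg <- tiny_cfg(n_lines = 20, n_features = 2, lines_per_trial = c(8, 10),
                  seed = 23)
  dat <- simulate_dataset(cfg)
  f1 <- fit_gblup(dat$plots, dat$G)
  plots2 <- dat$plots
  plots2$y <- plots2$y * 3
  f2 <- fit_gblup(plots2, dat$G)
  expect_equal(unname(f2$vc), unname(f1$vc) * 9, tolerance = 1e-3)
})

test_that("phenotype correction removes trial and batch effects", {
  cfg <- tiny_cfg(n_lines = 20, n_features = 2, trial_effect_sd = 2,
                  seed = 29)
  dat <- simulate_dataset(cfg)
  fit <- fit_gblup(dat$plots, dat$G)
  corr <- correct_phenotypes(fit)
  expect_named(corr)
  ## adding a constant to one trial is absorbed by its fixed effect
  plots2 <- dat$plots
  tr1 <- plots2$trial == plots2$trial[1]
  plots2$y[tr1] <- plots2$y[tr1] + 50
  fit2 <- fit_gblup(plots2, dat$G, vc = fit$vc)
  corr2 <- correct_phenotypes(fit2)
  base <- correct_phenotypes(fit_gblup(dat$plots, dat$G, vc = fit$vc))
  expect_equal(corr2[dat$plots$plot_id[tr1]], base[dat$plots$plot_id[tr1]],
               tolerance = 1e-6)
  ## corrected values center near zero within trial cells, unlike raw y
  cell_means <- tapply(corr, dat$plots$trial[match(names(corr),
                                                   dat$plots$plot_id)],
                       mean)
  raw_means <- tapply(dat$plots$y, dat$plots$trial, mean)
  expect_lt(mean(abs(cell_means)), mean(abs(raw_means - mean(dat$plots$y))))
})
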