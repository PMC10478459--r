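test_that("GBLUP recovers genetic signal and honours the zero-variance limit", {
  cfg <- tiny_cfg(n_lines = 60, n_features = 2, lines_per_trial = c(20, 30),
                  true_vc_phenotype = c(alpha = 0, g1 = 1, l1 = 0.1,
                                        ig1 = 0.1, il1 = 0.1, t1 = 0.1,
                                        e1 = 0.5),
                  seed = 101)
  dat <- simulate_dataset(cfg)
  fit <- fit_gblup(dat$plots, dat$G)
  r_strong <- cor(fit$breeding_values, dat$truth$g1)
  expect_gt(r_strong, 0.3)

  ## weaker genetic signal, same seed structure: lower accuracy
  cfg_w <- tiny_cfg(n_lines = 60, n_features = 2,
                    lines_per_trial = c(20, 30),
                    true_vc_phenotype = c(alpha = 0, g1 = 0.02, l1 = 0.1,
                                          ig1 = 0.1, il1 = 0.1, t1 = 0.1,
                                          e1 = 2),
                    seed = 101)
  dat_w <- simulate_dataset(cfg_w)
  fit_w <- fit_gblup(dat_w$plots, dat_w$G)
  expect_lt(cor(fit_w$breeding_values, dat_w$truth$g1), r_strong)

  ## fixed zero genomic variance: all predictions vanish
  vc0 <- c(g = 0, l = 0.2, ig = 0.1, il = 0.1, t = 0.1, residual = 0.5)
  fit0 <- fit_gblup(dat$plots, dat$G, vc = vc0)
  expect_equal(max(abs(fit0$breeding_values)), 0)
})

test_that("unphenotyped lines are predicted through genomic covariance", {
  cfg <- tiny_cfg(n_lines = 25, n_features = 2, seed = 103)
  dat <- simulate_dataset(cfg)
  drop_line <- dat$plots$line_id[1]
  plots <- dat$plots
  plots$y[plots$line_id == drop_line] <- NA
  fit <- fit_gblup(plots, dat$G)
  expect_true(drop_line %in% names(fit$breeding_values))
  ## the masked line's prediction responds only to its relatives
  expect_true(is.finite(fit$breeding_values[drop_line]))
})

test_that("two-step MGBLUP equals the joint-model oracle", {
  cfg <- tiny_cfg(n_lines = 12, n_markers = 80, n_features = 15,
                  lines_per_trial = c(5, 6), seed = 107)
  dat <- simulate_dataset(cfg)
  M <- standardize_features(dat$M_raw)
  q <- ncol(M)
  s2_alpha <- 0.02
  vc1 <- c(g = 0.3, l = 0.15, ig = 0.2, il = 0.1, t = 0.1, residual = 0.4)
  vc2 <- c(g = 0.25, l = 0.1, ig = 0.15, il = 0.1, t = 0.1, residual = 0.5)
  fit <- fit_mgblup(dat$plots, dat$G, M,
                    vc = list(step1 = c(u = q * s2_alpha, vc1),
                              step2 = vc2 * (q * s2_alpha)))
  a_oracle <- joint_model_bv(dat$plots, dat$G, M, s2_alpha, vc1, vc2)
  expect_equal(unname(fit$breeding_values), a_oracle, tolerance = 1e-4)
  ## the assembled breeding value is exactly g1 + g2
  expect_equal(fit$breeding_values,
               fit$step1$solution$random$g + fit$step2$solution$random$g)
})

test_that("MGBLUP collapses to GBLUP without metabolomic signal", {
  cfg <- tiny_cfg(n_lines = 20, n_features = 25, seed = 109)
  dat <- simulate_dataset(cfg)
  M <- standardize_features(dat$M_raw)
  vc <- c(g = 0.4, l = 0.15, ig = 0.2, il = 0.1, t = 0.1, residual = 0.5)
  g_fit <- fit_gblup(dat$plots, dat$G, vc = vc)
  m_fit <- fit_mgblup(dat$plots, dat$G, M,
                      vc = list(step1 = c(u = 1e-10, vc),
                                step2 = c(vc * 1e-10)))
  expect_equal(unname(m_fit$breeding_values),
               unname(g_fit$breeding_values), tolerance = 1e-4)
})

test_that("plot order does not affect predicted breeding values", {
  cfg <- tiny_cfg(n_lines = 15, n_features = 20, seed = 113)
  dat <- simulate_dataset(cfg)
  M <- standardize_features(dat$M_raw)
  vc <- list(step1 = c(u = 0.5, g = 0.3, l = 0.15, ig = 0.2, il = 0.1,
                       t = 0.1, residual = 0.4),
             step2 = c(g = 0.25, l = 0.1, ig = 0.15, il = 0.1, t = 0.1,
                       residual = 0.5))
  f1 <- fit_mgblup(dat$plots, dat$G, M, vc = vc)
  perm <- sample(nrow(dat$plots))
  f2 <- fit_mgblup(dat$plots[perm, ], dat$G, M[perm, ], vc = vc)
  expect_equal(f1$breeding_values, f2$breeding_values, tolerance = 1e-8)
})

test_that("scenario masking rules are honoured", {
  cfg <- tiny_cfg(n_lines = 18, n_features = 20, seed = 127)
  dat <- simulate_dataset(cfg)
  vp_lines <- sort(unique(dat$plots$line_id))[1:4]
  vp_plots <- dat$plots$plot_id[dat$plots$line_id %in% vp_lines &
                                  !dat$plots$is_control]
  vc <- list(step1 = c(u = 0.5, g = 0.3, l = 0.15, ig = 0.2, il = 0.1,
                       t = 0.1, residual = 0.4),
             step2 = c(g = 0.25, l = 0.1, ig = 0.15, il = 0.1, t = 0.1,
                       residual = 0.5))
  ## scenario g ignores validation features entirely
  p1 <- predict_scenario(dat$plots, dat$G, dat$M_raw, model = "mgblup",
                         masked_plots = vp_plots, scenario = "g", vc = vc)
  M_scrambled <- dat$M_raw
  vp_rows <- rownames(M_scrambled) %in% vp_plots
  M_scrambled[vp_rows, ] <- matrix(rnorm(sum(vp_rows) * ncol(M_scrambled)),
                                   sum(vp_rows))
  p2 <- predict_scenario(dat$plots, dat$G, M_scrambled, model = "mgblup",
                         masked_plots = vp_plots, scenario = "g", vc = vc)
  expect_equal(p1$breeding_values, p2$breeding_values, tolerance = 1e-10)

  ## scenario gm uses validation features: predictions change
  p3 <- predict_scenario(dat$plots, dat$G, dat$M_raw, model = "mgblup",
                         masked_plots = vp_plots, scenario = "gm", vc = vc)
  expect_false(isTRUE(all.equal(p1$breeding_values[vp_lines],
                                p3$breeding_values[vp_lines],
                                tolerance = 1e-6)))

  ## gp and gmp coincide for GBLUP (no metabolomic data used)
  vcg <- vc$step2
  g1 <- predict_scenario(dat$plots, dat$G, model = "gblup",
                         masked_plots = vp_plots, scenario = "gp", vc = vcg)
  g2 <- predict_scenario(dat$plots, dat$G, model = "gblup",
                         masked_plots = vp_plots, scenario = "gmp", vc = vcg)
  expect_identical(g1$breeding_values, g2$breeding_values)
  ## gm is undefined for GBLUP
  expect_error(predict_scenario(dat$plots, dat$G, model = "gblup",
                                masked_plots = vp_plots, scenario = "gm"),
               "MGBLUP")
  ## masking everything is rejected
  expect_error(predict_scenario(dat$plots, dat$G, dat$M_raw,
                                model = "mgblup",
                                masked_plots = dat$plots$plot_id,
                                scenario = "g", vc = vc),
               "all phenotypes")
})

test_that("informative validation features raise accuracy (gm vs g)", {
  ## strong metabolome-mediated signal
  cfg <- tiny_cfg(n_lines = 40, n_features = 60,
                  lines_per_trial = c(15, 20),
                  true_vc_phenotype = c(alpha = 1 / 60, g1 = 0.02,
                                        l1 = 0.05, ig1 = 0.05, il1 = 0.05,
                                        t1 = 0.05, e1 = 0.2),
                  true_vc_features = c(g2 = 0.5, l2 = 0.1, ig2 = 0.1,
                                       il2 = 0.1, t2 = 0.1, e2 = 0.2),
                  seed = 131)
  dat <- simulate_dataset(cfg)
  yr <- dat$plots$year == "Y2"
  vp_plots <- dat$plots$plot_id[yr]
  vp_lines <- unique(dat$plots$line_id[yr])
  pg <- predict_scenario(dat$plots, dat$G, dat$M_raw, model = "mgblup",
                         masked_plots = vp_plots, scenario = "g")
  pgm <- predict_scenario(dat$plots, dat$G, dat$M_raw, model = "mgblup",
                          masked_plots = vp_plots, scenario = "gm")
  a_true <- dat$truth$breeding_values[vp_lines]
  expect_gt(cor(pgm$breeding_values[vp_lines], a_true),
            cor(pg$breeding_values[vp_lines], a_true))
})
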