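#' Fit the baseline genomic model (GBLUP)
#'
#' Fits y = Xb + Z g + Z l + Z_ig i_g + Z_il i_l + Z_t t + e with g and i_g
#' correlated through the genomic relationship matrix, by REML followed by
#' BLUP. Per-line genomic predictions are returned for every line in `G`,
#' including lines without phenotyped plots (predicted through their genomic
#' covariance with observed lines).
#'
#' @param plots plot table; rows with a missing trait value are excluded
#'   from the fit.
#' @param G genomic relationship matrix.
#' @param trait response column name.
#' @param vc optional named variances (`g`, `l`, `ig`, `il`, `t`,
#'   `residual`); when supplied, REML is skipped.
#' @param control REML control list.
#' @return Object of class `gblup_fit` with elements `vc`, `loglik`,
#'   `converged`, `solution`, `breeding_values` (named over all lines of G),
#'   `G_bar` and design bookkeeping.
#' @export
fit_gblup <- function(plots, G, trait = "y", vc = NULL,
                      control = reml_control()) {
  des <- build_design(plots, trait, G)
  if (is.null(vc)) {
    est <- reml_fit(des$y, des$X, des$terms, control = control)
  } else {
    need <- c(names(des$terms), "residual")
    if (!all(need %in% names(vc)))
      stop("fit_gblup: vc must name ", paste(need, collapse = ", "),
           call. = FALSE)
    est <- list(vc = vc[need], loglik = NA_real_, converged = NA,
                iterations = 0L)
  }
  sol <- blup_solve(des$y, des$X, des$terms, est$vc)
  structure(list(trait = trait, vc = est$vc, loglik = est$loglik,
                 converged = est$converged, iterations = est$iterations,
                 solution = sol, terms = des$terms, X = des$X, y = des$y,
                 plot_ids = des$plot_ids, plots = des$plots,
                 breeding_values = sol$random$g,
                 G_bar = mean(diag(G))),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit (", length(x$y), " plots, trait '", x$trait, "')\n",
      sep = "")
  cat("  variance components:\n")
  print(round(x$vc, 6))
  if (!is.na(x$converged))
    cat(sprintf("  REML %s in %d iterations (loglik %.4f)\n",
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                x$iterations, x$loglik))
  invisible(x)
}

#' Fit the two-step metabolomic-genomic model (MGBLUP)
#'
#' Step 1 extends the genomic model with a per-plot metabolomic effect
#' u ~ N(0, Q s2_u), Q = MM'/q over standardized feature intensities, and
#' predicts u for every plot with features (phenotyped or not). Step 2
#' treats the predicted u-hat as the response of a second genomic model with
#' the same term structure, yielding the metabolome-mediated genetic effect
#' per line. Predicted breeding values are the sum of the direct (step 1)
#' and metabolome-mediated (step 2) genomic predictions.
#'
#' @param plots plot table; rows with missing trait are excluded from the
#'   step-1 response but may still carry features.
#' @param G genomic relationship matrix.
#' @param M standardized plot x feature matrix covering every plot intended
#'   to contribute metabolomic information (rownames = plot ids). Use
#'   [standardize_features()] first.
#' @param trait response column name.
#' @param vc optional list with named variance vectors `step1` (including
#'   `u`) and `step2`; when supplied, REML is skipped.
#' @param control REML control list.
#' @return Object of class `mgblup_fit` with `step1` and `step2` fit
#'   components, `breeding_values` (g1 + g2 per line), `u_hat` (per plot),
#'   `G_bar` and `Q_bar`.
#' @export
fit_mgblup <- function(plots, G, M, trait = "y", vc = NULL,
                       control = reml_control()) {
  if (is.null(rownames(M)))
    stop("fit_mgblup: M must have plot ids as rownames", call. = FALSE)
  feature_plots <- plots[plots$plot_id %in% rownames(M), , drop = FALSE]
  if (nrow(feature_plots) == 0L)
    stop("fit_mgblup: no plot of the design has feature data", call. = FALSE)
  Q <- compute_Q(M)

  ## step 1: phenotypes on plots that have both y and features
  des1 <- build_design(plots[plots$plot_id %in% rownames(Q), , drop = FALSE],
                       trait, G, Q = Q)
  if (is.null(vc)) {
    est1 <- reml_fit(des1$y, des1$X, des1$terms, control = control)
  } else {
    need <- c(names(des1$terms), "residual")
    if (!all(need %in% names(vc$step1)))
      stop("fit_mgblup: vc$step1 must name ", paste(need, collapse = ", "),
           call. = FALSE)
    est1 <- list(vc = vc$step1[need], loglik = NA_real_, converged = NA,
                 iterations = 0L)
  }
  sol1 <- blup_solve(des1$y, des1$X, des1$terms, est1$vc)
  u_hat <- sol1$random$u # over all plots in Q, masked ones included

  ## step 2: u-hat as response, same six-term genomic structure
  plots2 <- feature_plots
  plots2$.uhat <- u_hat[plots2$plot_id]
  des2 <- build_design(plots2, ".uhat", G)
  if (is.null(vc)) {
    est2 <- reml_fit(des2$y, des2$X, des2$terms, control = control)
  } else {
    need <- c(names(des2$terms), "residual")
    if (!all(need %in% names(vc$step2)))
      stop("fit_mgblup: vc$step2 must name ", paste(need, collapse = ", "),
           call. = FALSE)
    est2 <- list(vc = vc$step2[need], loglik = NA_real_, converged = NA,
                 iterations = 0L)
  }
  sol2 <- blup_solve(des2$y, des2$X, des2$terms, est2$vc)

  a_hat <- sol1$random$g + sol2$random$g
  structure(list(trait = trait,
                 step1 = list(vc = est1$vc, loglik = est1$loglik,
                              converged = est1$converged,
                              iterations = est1$iterations, solution = sol1,
                              terms = des1$terms, X = des1$X, y = des1$y,
                              plot_ids = des1$plot_ids),
                 step2 = list(vc = est2$vc, loglik = est2$loglik,
                              converged = est2$converged,
                              iterations = est2$iterations, solution = sol2,
                              terms = des2$terms, X = des2$X, y = des2$y,
                              plot_ids = des2$plot_ids),
                 u_hat = u_hat,
                 breeding_values = a_hat,
                 G_bar = mean(diag(G)),
                 Q_bar = attr(Q, "mean_diag")),
            class = "mgblup_fit")
}

#' @export
print.mgblup_fit <- function(x, ...) {
  cat("MGBLUP fit (trait '", x$trait, "')\n", sep = "")
  cat("  step 1 (phenotype) variance components:\n")
  print(round(x$step1$vc, 6))
  cat("  step 2 (metabolomic effects) variance components:\n")
  print(round(x$step2$vc, 6))
  invisible(x)
}

#' Predicted breeding values under a validation data scenario
#'
#' Refits a model class with the phenotypes (and, depending on the scenario,
#' the metabolomic features) of a validation set masked, and returns
#' predicted breeding values for every line.
#'
#' Scenarios: `"g"` masks both phenotypes and features of the validation
#' plots (prediction through the genomic relationship only); `"gm"` masks
#' phenotypes but keeps the validation plots' features (their metabolomic
#' effects are predicted through Q in step 1 and carried into step 2;
#' MGBLUP only); `"gp"`/`"gmp"` mask nothing (whole data). Feature
#' standardization is computed within the scenario on the plots whose
#' features are available.
#'
#' @param plots plot table.
#' @param G genomic relationship matrix.
#' @param M_raw raw (unstandardized) plot x feature matrix; required for
#'   `model = "mgblup"`.
#' @param trait response column name.
#' @param model `"gblup"` or `"mgblup"`.
#' @param masked_plots character vector of plot ids forming the validation
#'   set (may be empty for whole-data scenarios).
#' @param scenario one of `"g"`, `"gp"`, `"gm"`, `"gmp"`.
#' @param vc optional fixed variance components (see [fit_gblup()] /
#'   [fit_mgblup()]), e.g. full-data estimates reused across folds.
#' @param control REML control list.
#' @return list with `fit`, `breeding_values`, `scenario`, `masked_plots`.
#' @export
predict_scenario <- function(plots, G, M_raw = NULL, trait = "y",
                             model = c("gblup", "mgblup"),
                             masked_plots = character(0),
                             scenario = c("g", "gp", "gm", "gmp"),
                             vc = NULL, control = reml_control()) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  if (model == "gblup" && scenario == "gm")
    stop("predict_scenario: scenario 'gm' requires the MGBLUP model",
         call. = FALSE)
  mask <- plots$plot_id %in% masked_plots
  pheno_masked <- scenario %in% c("g", "gm")
  if (pheno_masked && all(mask | is.na(plots[[trait]])))
    stop("predict_scenario: masking removes all phenotypes", call. = FALSE)
  work <- plots
  if (pheno_masked) work[[trait]][mask] <- NA_real_

  if (model == "gblup") {
    fit <- fit_gblup(work, G, trait, vc = vc, control = control)
  } else {
    if (is.null(M_raw))
      stop("predict_scenario: M_raw required for MGBLUP", call. = FALSE)
    feat_rows <- rownames(M_raw)
    if (scenario == "g") # features of validation plots are unavailable too
      feat_rows <- setdiff(feat_rows, plots$plot_id[mask])
    M <- standardize_features(M_raw[feat_rows, , drop = FALSE])
    fit <- fit_mgblup(work, G, M, trait, vc = vc, control = control)
  }
  list(fit = fit, breeding_values = fit$breeding_values,
       scenario = scenario, masked_plots = masked_plots)
}
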