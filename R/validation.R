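#' Cross-validation folds
#'
#' Builds leave-one-year-out (LOYO) or leave-one-line-out (LOLO) folds. The
#' masked plot sets partition the plots: each plot is masked in exactly one
#' fold of a scheme.
#'
#' @param plots plot table.
#' @param scheme `"LOYO"` or `"LOLO"`.
#' @return list of folds, each a list with `scheme`, `fold_id`,
#'   `masked_plots`.
#' @export
make_folds <- function(plots, scheme = c("LOYO", "LOLO")) {
  scheme <- match.arg(scheme)
  unit <- if (scheme == "LOYO") plots$year else plots$line_id
  ids <- sort(unique(unit))
  if (scheme == "LOYO" && length(ids) < 2L)
    stop("make_folds: LOYO needs at least two years", call. = FALSE)
  if (scheme == "LOLO" && length(ids) < 2L)
    stop("make_folds: LOLO needs at least two lines", call. = FALSE)
  lapply(ids, function(id) {
    list(scheme = scheme, fold_id = id,
         masked_plots = plots$plot_id[unit == id])
  })
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests H0: rho12 = rho13 for correlations sharing variable 1, using the
#' Williams t statistic with n - 3 degrees of freedom.
#'
#' @param r12,r13 the two correlations being compared.
#' @param r23 correlation between variables 2 and 3.
#' @param n number of observations.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  if (n < 4L) stop("hotelling_williams: need n >= 4", call. = FALSE)
  if (any(abs(c(r12, r13, r23)) > 1))
    stop("hotelling_williams: correlations must lie in [-1, 1]",
         call. = FALSE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12)
    stop("hotelling_williams: correlation matrix not positive semidefinite",
         call. = FALSE)
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  tstat <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  p <- 2 * pt(-abs(tstat), df = n - 3)
  list(t = tstat, df = n - 3, p = p)
}

#' Cross-validated predictive correlation and dispersion
#'
#' For each fold the model is refitted with the validation plots' phenotypes
#' (and features) masked (scenario `"g"`), breeding values of the masked
#' lines are predicted, and predictions are pooled over all validation plots
#' before computing a single predictive correlation with corrected
#' phenotypes and the regression slope of corrected phenotypes on predicted
#' breeding values.
#'
#' @param plots plot table.
#' @param G genomic relationship matrix.
#' @param M_raw raw feature matrix (required for `model = "mgblup"`).
#' @param trait response column name.
#' @param model `"gblup"` or `"mgblup"`.
#' @param scheme `"LOYO"` or `"LOLO"`.
#' @param vc `NULL` to re-estimate variance components within every fold,
#'   `"full"` to reuse the full-data estimates in all folds (recommended for
#'   LOLO), or explicit values as in [predict_scenario()].
#' @param corrected optional named vector of corrected phenotypes; computed
#'   from a full-data GBLUP fit when missing.
#' @param control REML control list.
#' @return list with `cor`, `reg`, `n`, per-plot table `detail`, the scheme
#'   and the variance-component policy used.
#' @export
run_cv <- function(plots, G, M_raw = NULL, trait = "y",
                   model = c("gblup", "mgblup"),
                   scheme = c("LOYO", "LOLO"), vc = NULL, corrected = NULL,
                   control = reml_control()) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  folds <- make_folds(plots, scheme)
  full_fit <- NULL
  if (is.null(corrected) || (is.character(vc) && identical(vc, "full"))) {
    full_fit <- fit_gblup(plots, G, trait, control = control)
  }
  if (is.null(corrected)) corrected <- correct_phenotypes(full_fit)
  vc_policy <- if (is.null(vc)) "per-fold REML" else "fixed"
  fold_vc <- vc
  if (is.character(vc) && identical(vc, "full")) {
    vc_policy <- "full-data estimates reused"
    if (model == "gblup") {
      fold_vc <- full_fit$vc
    } else {
      M_all <- standardize_features(M_raw)
      full_m <- fit_mgblup(plots, G, M_all, trait, control = control)
      fold_vc <- list(step1 = full_m$step1$vc, step2 = full_m$step2$vc)
    }
  }
  detail <- list()
  for (f in folds) {
    vp <- plots[plots$plot_id %in% f$masked_plots & !is.na(plots[[trait]]), ]
    if (nrow(vp) == 0L) {
      warning("run_cv: fold ", f$fold_id, " has no validation phenotypes; ",
              "skipped")
      next
    }
    pred <- predict_scenario(plots, G, M_raw, trait, model,
                             masked_plots = f$masked_plots, scenario = "g",
                             vc = fold_vc, control = control)
    detail[[f$fold_id]] <- data.frame(
      fold = f$fold_id, plot_id = vp$plot_id, line_id = vp$line_id,
      corrected = unname(corrected[vp$plot_id]),
      predicted = unname(pred$breeding_values[vp$line_id]),
      stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, detail)
  if (is.null(pooled) || nrow(pooled) < 3L)
    stop("run_cv: fewer than 3 pooled validation observations",
         call. = FALSE)
  list(cor = cor(pooled$corrected, pooled$predicted),
       reg = unname(coef(lm(corrected ~ predicted, data = pooled))[2]),
       n = nrow(pooled), detail = pooled, scheme = scheme, model = model,
       vc_policy = vc_policy)
}

#' LR-method ratios of accuracies and dispersion
#'
#' For each fold and each ordered (partial, whole) scenario pair, predicted
#' breeding values of the validation lines are computed under both
#' scenarios; validation lines are pooled over folds, and per pair the
#' correlation between partial and whole predictions (estimating the ratio
#' of population accuracies) and the slope of the regression of whole on
#' partial predictions (estimating dispersion bias; expectation 1) are
#' reported.
#'
#' @inheritParams run_cv
#' @param pairs list of length-2 character vectors, e.g.
#'   `list(c("g", "gp"))` for GBLUP or
#'   `list(c("g", "gm"), c("gm", "gmp"), c("g", "gmp"))` for MGBLUP.
#' @return list with one element per pair: `ratio`, `slope`, `n_lines`,
#'   `detail`.
#' @export
run_lr <- function(plots, G, M_raw = NULL, trait = "y",
                   model = c("gblup", "mgblup"),
                   scheme = c("LOYO", "LOLO"), pairs = NULL,
                   vc = NULL, control = reml_control()) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  if (is.null(pairs))
    pairs <- if (model == "gblup") list(c("g", "gp")) else
      list(c("g", "gm"), c("gm", "gmp"), c("g", "gmp"))
  folds <- make_folds(plots, scheme)
  fold_vc <- vc
  if (is.character(vc) && identical(vc, "full")) {
    if (model == "gblup") {
      fold_vc <- fit_gblup(plots, G, trait, control = control)$vc
    } else {
      full_m <- fit_mgblup(plots, G, standardize_features(M_raw), trait,
                           control = control)
      fold_vc <- list(step1 = full_m$step1$vc, step2 = full_m$step2$vc)
    }
  }
  scen_needed <- unique(unlist(pairs))
  bad <- setdiff(scen_needed, c("g", "gp", "gm", "gmp"))
  if (length(bad))
    stop("run_lr: unknown scenarios ", paste(bad, collapse = ", "),
         call. = FALSE)
  ## whole-data scenarios do not depend on the fold: compute once
  whole_cache <- list()
  for (sc in intersect(scen_needed, c("gp", "gmp"))) {
    whole_cache[[sc]] <- predict_scenario(plots, G, M_raw, trait, model,
                                          masked_plots = character(0),
                                          scenario = sc, vc = fold_vc,
                                          control = control)$breeding_values
  }
  per_fold <- list()
  for (f in folds) {
    vp_lines <- unique(plots$line_id[plots$plot_id %in% f$masked_plots])
    preds <- list()
    for (sc in setdiff(scen_needed, names(whole_cache))) {
      preds[[sc]] <- predict_scenario(plots, G, M_raw, trait, model,
                                      masked_plots = f$masked_plots,
                                      scenario = sc, vc = fold_vc,
                                      control = control)$breeding_values
    }
    for (sc in names(whole_cache)) preds[[sc]] <- whole_cache[[sc]]
    df <- data.frame(fold = f$fold_id, line_id = vp_lines,
                     stringsAsFactors = FALSE)
    for (sc in names(preds)) df[[sc]] <- unname(preds[[sc]][vp_lines])
    per_fold[[f$fold_id]] <- df
  }
  pooled <- do.call(rbind, per_fold)
  out <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "/")
    ap <- pooled[[pr[1]]]; aw <- pooled[[pr[2]]]
    if (identical(pr[1], pr[2])) {
      warning("run_lr: identical scenarios in pair ", key)
      out[[key]] <- list(ratio = 1, slope = 1, n_lines = length(ap))
      next
    }
    out[[key]] <- list(ratio = cor(ap, aw),
                       slope = unname(coef(lm(aw ~ ap))[2]),
                       n_lines = length(ap),
                       detail = pooled[, c("fold", "line_id", pr)])
  }
  out
}

#' Projected accuracy gains from LR accuracy ratios
#'
#' The accuracy of genomic-only prediction is the predictive correlation
#' divided by the square root of the heritability of corrected phenotypes;
#' the gain from adding data is (1 - ratio of accuracies) times that
#' accuracy.
#'
#' @param cor_g predictive correlation of the genomic-only scenario.
#' @param h2_corrected heritability of corrected phenotypes, in (0, 1].
#' @param ratios named numeric of LR accuracy ratios (partial/whole), e.g.
#'   `c(gm = 0.84, gmp = 0.73)`.
#' @return list with `acc_g` and, per ratio, the projected accuracy after
#'   adding the corresponding data. Ratios above 1 are clipped (projection
#'   equals `acc_g`) with a warning.
#' @export
accuracy_projection <- function(cor_g, h2_corrected, ratios) {
  if (h2_corrected <= 0 || h2_corrected > 1)
    stop("accuracy_projection: h2_corrected must be in (0, 1]",
         call. = FALSE)
  acc_g <- cor_g / sqrt(h2_corrected)
  proj <- vapply(ratios, function(r) {
    if (r > 1) {
      warning("accuracy_projection: ratio above 1 clipped")
      r <- 1
    }
    acc_g + (1 - r) * acc_g
  }, numeric(1))
  list(acc_g = acc_g, projected = proj)
}

#' Heritability of corrected phenotypes
#'
#' Genomic heritability after removing the trial fixed effects and batch
#' effects from the phenotypes: the batch variance is excluded from the
#' denominator.
#'
#' @inheritParams gblup_heritability
#' @return G_bar * s2_g / (s2_P - s2_t).
#' @export
corrected_heritability <- function(vc, G_bar) {
  tot <- total_phenotypic_variance(vc, G_bar) - vc[["t"]]
  G_bar * vc[["g"]] / tot
}
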