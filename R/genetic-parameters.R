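#' Total phenotypic variance at plot level
#'
#' Weighted sum of variance components: genomically structured terms (`g`,
#' `ig`) are weighted by the average diagonal of G, the metabolomic term
#' (`u`, if present) by the average diagonal of Q, and identity-structured
#' terms (including the residual) by 1.
#'
#' @param vc named variances (`u` optional, `g`, `l`, `ig`, `il`, `t`,
#'   `residual`).
#' @param G_bar average diagonal of the genomic relationship matrix.
#' @param Q_bar average diagonal of the metabolomic similarity matrix;
#'   required when `vc` contains `u`.
#' @return Total phenotypic variance (trait units squared).
#' @export
total_phenotypic_variance <- function(vc, G_bar, Q_bar = NULL) {
  need <- c("g", "l", "ig", "il", "t", "residual")
  if (!all(need %in% names(vc)))
    stop("total_phenotypic_variance: vc must name ",
         paste(need, collapse = ", "), call. = FALSE)
  tot <- G_bar * vc[["g"]] + vc[["l"]] + G_bar * vc[["ig"]] + vc[["il"]] +
    vc[["t"]] + vc[["residual"]]
  if ("u" %in% names(vc)) {
    if (is.null(Q_bar))
      stop("total_phenotypic_variance: Q_bar required when vc contains 'u'",
           call. = FALSE)
    tot <- tot + Q_bar * vc[["u"]]
  }
  unname(tot)
}

#' Weighted relative variance components
#'
#' Proportion of the total phenotypic variance attributed to each term, with
#' the same diagonal-average weighting as [total_phenotypic_variance()].
#'
#' @inheritParams total_phenotypic_variance
#' @return Named numeric summing to 1.
#' @export
relative_variance_components <- function(vc, G_bar, Q_bar = NULL) {
  tot <- total_phenotypic_variance(vc, G_bar, Q_bar)
  w <- vapply(names(vc), function(nm) {
    switch(nm, g = , ig = G_bar, u = Q_bar, 1)
  }, numeric(1))
  rvc <- w * vc / tot
  rvc
}

#' Genomic heritability of the baseline model
#'
#' @inheritParams total_phenotypic_variance
#' @return h2 = G_bar * s2_g / s2_P.
#' @export
gblup_heritability <- function(vc, G_bar) {
  G_bar * vc[["g"]] / total_phenotypic_variance(vc, G_bar)
}

#' Combine the heritability decomposition
#'
#' The genomic heritability of the metabolomic-genomic model is the
#' metabolome-mediated part plus the direct part:
#' h2 = c2_m * h2_m + h2_d.
#'
#' @param c2_m metabolomic variance ratio.
#' @param h2_m heritability of the (weighted) metabolomic intensities.
#' @param h2_d direct heritability.
#' @return Combined genomic heritability.
#' @export
combine_heritability <- function(c2_m, h2_m, h2_d) {
  c2_m * h2_m + h2_d
}

#' Heritability decomposition from a two-step fit
#'
#' Computes, from the step-1 and step-2 variance components, the total
#' phenotypic variance, the direct heritability h2_d, the metabolomic
#' variance ratio c2_m, the heritability of the metabolomic intensities
#' h2_m, and the combined genomic heritability h2 = c2_m * h2_m + h2_d,
#' together with the relative variance components of step 1.
#'
#' @param step1_vc named variances of the phenotype model (`u`, `g`, `l`,
#'   `ig`, `il`, `t`, `residual`).
#' @param step2_vc named variances of the metabolomic-effect model (`g`,
#'   `l`, `ig`, `il`, `t`, `residual`).
#' @param G_bar,Q_bar average diagonals of G and Q.
#' @return Object of class `heritability_report` (list with `sigma2_P`,
#'   `h2_d`, `c2_m`, `h2_m`, `h2`, `rvc`).
#' @export
heritability_decomposition <- function(step1_vc, step2_vc, G_bar, Q_bar) {
  if (!"u" %in% names(step1_vc))
    stop("heritability_decomposition: step1_vc must contain 'u'",
         call. = FALSE)
  s2P1 <- total_phenotypic_variance(step1_vc, G_bar, Q_bar)
  if (s2P1 <= 0)
    stop("heritability_decomposition: zero total phenotypic variance",
         call. = FALSE)
  h2_d <- G_bar * step1_vc[["g"]] / s2P1
  c2_m <- Q_bar * step1_vc[["u"]] / s2P1
  denom2 <- G_bar * step2_vc[["g"]] + step2_vc[["l"]] +
    G_bar * step2_vc[["ig"]] + step2_vc[["il"]] + step2_vc[["t"]] +
    step2_vc[["residual"]]
  h2_m <- if (denom2 > 0) G_bar * step2_vc[["g"]] / denom2 else 0
  structure(list(sigma2_P = s2P1,
                 h2_d = unname(h2_d),
                 c2_m = unname(c2_m),
                 h2_m = unname(h2_m),
                 h2 = combine_heritability(unname(c2_m), unname(h2_m),
                                           unname(h2_d)),
                 rvc = relative_variance_components(step1_vc, G_bar, Q_bar)),
            class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, digits = 2, ...) {
  cat("Heritability decomposition (plot level)\n")
  cat(sprintf("  total phenotypic variance: %.4g\n", x$sigma2_P))
  cat(sprintf("  c2_m = %.*f  h2_m = %.*f  h2_d = %.*f  ->  h2 = %.*f\n",
              digits, x$c2_m, digits, x$h2_m, digits, x$h2_d, digits, x$h2))
  invisible(x)
}

#' Coefficient of phenotypic variation
#'
#' CV% = 100 * sd / mean, with the sample (n-1) standard deviation when a
#' variance is supplied directly from summary tables.
#'
#' @param mean trait mean.
#' @param variance trait variance (sample convention).
#' @return CV in percent; `NaN` with a warning when the mean is zero.
#' @export
cv_percent <- function(mean, variance) {
  if (any(mean == 0)) warning("cv_percent: zero mean, CV undefined")
  100 * sqrt(variance) / mean
}

#' Descriptive statistics for trait phenotypes
#'
#' @param plots plot table.
#' @param traits character vector of trait column names.
#' @return data.frame with one row per trait: `n`, `mean`, `variance`,
#'   `min`, `max`, `cv_pct` (CV% = 100 sd/mean, sample sd).
#' @export
descriptive_stats <- function(plots, traits = "y") {
  rows <- lapply(traits, function(tr) {
    v <- plots[[tr]]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      stop("descriptive_stats: need >= 2 records for trait '", tr, "'",
           call. = FALSE)
    m <- mean(v); s2 <- var(v)
    cv <- if (m == 0) {
      warning("descriptive_stats: zero mean for '", tr, "', CV undefined")
      NaN
    } else if (s2 == 0) 0 else cv_percent(m, s2)
    data.frame(trait = tr, n = length(v), mean = m, variance = s2,
               min = min(v), max = max(v), cv_pct = cv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent decrease between two variance estimates
#'
#' Convenience for reporting how much a variance shrinks between two models
#' (e.g. the genomic variance when the direct part is separated from the
#' metabolome-mediated part).
#'
#' @param from reference value.
#' @param to comparison value.
#' @return 100 * (from - to) / from.
#' @export
percent_decrease <- function(from, to) {
  if (any(from == 0)) stop("percent_decrease: zero reference", call. = FALSE)
  100 * (from - to) / from
}
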