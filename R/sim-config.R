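#' Configuration for the synthetic trial generator
#'
#' Bundles every parameter of the generative joint model for phenotypes and
#' metabolomic features, together with the trial-design layout. The defaults
#' describe a scaled-down multi-environment barley-style trial series: lines
#' tested in randomised complete blocks of 20-45 lines with three replicates,
#' trials nested within location x year environments, two control lines in
#' every trial, and samples processed in batches.
#'
#' @param n_lines number of breeding lines.
#' @param n_markers number of SNP markers.
#' @param n_features number of metabolomic features (columns of M).
#' @param years character vector of year labels.
#' @param locations character vector of location labels.
#' @param lines_per_trial integer vector of length 2, the inclusive range of
#'   non-control lines per trial.
#' @param replicates_per_line replicates of each line within its trial.
#' @param n_control_lines number of control lines added to every trial.
#' @param plots_per_batch target number of plots per processing batch;
#'   batches are contiguous blocks of plots within a trial.
#' @param allele_freq_range length-2 numeric in (0,1), the range from which
#'   per-marker allele frequencies are drawn.
#' @param second_appearance_prop proportion of non-control lines that are
#'   tested in a second environment (the study-scale data have roughly 1.4
#'   trial appearances per line).
#' @param line_assignment `"spread"` deals lines across environments at
#'   random; `"cohort"` assigns contiguous blocks of lines to years, mimicking
#'   breeding cycles where each year contributes a new, more closely related
#'   set of lines.
#' @param cohort_fst differentiation between year cohorts when
#'   `line_assignment = "cohort"`; per-cohort allele frequencies are drawn
#'   from a Beta distribution with this Wright-style F_ST.
#' @param family_size when > 1, lines are generated in full-sib families of
#'   this size (two simulated parents per family, Mendelian transmission per
#'   marker), nested within year cohorts under `line_assignment = "cohort"`.
#'   Default 1: unrelated lines.
#' @param true_vc_phenotype named numeric of generative variance components
#'   for the phenotype equation: `alpha` (variance of each feature regression
#'   effect), `g1` (direct genomic), `l1` (line), `ig1` (genotype x
#'   environment), `il1` (line x environment), `t1` (batch), `e1` (residual).
#' @param true_vc_features named numeric of the common per-feature variance
#'   components: `g2`, `l2`, `ig2`, `il2`, `t2`, `e2`. All features share one
#'   variance set (the common-heritability assumption of the two-step model);
#'   see `feature_vc_multipliers`.
#' @param feature_vc_multipliers optional numeric vector of length
#'   `n_features`; multiplies every variance of feature j, to probe
#'   robustness against heterogeneous feature heritabilities.
#' @param trial_effect_sd standard deviation of location x year x trial fixed
#'   effects injected into phenotypes and features (default 0: fixed effects
#'   are zero).
#' @param seed integer seed; fully determines all generated data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_lines = 120,
                       n_markers = 400,
                       n_features = 100,
                       years = c("2014", "2015", "2016"),
                       locations = c("L1", "L2"),
                       lines_per_trial = c(20L, 45L),
                       replicates_per_line = 3L,
                       n_control_lines = 2L,
                       plots_per_batch = 30L,
                       allele_freq_range = c(0.1, 0.9),
                       second_appearance_prop = 0.45,
                       line_assignment = c("spread", "cohort"),
                       cohort_fst = 0.15,
                       family_size = 1L,
                       true_vc_phenotype = c(alpha = 0.5 / n_features,
                                             g1 = 0.05, l1 = 0.05,
                                             ig1 = 0.05, il1 = 0.05,
                                             t1 = 0.05, e1 = 0.25),
                       true_vc_features = c(g2 = 0.2, l2 = 0.1, ig2 = 0.1,
                                            il2 = 0.1, t2 = 0.1, e2 = 0.4),
                       feature_vc_multipliers = NULL,
                       trial_effect_sd = 0,
                       seed = 1L) {
  line_assignment <- match.arg(line_assignment)
  cfg <- list(n_lines = as.integer(n_lines),
              n_markers = as.integer(n_markers),
              n_features = as.integer(n_features),
              years = as.character(years),
              locations = as.character(locations),
              lines_per_trial = as.integer(lines_per_trial),
              replicates_per_line = as.integer(replicates_per_line),
              n_control_lines = as.integer(n_control_lines),
              plots_per_batch = as.integer(plots_per_batch),
              allele_freq_range = as.numeric(allele_freq_range),
              second_appearance_prop = second_appearance_prop,
              line_assignment = line_assignment,
              cohort_fst = cohort_fst,
              family_size = as.integer(family_size),
              true_vc_phenotype = true_vc_phenotype,
              true_vc_features = true_vc_features,
              feature_vc_multipliers = feature_vc_multipliers,
              trial_effect_sd = trial_effect_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_lines < 1L)
    stop("sim_config: n_lines must be >= 1", call. = FALSE)
  if (length(cfg$years) < 1L || length(cfg$locations) < 1L)
    stop("sim_config: at least one year and one location required",
         call. = FALSE)
  if (length(cfg$lines_per_trial) != 2L ||
      cfg$lines_per_trial[1] > cfg$lines_per_trial[2] ||
      cfg$lines_per_trial[1] < 1L)
    stop("sim_config: lines_per_trial must be an increasing positive range",
         call. = FALSE)
  if (cfg$lines_per_trial[1] + cfg$n_control_lines > cfg$n_lines)
    stop("sim_config: lines_per_trial exceeds the number of available lines",
         call. = FALSE)
  if (any(cfg$allele_freq_range <= 0) || any(cfg$allele_freq_range >= 1))
    stop("sim_config: allele_freq_range must lie strictly within (0, 1)",
         call. = FALSE)
  need_p <- c("alpha", "g1", "l1", "ig1", "il1", "t1", "e1")
  need_f <- c("g2", "l2", "ig2", "il2", "t2", "e2")
  if (!all(need_p %in% names(cfg$true_vc_phenotype)))
    stop("sim_config: true_vc_phenotype must name ",
         paste(need_p, collapse = ", "), call. = FALSE)
  if (!all(need_f %in% names(cfg$true_vc_features)))
    stop("sim_config: true_vc_features must name ",
         paste(need_f, collapse = ", "), call. = FALSE)
  if (any(cfg$true_vc_phenotype < 0) || any(cfg$true_vc_features < 0))
    stop("sim_config: variances must be non-negative", call. = FALSE)
  if (!is.null(cfg$feature_vc_multipliers) &&
      length(cfg$feature_vc_multipliers) != cfg$n_features)
    stop("sim_config: feature_vc_multipliers must have length n_features",
         call. = FALSE)
  if (cfg$replicates_per_line < 1L || cfg$plots_per_batch < 1L)
    stop("sim_config: replicates_per_line and plots_per_batch must be >= 1",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trial configuration\n")
  cat(sprintf("  %d lines, %d markers, %d features\n",
              x$n_lines, x$n_markers, x$n_features))
  cat(sprintf("  %d years x %d locations (%d environments), trials of %d-%d lines, %d reps\n",
              length(x$years), length(x$locations),
              length(x$years) * length(x$locations),
              x$lines_per_trial[1], x$lines_per_trial[2],
              x$replicates_per_line))
  cat(sprintf("  line assignment: %s; seed %d\n", x$line_assignment, x$seed))
  invisible(x)
}
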