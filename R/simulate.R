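## Synthetic data generator for the joint phenotype-metabolome model.
## Every function derives its RNG state from config$seed (plus a fixed
## per-stage offset), so a config fully determines all outputs regardless
## of which subset of generators is called.

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% .Machine$integer.max)
}

line_ids <- function(cfg) sprintf("L%04d", seq_len(cfg$n_lines))

## Cohort membership used when line_assignment = "cohort": non-control lines
## are split into length(years) contiguous blocks; controls sit in cohort 1.
line_cohorts <- function(cfg) {
  ids <- line_ids(cfg)
  coh <- rep(1L, cfg$n_lines)
  pool <- setdiff(seq_len(cfg$n_lines), seq_len(cfg$n_control_lines))
  ny <- length(cfg$years)
  if (length(pool) > 0L) {
    blocks <- cut(seq_along(pool), breaks = ny, labels = FALSE)
    coh[pool] <- blocks
  }
  names(coh) <- ids
  coh
}

#' Simulate a multi-environment trial design
#'
#' Lays out trials nested within location x year environments. Each trial is
#' a randomised complete block of `lines_per_trial` lines plus the control
#' lines, with `replicates_per_line` complete blocks. Samples are assigned to
#' processing batches as contiguous blocks of plots within each trial.
#'
#' @param config a [sim_config()] object.
#' @return A plot table (`data.frame`) with columns `plot_id`, `line_id`,
#'   `year`, `location`, `trial`, `env`, `batch`, `is_control` and an empty
#'   phenotype column `y`.
#' @export
simulate_design <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(stage_seed(cfg$seed, 1L))
  ids <- line_ids(cfg)
  controls <- ids[seq_len(cfg$n_control_lines)]
  pool <- setdiff(ids, controls)
  envs <- expand.grid(location = cfg$locations, year = cfg$years,
                      stringsAsFactors = FALSE)
  envs$env <- paste(envs$location, envs$year, sep = ":")
  ne <- nrow(envs)

  ## allocate non-control lines to environments
  env_lines <- vector("list", ne)
  if (length(pool) > 0L) {
    if (cfg$line_assignment == "spread") {
      shuffled <- sample(pool)
      alloc <- rep(seq_len(ne), length.out = length(shuffled))
      for (e in seq_len(ne)) env_lines[[e]] <- shuffled[alloc == e]
      n2 <- floor(cfg$second_appearance_prop * length(pool))
      if (n2 > 0L) {
        twice <- sample(shuffled, n2)
        for (ln in twice) {
          e1 <- which(vapply(env_lines, function(v) ln %in% v, logical(1)))[1]
          e2 <- if (ne > 1L) (e1 %% ne) + 1L else e1
          if (e2 != e1) env_lines[[e2]] <- c(env_lines[[e2]], ln)
        }
      }
    } else { # cohort: line blocks follow years (new lines each breeding cycle)
      coh <- line_cohorts(cfg)
      for (e in seq_len(ne)) {
        yr_idx <- match(envs$year[e], cfg$years)
        members <- pool[coh[pool] == yr_idx]
        year_envs <- which(envs$year == envs$year[e])
        slot <- match(e, year_envs)
        alloc <- rep(seq_along(year_envs), length.out = length(members))
        env_lines[[e]] <- members[alloc == slot]
        n2 <- floor(cfg$second_appearance_prop * length(members))
        if (n2 > 0L && length(year_envs) > 1L) {
          other <- setdiff(year_envs, e)[1]
          env_lines[[other]] <- unique(c(env_lines[[other]],
                                         sample(members, n2)))
        }
      }
    }
  }
  ## guarantee every line appears at least once
  placed <- unique(unlist(env_lines))
  missing_lines <- setdiff(pool, placed)
  for (ln in missing_lines) {
    e <- sample.int(ne, 1L)
    env_lines[[e]] <- c(env_lines[[e]], ln)
  }

  rows <- list()
  trial_counter <- 0L
  for (e in seq_len(ne)) {
    lns <- env_lines[[e]]
    if (length(lns) == 0L && cfg$n_control_lines == 0L) next
    ## partition the environment's lines into trials
    trials <- list()
    remaining <- lns
    lo <- cfg$lines_per_trial[1]; hi <- cfg$lines_per_trial[2]
    while (length(remaining) > 0L) {
      if (length(remaining) <= hi + lo - 1L) {
        trials[[length(trials) + 1L]] <- remaining
        remaining <- character(0)
      } else {
        size <- sample(seq(lo, hi), 1L)
        trials[[length(trials) + 1L]] <- remaining[seq_len(size)]
        remaining <- remaining[-seq_len(size)]
      }
    }
    if (length(trials) == 0L) trials <- list(character(0))
    for (tr in trials) {
      trial_counter <- trial_counter + 1L
      trial_id <- sprintf("%s_T%03d", envs$env[e], trial_counter)
      entry <- c(controls, tr)
      ## randomised complete block: each replicate is a shuffled block
      block_rows <- unlist(lapply(seq_len(cfg$replicates_per_line),
                                  function(b) sample(entry)))
      batch_idx <- (seq_along(block_rows) - 1L) %/% cfg$plots_per_batch + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = block_rows,
        year = envs$year[e],
        location = envs$location[e],
        trial = trial_id,
        env = envs$env[e],
        batch = sprintf("%s_B%02d", trial_id, batch_idx),
        is_control = block_rows %in% controls,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(plot_id = sprintf("P%05d", seq_len(nrow(out))), out)
  out$y <- NA_real_
  rownames(out) <- NULL
  out
}

#' Simulate line genotypes
#'
#' Draws per-marker allele frequencies uniformly from
#' `config$allele_freq_range` and samples 0/1/2 genotype codes binomially.
#' Under `line_assignment = "cohort"`, each year cohort gets its own
#' frequencies drawn around the base frequency with differentiation
#' `cohort_fst`, so that lines are more related within than across years.
#'
#' @param config a [sim_config()] object.
#' @return Integer matrix of 0/1/2 codes, lines in rows (named), markers in
#'   columns.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  cfg <- config
  if (cfg$n_markers < 1L)
    stop("simulate_genotypes: n_markers must be >= 1 (G is undefined otherwise)",
         call. = FALSE)
  set.seed(stage_seed(cfg$seed, 2L))
  p <- runif(cfg$n_markers, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
  codes <- matrix(0L, cfg$n_lines, cfg$n_markers,
                  dimnames = list(line_ids(cfg),
                                  sprintf("M%04d", seq_len(cfg$n_markers))))
  groups <- if (cfg$line_assignment == "spread") {
    rep(1L, cfg$n_lines)
  } else {
    line_cohorts(cfg)
  }
  fst <- min(max(cfg$cohort_fst, 1e-6), 0.999)
  for (cc in unique(groups)) {
    sel <- which(groups == cc)
    pc <- if (cfg$line_assignment == "spread") p else {
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      pmin(pmax(stats::rbeta(cfg$n_markers, a, b), 0.01), 0.99)
    }
    if (cfg$family_size > 1L) {
      ## full-sib families: two parents per family, Mendelian transmission
      fam <- (seq_along(sel) - 1L) %/% cfg$family_size
      for (f in unique(fam)) {
        members <- sel[fam == f]
        par1 <- rbinom(cfg$n_markers, 2L, pc)
        par2 <- rbinom(cfg$n_markers, 2L, pc)
        for (i in members)
          codes[i, ] <- rbinom(cfg$n_markers, 1L, par1 / 2) +
            rbinom(cfg$n_markers, 1L, par2 / 2)
      }
    } else {
      for (j in seq_len(cfg$n_markers))
        codes[sel, j] <- rbinom(length(sel), 2L, pc[j])
    }
  }
  codes
}

## Symmetric square root via eigendecomposition; tolerates PSD matrices.
psd_factor <- function(K, name = "matrix") {
  eg <- eigen(K, symmetric = TRUE)
  tol <- -1e-8 * max(abs(eg$values), 1)
  if (min(eg$values) < tol)
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(eg$values)), call. = FALSE)
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

## index helpers shared by the generators
design_indices <- function(design, G) {
  lid <- match(design$line_id, rownames(G))
  if (anyNA(lid))
    stop("design contains lines absent from G: ",
         paste(unique(design$line_id[is.na(lid)]), collapse = ", "),
         call. = FALSE)
  env <- factor(design$env)
  le <- interaction(design$line_id, design$env, drop = FALSE)
  batch <- factor(design$batch)
  trial <- factor(design$trial)
  list(lid = lid, env = env, batch = batch, trial = trial)
}

#' Simulate metabolomic feature intensities
#'
#' Generates each feature column independently from the line / genotype x
#' environment / line x environment / batch / residual decomposition, with
#' genetic effects correlated between lines through `G`. All features share
#' the common variance set of the configuration (optionally modulated by
#' `feature_vc_multipliers`); fixed effects default to zero.
#'
#' @param design plot table from [simulate_design()].
#' @param G genomic relationship matrix covering every line in `design`.
#' @param config a [sim_config()] object.
#' @return list with `M`: plot x feature matrix of raw intensities, and
#'   `truth`: list carrying the per-line genetic effects `g_j2`
#'   (lines x features, raw-feature scale).
#' @export
simulate_features <- function(design, G, config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(stage_seed(cfg$seed, 3L))
  idx <- design_indices(design, G)
  L <- psd_factor(G, "G")
  nl <- nrow(G); np <- nrow(design); k <- cfg$n_features
  vc <- cfg$true_vc_features
  envs <- levels(idx$env); ne <- length(envs)

  g2 <- L %*% matrix(rnorm(nl * k), nl, k) * sqrt(vc["g2"])
  l2 <- matrix(rnorm(nl * k), nl, k) * sqrt(vc["l2"])
  ig2 <- matrix(0, nl * ne, k)
  if (vc["ig2"] > 0)
    for (e in seq_len(ne))
      ig2[(e - 1L) * nl + seq_len(nl), ] <-
        L %*% matrix(rnorm(nl * k), nl, k) * sqrt(vc["ig2"])
  il2 <- matrix(rnorm(nl * ne * k), nl * ne, k) * sqrt(vc["il2"])
  nbatch <- nlevels(idx$batch)
  t2 <- matrix(rnorm(nbatch * k), nbatch, k) * sqrt(vc["t2"])
  e2 <- matrix(rnorm(np * k), np, k) * sqrt(vc["e2"])

  le_idx <- (as.integer(idx$env) - 1L) * nl + idx$lid
  M <- g2[idx$lid, , drop = FALSE] + l2[idx$lid, , drop = FALSE] +
    ig2[le_idx, , drop = FALSE] + il2[le_idx, , drop = FALSE] +
    t2[as.integer(idx$batch), , drop = FALSE] + e2
  if (cfg$trial_effect_sd > 0) {
    beta <- matrix(rnorm(nlevels(idx$trial) * k, 0, cfg$trial_effect_sd),
                   nlevels(idx$trial), k)
    M <- M + beta[as.integer(idx$trial), , drop = FALSE]
  }
  if (!is.null(cfg$feature_vc_multipliers)) {
    sc <- sqrt(cfg$feature_vc_multipliers)
    M <- sweep(M, 2L, sc, "*")
    g2 <- sweep(g2, 2L, sc, "*")
  }
  dimnames(M) <- list(design$plot_id, sprintf("F%05d", seq_len(k)))
  colnames(g2) <- colnames(M); rownames(g2) <- rownames(G)
  list(M = M, truth = list(g_j2 = g2))
}

#' Simulate phenotypes from the joint model
#'
#' Standardizes the raw feature matrix (population-sd convention, the same
#' convention as [compute_Q()]), draws feature regression effects
#' alpha ~ N(0, I sigma2_alpha), and assembles the phenotype from the
#' metabolomic term M alpha plus direct genetic, line, genotype x
#' environment, line x environment, batch and residual effects.
#'
#' The completed truth stores `g_j2` on the standardized-feature scale (the
#' scale on which alpha acts), so the breeding-value identity
#' a = sum_j g_j2[, j] alpha_j + g1 holds exactly.
#'
#' @param design plot table from [simulate_design()].
#' @param M_raw raw feature matrix from [simulate_features()].
#' @param truth partial truth list from [simulate_features()].
#' @param G genomic relationship matrix covering every line in `design`.
#' @param config a [sim_config()] object.
#' @return list with `plots` (design with `y` filled) and `truth` (list with
#'   `alpha`, `g1`, `g_j2`, `breeding_values`, `u`).
#' @export
simulate_phenotypes <- function(design, M_raw, truth, G, config) {
  validate_sim_config(config)
  cfg <- config
  if (nrow(M_raw) != nrow(design))
    stop("simulate_phenotypes: M_raw rows must match design plots",
         call. = FALSE)
  set.seed(stage_seed(cfg$seed, 4L))
  idx <- design_indices(design, G)
  L <- psd_factor(G, "G")
  nl <- nrow(G); np <- nrow(design)
  vc <- cfg$true_vc_phenotype
  envs <- levels(idx$env); ne <- length(envs)

  std <- .standardize_matrix(M_raw)
  Ms <- std$M
  k <- ncol(Ms)
  alpha <- rnorm(k, 0, sqrt(vc["alpha"]))
  names(alpha) <- colnames(Ms)
  u <- drop(Ms %*% alpha)

  g1 <- drop(L %*% rnorm(nl)) * sqrt(vc["g1"])
  l1 <- rnorm(nl) * sqrt(vc["l1"])
  ig1 <- numeric(nl * ne)
  if (vc["ig1"] > 0)
    for (e in seq_len(ne))
      ig1[(e - 1L) * nl + seq_len(nl)] <- drop(L %*% rnorm(nl)) * sqrt(vc["ig1"])
  il1 <- rnorm(nl * ne) * sqrt(vc["il1"])
  t1 <- rnorm(nlevels(idx$batch)) * sqrt(vc["t1"])
  e1 <- rnorm(np) * sqrt(vc["e1"])

  le_idx <- (as.integer(idx$env) - 1L) * nl + idx$lid
  y <- u + g1[idx$lid] + l1[idx$lid] + ig1[le_idx] + il1[le_idx] +
    t1[as.integer(idx$batch)] + e1
  if (cfg$trial_effect_sd > 0) {
    b <- rnorm(nlevels(idx$trial), 0, cfg$trial_effect_sd)
    y <- y + b[as.integer(idx$trial)]
  }
  names(g1) <- rownames(G)
  g_j2_std <- sweep(truth$g_j2[, std$kept, drop = FALSE], 2L, std$scale, "/")
  a <- drop(g_j2_std %*% alpha) + g1
  plots <- design
  plots$y <- y
  list(plots = plots,
       truth = list(alpha = alpha, g1 = g1, g_j2 = g_j2_std,
                    breeding_values = a, u = u))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genotypes, marker QC, G matrix, trial design,
#' feature matrix and phenotypes in one call.
#'
#' @param config a [sim_config()] object.
#' @return list with `config`, `plots`, `geno`, `G`, `M_raw` and `truth`.
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genotypes(config)
  geno_qc <- qc_markers(geno)
  G <- compute_G(geno_qc)
  design <- simulate_design(config)
  feats <- simulate_features(design, G, config)
  phen <- simulate_phenotypes(design, feats$M, feats$truth, G, config)
  list(config = config, plots = phen$plots, geno = geno_qc, G = G,
       M_raw = feats$M, truth = phen$truth)
}
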