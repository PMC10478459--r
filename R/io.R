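## Readers and writers for the tab-delimited interchange formats, plus the
## end-to-end pipeline driver. All writers produce files their paired
## readers parse back to equal objects.

required_plot_cols <- c("plot_id", "line_id", "year", "location", "trial",
                        "batch")

#' Read a plot-level phenotype table
#'
#' Tab-delimited, one header row. Requires columns `plot_id`, `line_id`,
#' `year`, `location`, `trial`, `batch`; an `env` column is derived from
#' location and year when absent; every remaining numeric column is treated
#' as a trait. Missing trait cells (`NA`) are allowed and excluded from that
#' trait's response at fitting time.
#'
#' @param path file path.
#' @return data.frame plot table.
#' @export
read_phenotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(plot_id = "character",
                                 line_id = "character"))
  miss <- setdiff(required_plot_cols, names(d))
  if (length(miss))
    stop("read_phenotypes: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$plot_id))
    stop("read_phenotypes: duplicate plot ids", call. = FALSE)
  for (col in c("year", "location", "trial", "batch"))
    d[[col]] <- as.character(d[[col]])
  if (!"env" %in% names(d))
    d$env <- paste(d$location, d$year, sep = ":")
  trait_cols <- setdiff(names(d), c(required_plot_cols, "env", "is_control"))
  for (tr in trait_cols) {
    v <- suppressWarnings(as.numeric(d[[tr]]))
    bad <- which(!is.na(d[[tr]]) & d[[tr]] != "" & is.na(v))
    if (length(bad))
      stop("read_phenotypes: non-numeric value in trait '", tr,
           "' at row ", bad[1], call. = FALSE)
    d[[tr]] <- v
  }
  d
}

#' Write a plot table
#' @param plots plot table.
#' @param path file path.
#' @export
write_phenotypes <- function(plots, path) {
  write.table(plots, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genotype matrix
#'
#' Tab-delimited, lines in rows; first column holds line ids, remaining
#' columns marker codes in \{0, 1, 2, NA\}.
#'
#' @param path file path.
#' @return numeric matrix with line rownames.
#' @export
read_genotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) == 0L)
    stop("read_genotypes: no marker columns", call. = FALSE)
  bad <- which(!(m %in% c(0, 1, 2)) & !is.na(m))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("read_genotypes: invalid code '%s' at line %s, marker %s",
                 m[bad[1]], ids[rc[1]], colnames(m)[rc[2]]), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write a genotype matrix
#' @param geno line x marker matrix with rownames.
#' @param path file path.
#' @export
write_genotypes <- function(geno, path) {
  d <- data.frame(line_id = rownames(geno), geno, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a feature intensity matrix
#'
#' Tab-delimited, plots in rows; first column holds plot ids.
#'
#' @param path file path.
#' @return numeric matrix with plot rownames.
#' @export
read_features <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  if (ncol(m) == 0L)
    stop("read_features: feature matrix has zero columns", call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature intensity matrix
#' @param M plot x feature matrix with rownames.
#' @param path file path.
#' @export
write_features <- function(M, path) {
  d <- data.frame(plot_id = rownames(M), M, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a square relationship matrix
#'
#' Delimited square table with ids as both header and first column.
#' @param K square matrix with dimnames.
#' @param path file path.
#' @export
write_matrix <- function(K, path) {
  d <- data.frame(id = rownames(K), K, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(m))
  m
}

#' Read / write a run configuration
#'
#' YAML with either an `input` section (paths to phenotype, genotype and
#' feature tables) or a `simulation` section ([sim_config()] fields), plus
#' optional `model`, `scheme`, `qc` and `reml` settings.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim)
    stop("run config: exactly one of 'input' or 'simulation' must be given",
         call. = FALSE)
  cfg
}

#' @rdname read_run_config
#' @param config named list to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
}

#' Run the full analysis pipeline
#'
#' Simulates or loads the data, runs marker QC and builds G, standardizes
#' features and builds Q, fits GBLUP and MGBLUP, computes the heritability
#' decomposition, and (optionally) runs cross-validation and the LR method.
#' Tidy result tables and a JSON manifest (dimensions, seed, convergence
#' flags, variance-component policy) are written to `out_dir`.
#'
#' @param config a run-config list (see [read_run_config()]) or a path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mgblup")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   warnings = character(0))
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    manifest$log <<- c(manifest$log, msg)
  }

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    scfg <- do.call(sim_config, sim_args)
    manifest$seed <- scfg$seed
    dat <- simulate_dataset(scfg)
    plots <- dat$plots; geno <- dat$geno; M_raw <- dat$M_raw; G <- dat$G
    trait <- "y"
    note("simulated %d plots, %d lines, %d markers, %d features",
         nrow(plots), nrow(G), ncol(geno), ncol(M_raw))
  } else {
    plots <- read_phenotypes(config$input$phenotypes)
    geno_raw <- read_genotypes(config$input$genotypes)
    M_raw <- read_features(config$input$features)
    qc <- config$qc %||% list()
    geno <- qc_markers(geno_raw, maf_min = qc$maf_min %||% 0.05,
                       max_missing = qc$max_missing %||% 0.20)
    G <- compute_G(geno)
    trait <- config$trait %||%
      setdiff(names(plots), c(required_plot_cols, "env", "is_control"))[1]
    note("loaded %d plots; %d/%d markers pass QC", nrow(plots), ncol(geno),
         ncol(geno_raw))
  }
  manifest$dims <- list(plots = nrow(plots), lines = nrow(G),
                        markers = ncol(geno), features = ncol(M_raw))
  manifest$trait <- trait

  M <- standardize_features(M_raw)
  note("standardized features: %d retained, %d zero-variance dropped",
       ncol(M), attr(M, "n_dropped"))

  ctrl <- do.call(reml_control, config$reml %||% list())
  gfit <- fit_gblup(plots, G, trait, control = ctrl)
  mfit <- fit_mgblup(plots, G, M, trait, control = ctrl)
  manifest$convergence <- list(gblup = gfit$converged,
                               mgblup_step1 = mfit$step1$converged,
                               mgblup_step2 = mfit$step2$converged)

  herit <- heritability_decomposition(mfit$step1$vc, mfit$step2$vc,
                                      mfit$G_bar, mfit$Q_bar)
  vc_tab <- rbind(
    data.frame(model = "GBLUP", step = 1, term = names(gfit$vc),
               estimate = unname(gfit$vc)),
    data.frame(model = "MGBLUP", step = 1, term = names(mfit$step1$vc),
               estimate = unname(mfit$step1$vc)),
    data.frame(model = "MGBLUP", step = 2, term = names(mfit$step2$vc),
               estimate = unname(mfit$step2$vc)))
  write.table(vc_tab, file.path(out_dir, "variance_components.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  herit_tab <- data.frame(
    trait = trait,
    gblup_h2 = gblup_heritability(gfit$vc, gfit$G_bar),
    gblup_total = total_phenotypic_variance(gfit$vc, gfit$G_bar),
    mgblup_total = herit$sigma2_P, h2_d = herit$h2_d, c2_m = herit$c2_m,
    h2_m = herit$h2_m, mgblup_h2 = herit$h2)
  write.table(herit_tab, file.path(out_dir, "heritability.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bv_tab <- rbind(
    data.frame(model = "GBLUP", line_id = names(gfit$breeding_values),
               breeding_value = unname(gfit$breeding_values)),
    data.frame(model = "MGBLUP", line_id = names(mfit$breeding_values),
               breeding_value = unname(mfit$breeding_values)))
  write.table(bv_tab, file.path(out_dir, "breeding_values.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(descriptive_stats(plots, trait),
              file.path(out_dir, "descriptive_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  results <- list(gblup = gfit, mgblup = mfit, heritability = herit)

  if (isTRUE(config$cv$run)) {
    scheme <- config$cv$scheme %||% "LOYO"
    vc_pol <- config$cv$vc %||% "full"
    cv_rows <- list()
    for (mdl in c("gblup", "mgblup")) {
      res <- run_cv(plots, G, M_raw, trait, mdl, scheme, vc = vc_pol,
                    control = ctrl)
      cv_rows[[mdl]] <- data.frame(trait = trait, scheme = scheme,
                                   model = mdl, cor = res$cor, reg = res$reg,
                                   n = res$n)
      results$cv[[mdl]] <- res
    }
    write.table(do.call(rbind, cv_rows), file.path(out_dir, "cv.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(config$lr$run)) {
    scheme <- config$lr$scheme %||% "LOYO"
    vc_pol <- config$lr$vc %||% "full"
    lr_rows <- list()
    for (mdl in c("gblup", "mgblup")) {
      res <- run_lr(plots, G, M_raw, trait, mdl, scheme, vc = vc_pol,
                    control = ctrl)
      for (key in names(res))
        lr_rows[[paste(mdl, key)]] <-
          data.frame(trait = trait, scheme = scheme, model = mdl, pair = key,
                     ratio = res[[key]]$ratio, slope = res[[key]]$slope,
                     n_lines = res[[key]]$n_lines)
      results$lr[[mdl]] <- res
    }
    write.table(do.call(rbind, lr_rows), file.path(out_dir, "lr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
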