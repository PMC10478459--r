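## Dense linear mixed model engine.
##
## A model is a response y, a fixed-effect design X and an ordered list of
## random terms. Each term carries an incidence mapping from plots to levels
## and one of four covariance structures:
##   identity   u ~ N(0, I s2)         (line, line x env, batch effects)
##   K          u ~ N(0, K s2)         (genomic G or metabolomic Q kernels)
##   envblockK  u ~ N(0, diag(K,..,K) s2) over environments (G x E)
## The engine works with the n x n phenotypic covariance
## V = sum_k s2_k V_k + s2_e I, where V_k is the unit-variance contribution
## of term k, so REML cost is O(n^3) per iteration independent of the number
## of levels. Intended scale is a few thousand plots at most.

#' Construct a random model term
#'
#' @param name term label (unique within a model).
#' @param struct one of `"identity"`, `"K"`, `"envblockK"`.
#' @param map factor (or vector) of length n mapping each observation to a
#'   level. For `"K"` the levels must index rows of `K`; for `"envblockK"`
#'   `map` indexes rows of `K` and `env` gives the environment of each
#'   observation.
#' @param K level covariance matrix (required for `"K"` and `"envblockK"`).
#' @param env factor of environments (only for `"envblockK"`).
#' @return An object of class `lmm_term`.
#' @export
lmm_term <- function(name, struct = c("identity", "K", "envblockK"),
                     map, K = NULL, env = NULL) {
  struct <- match.arg(struct)
  if (struct %in% c("K", "envblockK")) {
    if (is.null(K)) stop("term '", name, "': K matrix required", call. = FALSE)
    idx <- match(as.character(map), rownames(K))
    if (anyNA(idx))
      stop("term '", name, "': levels absent from K: ",
           paste(unique(as.character(map)[is.na(idx)]), collapse = ", "),
           call. = FALSE)
  } else {
    map <- factor(map)
    idx <- as.integer(map)
  }
  if (struct == "envblockK" && is.null(env))
    stop("term '", name, "': env factor required", call. = FALSE)
  structure(list(name = name, struct = struct, map = map, idx = idx,
                 K = K, env = if (!is.null(env)) factor(env) else NULL),
            class = "lmm_term")
}

## n x n covariance contribution of a term at unit variance
term_V <- function(term) {
  n <- length(term$idx)
  if (term$struct == "identity") {
    out <- outer(term$idx, term$idx, "==") * 1
  } else if (term$struct == "K") {
    out <- term$K[term$idx, term$idx, drop = FALSE]
  } else {
    out <- term$K[term$idx, term$idx, drop = FALSE] *
      outer(as.integer(term$env), as.integer(term$env), "==")
  }
  unname(out)
}

## BLUP of the term's level effects given Py = V^{-1}(y - Xb):
## u_hat = s2 * K * Z' * Py, returned over all levels of K (structured
## terms) or the observed factor levels (identity terms).
term_blup <- function(term, s2, Py) {
  if (term$struct == "identity") {
    u <- s2 * as.vector(rowsum(Py, group = term$idx,
                               reorder = TRUE))
    names(u) <- levels(term$map)[sort(unique(term$idx))]
    full <- setNames(numeric(nlevels(term$map)), levels(term$map))
    full[names(u)] <- u
    full
  } else if (term$struct == "K") {
    agg <- rowsum(Py, group = term$idx, reorder = TRUE)
    z <- numeric(nrow(term$K))
    z[as.integer(rownames(agg))] <- agg
    setNames(drop(s2 * term$K %*% z), rownames(term$K))
  } else {
    envs <- levels(term$env)
    out <- matrix(0, nrow(term$K), length(envs),
                  dimnames = list(rownames(term$K), envs))
    for (e in seq_along(envs)) {
      sel <- which(as.integer(term$env) == e)
      if (length(sel) == 0L) next
      agg <- rowsum(Py[sel], group = term$idx[sel], reorder = TRUE)
      z <- numeric(nrow(term$K))
      z[as.integer(rownames(agg))] <- agg
      out[, e] <- s2 * drop(term$K %*% z)
    }
    out
  }
}

## expand a term's level predictions back to observations
term_expand <- function(term, u) {
  if (term$struct == "identity") {
    u[as.integer(term$map)]
  } else if (term$struct == "K") {
    u[term$idx]
  } else {
    u[cbind(term$idx, as.integer(term$env))]
  }
}

#' Assemble design matrices for the trial models
#'
#' Builds the fixed-effect design (one column per observed location x year x
#' trial cell) and the random terms of the baseline genomic model
#' \{g, l, i_g, i_l, t\} or its metabolomic extension that prepends a
#' per-plot term with covariance Q.
#'
#' @param plots plot table with columns `plot_id`, `line_id`, `year`,
#'   `location`, `trial`, `env`, `batch` and the trait.
#' @param trait name of the response column.
#' @param G genomic relationship matrix covering every line in `plots`.
#' @param Q optional plot x plot metabolomic similarity matrix; when given,
#'   the metabolomic term `u` is prepended.
#' @param keep_na keep rows with a missing response (default drops them).
#' @return list with `y`, `X`, `terms`, `plot_ids` and the subset of `plots`
#'   used.
#' @export
build_design <- function(plots, trait = "y", G, Q = NULL, keep_na = FALSE) {
  if (!trait %in% names(plots))
    stop("build_design: trait column '", trait, "' not found", call. = FALSE)
  use <- if (keep_na) rep(TRUE, nrow(plots)) else !is.na(plots[[trait]])
  d <- plots[use, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("build_design: no observations with phenotypes", call. = FALSE)
  if (!all(d$line_id %in% rownames(G))) {
    missing <- setdiff(unique(d$line_id), rownames(G))
    stop("build_design: lines absent from G: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cell <- interaction(d$location, d$year, d$trial, drop = TRUE, sep = ":")
  ## cell-means coding (one indicator column per observed cell); built by
  ## hand so single-cell designs need no contrasts
  X <- vapply(levels(cell), function(l) as.numeric(cell == l),
              numeric(nrow(d)))
  X <- matrix(X, nrow = nrow(d), dimnames = list(NULL, levels(cell)))
  env <- factor(d$env)
  terms <- list()
  if (!is.null(Q)) {
    if (!all(d$plot_id %in% rownames(Q)))
      stop("build_design: plots absent from Q: ",
           paste(setdiff(d$plot_id, rownames(Q)), collapse = ", "),
           call. = FALSE)
    terms$u <- lmm_term("u", "K", map = d$plot_id, K = Q)
  }
  terms$g <- lmm_term("g", "K", map = d$line_id, K = G)
  terms$l <- lmm_term("l", "identity", map = d$line_id)
  terms$ig <- lmm_term("ig", "envblockK", map = d$line_id, K = G, env = env)
  terms$il <- lmm_term("il", "identity",
                       map = interaction(d$line_id, env, drop = FALSE))
  terms$t <- lmm_term("t", "identity", map = d$batch)
  list(y = d[[trait]], X = X, terms = terms, plot_ids = d$plot_id, plots = d)
}

reml_control <- function(tol_par = 1e-8, tol_loglik = 1e-9, max_iter = 500L,
                         em_iter = 2L, verbose = FALSE) {
  list(tol_par = tol_par, tol_loglik = tol_loglik,
       max_iter = as.integer(max_iter), em_iter = as.integer(em_iter),
       verbose = verbose)
}

## One evaluation of the restricted likelihood at theta. Returns P, Py and
## the pieces needed for scores / AI updates.
.reml_eval <- function(theta, y, X, Vlist) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Vlist)) {
    if (theta[k] != 0) V <- V + theta[k] * Vlist[[k]]
  }
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) {
    cV <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), n)),
                   error = function(e) NULL)
    if (is.null(cV)) return(NULL)
  }
  Vinv <- chol2inv(cV)
  if (ncol(X) > 0L) {
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX))
      stop("reml: singular fixed-effect design", call. = FALSE)
    P <- Vinv - W %*% chol2inv(cX) %*% t(W)
    ldX <- 2 * sum(log(diag(cX)))
  } else {
    P <- Vinv
    ldX <- 0
  }
  P <- (P + t(P)) / 2
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(cV))) + ldX + sum(y * Py))
  list(loglik = ll, P = P, Py = Py, Vinv = Vinv)
}

#' REML estimation of variance components
#'
#' Estimates one variance per random term plus a residual variance by
#' restricted maximum likelihood, using average-information updates after a
#' few stabilising EM-type fixed-point iterations, with fallback to the
#' fixed-point update whenever an AI step is inadmissible (non-finite, below
#' the variance floor after clipping, or likelihood-decreasing). Variances
#' are floored at `1e-10 * var(y)`; a floored component re-enters estimation
#' at the next iteration.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (full column rank).
#' @param terms named list of [lmm_term()] objects.
#' @param start optional named numeric of starting values (terms then
#'   `residual`).
#' @param control list from `reml_control()`.
#' @return list with `vc` (named variances including `residual`), `loglik`,
#'   `converged`, `iterations`.
#' @export
reml_fit <- function(y, X, terms, start = NULL, control = reml_control()) {
  n <- length(y)
  if (n <= ncol(X))
    stop("reml_fit: need more observations than fixed-effect columns",
         call. = FALSE)
  Vlist <- lapply(terms, term_V)
  K <- length(Vlist)
  vy <- var(y)
  floor_vc <- 1e-10 * vy
  if (is.null(start)) {
    theta <- rep(vy / (K + 1), K + 1L)
  } else {
    theta <- c(start[names(terms)], start["residual"])
  }
  theta <- pmax(theta, floor_vc)
  cur <- .reml_eval(theta, y, X, Vlist)
  if (is.null(cur)) stop("reml_fit: initial covariance not factorizable",
                         call. = FALSE)
  converged <- FALSE
  it <- 0L
  trPV <- numeric(K + 1L)
  while (it < control$max_iter) {
    it <- it + 1L
    ## quadratic forms and traces for each component (residual last)
    q_vec <- vector("list", K + 1L)
    yPVPy <- numeric(K + 1L)
    for (k in seq_len(K)) {
      q_vec[[k]] <- drop(Vlist[[k]] %*% cur$Py)
      yPVPy[k] <- sum(cur$Py * q_vec[[k]])
      trPV[k] <- sum(cur$P * Vlist[[k]])
    }
    q_vec[[K + 1L]] <- cur$Py
    yPVPy[K + 1L] <- sum(cur$Py^2)
    trPV[K + 1L] <- sum(diag(cur$P))

    em_theta <- theta
    for (k in seq_len(K + 1L)) {
      if (trPV[k] > 0)
        em_theta[k] <- theta[k] * yPVPy[k] / trPV[k]
    }
    em_theta <- pmax(em_theta, floor_vc)

    cand <- NULL
    if (it > control$em_iter) {
      score <- -0.5 * (trPV - yPVPy)
      AI <- matrix(0, K + 1L, K + 1L)
      for (a in seq_len(K + 1L)) {
        Pqa <- drop(cur$P %*% q_vec[[a]])
        for (b in a:(K + 1L)) {
          AI[a, b] <- AI[b, a] <- 0.5 * sum(q_vec[[b]] * Pqa)
        }
      }
      ## active-set AI step: components pushed below the floor are fixed
      ## there and the AI system is re-solved for the free components
      free <- rep(TRUE, K + 1L)
      prop <- NULL
      for (pass in seq_len(K + 1L)) {
        if (!any(free)) break
        step <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                         error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) { prop <- NULL; break }
        cand_theta <- theta
        cand_theta[free] <- theta[free] + step
        cand_theta[!free] <- floor_vc
        hit <- free & (cand_theta < floor_vc)
        if (!any(hit)) { prop <- pmax(cand_theta, floor_vc); break }
        free[hit] <- FALSE
      }
      if (!is.null(prop)) {
        fac <- 1
        for (h in seq_len(5L)) {
          cand_theta <- pmax(theta + fac * (prop - theta), floor_vc)
          ev <- .reml_eval(cand_theta, y, X, Vlist)
          if (!is.null(ev) && is.finite(ev$loglik) &&
              ev$loglik >= cur$loglik - 1e-10) {
            cand <- list(theta = cand_theta, ev = ev)
            break
          }
          fac <- fac / 2
        }
      }
    }
    if (is.null(cand)) {
      ev <- .reml_eval(em_theta, y, X, Vlist)
      if (is.null(ev)) break
      cand <- list(theta = em_theta, ev = ev)
    }
    dpar <- max(abs(cand$theta - theta) / (abs(theta) + 1e-12))
    dll <- abs(cand$ev$loglik - cur$loglik)
    theta <- cand$theta
    cur <- cand$ev
    if (control$verbose)
      message(sprintf("iter %3d  loglik %.6f  max rel dpar %.2e", it,
                      cur$loglik, dpar))
    if (dpar < control$tol_par || dll < control$tol_loglik) {
      converged <- TRUE
      break
    }
  }
  vc <- setNames(theta, c(names(terms), "residual"))
  list(vc = vc, loglik = cur$loglik, converged = converged, iterations = it)
}

#' Solve the mixed model for fixed estimates and BLUPs
#'
#' Given variance components, computes generalized least squares estimates
#' of the fixed effects and BLUP predictions for every random term,
#' including levels without records (which are shrunk toward zero through
#' their covariance with observed levels). The solution satisfies the mixed
#' model equations; an internal reconstruction identity
#' y = X b + sum_k Z_k u_k + e is asserted to 1e-8 relative accuracy.
#'
#' @inheritParams reml_fit
#' @param vc named variances (terms then `residual`), e.g. from
#'   [reml_fit()].
#' @return list with `fixed` (named coefficients), `fitted_fixed` (per
#'   observation), `random` (list of per-level predictions), `residuals`,
#'   `vc`.
#' @export
blup_solve <- function(y, X, terms, vc) {
  n <- length(y)
  Vlist <- lapply(terms, term_V)
  s2e <- vc[["residual"]]
  V <- diag(s2e, n)
  for (k in seq_along(Vlist)) V <- V + vc[[names(terms)[k]]] * Vlist[[k]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) {
    warning("blup_solve: covariance singular; adding 1e-6 ridge")
    cV <- chol(V + diag(1e-6 * mean(diag(V)), n))
  }
  Vinv <- chol2inv(cV)
  if (ncol(X) > 0L) {
    W <- Vinv %*% X
    XtVX <- crossprod(X, W)
    b <- tryCatch(solve(XtVX, crossprod(W, y)),
                  error = function(e) {
                    warning("blup_solve: singular fixed-effect equations; ",
                            "using pseudo-inverse")
                    MASS_ginv(XtVX) %*% crossprod(W, y)
                  })
    b <- drop(b)
    names(b) <- colnames(X)
    fitted_fixed <- drop(X %*% b)
  } else {
    b <- numeric(0)
    fitted_fixed <- numeric(n)
  }
  Py <- drop(Vinv %*% (y - fitted_fixed))
  random <- list()
  recon <- fitted_fixed
  for (k in seq_along(terms)) {
    nm <- names(terms)[k]
    u <- term_blup(terms[[k]], vc[[nm]], Py)
    random[[nm]] <- u
    recon <- recon + term_expand(terms[[k]], u)
  }
  resid <- s2e * Py
  recon <- recon + resid
  rel_err <- max(abs(recon - y)) / max(abs(y), 1e-12)
  if (rel_err > 1e-8)
    warning(sprintf("blup_solve: reconstruction residual %.2e", rel_err))
  list(fixed = b, fitted_fixed = fitted_fixed, random = random,
       residuals = resid, vc = vc)
}

## Minimal Moore-Penrose pseudo-inverse (symmetric case), used only when the
## fixed-effect equations are singular.
MASS_ginv <- function(A, tol = 1e-10) {
  eg <- eigen(A, symmetric = TRUE)
  pos <- abs(eg$values) > tol * max(abs(eg$values))
  eg$vectors[, pos, drop = FALSE] %*%
    ((1 / eg$values[pos]) * t(eg$vectors[, pos, drop = FALSE]))
}

#' Correct phenotypes for trial fixed effects and batch effects
#'
#' Subtracts the estimated location x year x trial fixed effects and the
#' predicted batch effects of a (full-data) genomic model fit from the raw
#' phenotypes, producing the validation response used in cross-validation.
#'
#' @param fit a [fit_gblup()] object fitted with a batch term.
#' @return Named numeric of corrected phenotypes (by plot id) for the plots
#'   used in the fit.
#' @export
correct_phenotypes <- function(fit) {
  sol <- fit$solution
  if (!"t" %in% names(sol$random))
    stop("correct_phenotypes: fit has no batch term", call. = FALSE)
  t_hat <- term_expand(fit$terms$t, sol$random$t)
  corrected <- fit$y - sol$fitted_fixed - t_hat
  setNames(corrected, fit$plot_ids)
}
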