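# Independent oracles used across the suite.
#
# The BLUP oracle goes through Henderson's mixed model equations with
# explicit incidence matrices and inverted level covariances -- a different
# route from the package's phenotypic-covariance (V-inverse) solver.

# incidence matrix from a level-index vector
inc_matrix <- function(idx, nlev) {
  Z <- matrix(0, length(idx), nlev)
  Z[cbind(seq_along(idx), idx)] <- 1
  Z
}

# Dense MME solver. random = list of list(Z, K, s2); K = NULL means identity.
# Returns list(b, u = list of per-level predictions).
mme_oracle <- function(y, X, random, s2e, ridge = 1e-10) {
  Zs <- lapply(random, `[[`, "Z")
  Dinvs <- lapply(random, function(r) {
    q <- ncol(r$Z)
    K <- if (is.null(r$K)) diag(q) else r$K
    solve(K + diag(ridge * mean(diag(K)), q)) * (s2e / r$s2)
  })
  Zall <- do.call(cbind, Zs)
  p <- ncol(X); qtot <- ncol(Zall)
  C <- matrix(0, p + qtot, p + qtot)
  if (p > 0) {
    C[seq_len(p), seq_len(p)] <- crossprod(X)
    C[seq_len(p), p + seq_len(qtot)] <- crossprod(X, Zall)
    C[p + seq_len(qtot), seq_len(p)] <- t(C[seq_len(p), p + seq_len(qtot)])
  }
  C[p + seq_len(qtot), p + seq_len(qtot)] <- crossprod(Zall)
  off <- p
  for (k in seq_along(random)) {
    qk <- ncol(Zs[[k]])
    sel <- off + seq_len(qk)
    C[sel, sel] <- C[sel, sel] + Dinvs[[k]]
    off <- off + qk
  }
  rhs <- c(if (p > 0) crossprod(X, y) else numeric(0), crossprod(Zall, y))
  sol <- solve(C, rhs)
  b <- if (p > 0) sol[seq_len(p)] else numeric(0)
  u <- list()
  off <- p
  for (k in seq_along(random)) {
    qk <- ncol(Zs[[k]])
    u[[k]] <- sol[off + seq_len(qk)]
    off <- off + qk
  }
  list(b = b, u = u)
}

# Build the explicit incidence/covariance ingredients of the six-term trial
# model from a plot table, for use with mme_oracle().
trial_model_parts <- function(plots, G, s2, trait = "y") {
  d <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  lid <- match(d$line_id, rownames(G))
  env <- factor(d$env)
  nl <- nrow(G); ne <- nlevels(env)
  cell <- interaction(d$location, d$year, d$trial, drop = TRUE)
  X <- inc_matrix(as.integer(cell), nlevels(cell))
  Zg <- inc_matrix(lid, nl)
  Zle <- inc_matrix((as.integer(env) - 1L) * nl + lid, nl * ne)
  batch <- factor(d$batch)
  Zt <- inc_matrix(as.integer(batch), nlevels(batch))
  Kblock <- kronecker(diag(ne), G)
  list(y = d[[trait]], X = X,
       random = list(g = list(Z = Zg, K = G, s2 = s2[["g"]]),
                     l = list(Z = Zg, K = NULL, s2 = s2[["l"]]),
                     ig = list(Z = Zle, K = Kblock, s2 = s2[["ig"]]),
                     il = list(Z = Zle, K = NULL, s2 = s2[["il"]]),
                     t = list(Z = Zt, K = NULL, s2 = s2[["t"]])),
       lid = lid, env = env)
}

# Joint-model oracle for the two-step equivalence: explicit per-feature
# regression effects alpha in the phenotype model, plus per-feature genomic
# BLUP of the metabolomic genetic effects.
joint_model_bv <- function(plots, G, M, s2_alpha, vc1, vc2, trait = "y") {
  parts <- trial_model_parts(plots, G, vc1, trait)
  Mobs <- M[plots$plot_id[!is.na(plots[[trait]])], , drop = FALSE]
  q <- ncol(M)
  step1 <- mme_oracle(parts$y, parts$X,
                      c(list(alpha = list(Z = Mobs, K = NULL,
                                          s2 = s2_alpha)),
                        parts$random),
                      s2e = vc1[["residual"]])
  alpha_hat <- step1$u[[1]]
  g1_hat <- step1$u[[2]]
  ## per-feature BLUP of the genetic effect on each (standardized) feature;
  ## all features share one model matrix set, fitted on all feature plots
  fplots <- plots[plots$plot_id %in% rownames(M), , drop = FALSE]
  fplots$.m <- 0
  parts2 <- trial_model_parts(fplots, G, vc2, ".m")
  g2_hat <- matrix(0, nrow(G), q)
  Mf <- M[fplots$plot_id, , drop = FALSE]
  for (j in seq_len(q)) {
    fit_j <- mme_oracle(Mf[, j], parts2$X, parts2$random,
                        s2e = vc2[["residual"]])
    g2_hat[, j] <- fit_j$u[[1]]
  }
  drop(g2_hat %*% alpha_hat) + g1_hat
}
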