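## Joint empirical-Bayes analysis of per-cell-type effect estimates: a
## mixture of zero-centered multivariate normals over canonical and
## data-driven covariance patterns, fitted by EM on the mixture weights,
## yielding per-condition shrunken posterior effects and local false sign
## rates (lfsr).

#' Assemble multi-condition statistics
#'
#' Pivots a long association table (one row per cell type x gene x variant)
#' into association x cell-type matrices of effect estimates and standard
#' errors. Combinations absent for a cell type are marked missing (NA) and
#' dropped row-wise from likelihood computations downstream.
#'
#' @param assoc association data.frame with columns cell_type, gene,
#'   variant, beta, se (a single `term`).
#' @return an object of class `scqtl_mcstats`: `ids`, `Bhat`, `Shat`,
#'   `conditions`, and the id-to-(gene, variant) map.
#' @export
multi_condition_stats <- function(assoc) {
  need <- c("cell_type", "gene", "variant", "beta", "se")
  assert_that(all(need %in% names(assoc)), "multi_condition_stats: missing columns")
  assert_that(all(assoc$se > 0, na.rm = TRUE), "multi_condition_stats: se must be > 0")
  dt <- data.table::as.data.table(assoc[, need])
  dt[, id := paste(gene, variant, sep = ":")]
  B <- data.table::dcast(dt, id ~ cell_type, value.var = "beta")
  S <- data.table::dcast(dt, id ~ cell_type, value.var = "se")
  ids <- B$id
  Bhat <- as.matrix(B[, -1])
  Shat <- as.matrix(S[, -1])
  rownames(Bhat) <- rownames(Shat) <- ids
  map <- unique(dt[, c("id", "gene", "variant")])
  out <- list(ids = ids, Bhat = Bhat, Shat = Shat,
              conditions = colnames(Bhat),
              map = as.data.frame(map[match(ids, map$id), ]))
  class(out) <- "scqtl_mcstats"
  out
}

#' Build multi-condition statistics from matrices
#'
#' @param Bhat,Shat association x condition matrices of estimates and
#'   standard errors (same shape; NA/non-finite `Shat` marks a missing
#'   condition).
#' @param ids optional association ids (`gene:variant` strings).
#' @return a `scqtl_mcstats` object.
#' @export
mcstats_from_matrices <- function(Bhat, Shat, ids = NULL) {
  assert_that(all(dim(Bhat) == dim(Shat)), "mcstats_from_matrices: shape mismatch")
  assert_that(all(Shat > 0 | !is.finite(Shat), na.rm = TRUE),
              "mcstats_from_matrices: se must be > 0 where observed")
  if (is.null(ids)) ids <- sprintf("g%05d:v%05d", seq_len(nrow(Bhat)), seq_len(nrow(Bhat)))
  if (is.null(colnames(Bhat))) colnames(Bhat) <- paste0("cond", seq_len(ncol(Bhat)))
  colnames(Shat) <- colnames(Bhat)
  rownames(Bhat) <- rownames(Shat) <- ids
  gv <- do.call(rbind, strsplit(ids, ":", fixed = TRUE))
  out <- list(ids = ids, Bhat = Bhat, Shat = Shat, conditions = colnames(Bhat),
              map = data.frame(id = ids, gene = gv[, 1],
                               variant = gv[, min(2, ncol(gv))],
                               stringsAsFactors = FALSE))
  class(out) <- "scqtl_mcstats"
  out
}

#' Simulate effects and estimates from a known shrinkage prior
#'
#' Draws true effect vectors from a mixture of zero-centered multivariate
#' normals (include a zero matrix for a null component) and observes them
#' with heteroskedastic normal noise - the generative model the joint
#' shrinkage analysis assumes. Used for calibration checks.
#'
#' @param n number of associations.
#' @param Ulist list of R x R covariance components.
#' @param pi_u mixture weights over `Ulist`.
#' @param omega scalar or vector of scale(s) applied to the drawn
#'   component covariance.
#' @param se_range range of standard errors (uniform per entry).
#' @param seed integer seed.
#' @return list with `B` (true effects), `Bhat`, `Shat`, `component`
#'   (index per row), and `stats` (a ready `scqtl_mcstats`).
#' @export
simulate_mash_data <- function(n, Ulist, pi_u = NULL, omega = 1,
                               se_range = c(0.05, 0.3), seed = 1) {
  R <- nrow(Ulist[[1]])
  if (is.null(pi_u)) pi_u <- rep(1 / length(Ulist), length(Ulist))
  withr::with_seed(seed, {
    comp <- sample(length(Ulist), n, replace = TRUE, prob = pi_u)
    om <- if (length(omega) == 1) rep(omega, n) else sample(omega, n, replace = TRUE)
    B <- matrix(0, n, R)
    for (k in seq_along(Ulist)) {
      idx <- which(comp == k)
      if (length(idx) == 0) next
      ev <- eigen(Ulist[[k]], symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), R, R)
      Z <- matrix(rnorm(length(idx) * R), length(idx), R)
      B[idx, ] <- sqrt(om[idx]) * Z %*% t(L)
    }
    S <- matrix(runif(n * R, se_range[1], se_range[2]), n, R)
    Bhat <- B + S * matrix(rnorm(n * R), n, R)
  })
  list(B = B, Bhat = Bhat, Shat = S, component = comp,
       stats = mcstats_from_matrices(Bhat, S))
}

#' Univariate adaptive shrinkage
#'
#' Fits, by EM, a unimodal-at-zero symmetric mixture of a point mass and
#' zero-mean normals on a geometric standard-deviation grid spanning
#' `[min(s)/10, 2 max(|b|)]`, and returns the local false sign rate of each
#' observation. The mixture weights carry a null-biased Dirichlet prior
#' (`null_weight` pseudo-counts on the point mass) so that, on null data,
#' mass concentrates on the point mass rather than diffusing into
#' indistinguishable near-zero-variance components - the convention of
#' adaptive-shrinkage FDR estimation.
#'
#' @param b effect estimates.
#' @param s standard errors (> 0).
#' @param gridmult geometric spacing of the sd grid.
#' @param maxiter,tol EM controls.
#' @param sd_grid optional explicit grid of component standard deviations
#'   (0 = the point mass); overrides the automatic grid.
#' @param fix_pi optional fixed mixture weights over `sd_grid` (no EM);
#'   used for closed-form cross-checks.
#' @param null_weight Dirichlet pseudo-count on the point-mass component
#'   (1 = unpenalized maximum likelihood).
#' @return list with `lfsr`, mixture weights `pi` (named by component sd),
#'   grid `sd`, posterior means `post_mean`, and the (penalized) objective
#'   trace `loglik`.
#' @export
ash_univariate <- function(b, s, gridmult = sqrt(2), maxiter = 500, tol = 1e-7,
                           sd_grid = NULL, fix_pi = NULL, null_weight = 10) {
  assert_that(all(s > 0), "ash_univariate: s must be > 0")
  n <- length(b)
  if (is.null(sd_grid)) {
    lo <- min(s) / 10
    hi <- max(2 * max(abs(b)), lo * gridmult)
    sds <- lo * gridmult^(0:ceiling(log(hi / lo) / log(gridmult)))
    sds <- c(0, sds)
  } else sds <- sd_grid
  K <- length(sds)
  ## likelihood matrix: b_i ~ N(0, sd_k^2 + s_i^2)
  Lik <- vapply(sds, function(sk) dnorm(b, 0, sqrt(sk^2 + s^2)), numeric(n))
  Lik <- matrix(pmax(Lik, 1e-300), n, K)
  pi_k <- if (is.null(fix_pi)) rep(1 / K, K) else fix_pi / sum(fix_pi)
  lambda <- c(null_weight, rep(1, K - 1))      # Dirichlet pseudo-counts
  ll_trace <- numeric(0)
  for (it in seq_len(if (is.null(fix_pi)) maxiter else 1L)) {
    rs <- as.numeric(Lik %*% pi_k)
    ll <- sum(log(rs)) + sum((lambda - 1) * log(pmax(pi_k, 1e-300)))
    if (length(ll_trace) && ll < tail(ll_trace, 1) - 1e-8)
      stop("ash_univariate: EM objective decreased (internal error)")
    ll_trace <- c(ll_trace, ll)
    if (length(ll_trace) > 1 &&
        abs(ll - ll_trace[length(ll_trace) - 1]) < tol * (1 + abs(ll))) break
    if (is.null(fix_pi)) {
      pi_k <- pi_k * as.numeric(crossprod(Lik, 1 / rs)) + lambda - 1
      pi_k <- pi_k / sum(pi_k)
    }
  }
  ## posterior summaries
  resp <- Lik * matrix(pi_k, n, K, byrow = TRUE)
  resp <- resp / rowSums(resp)
  sd2 <- matrix(sds^2, n, K, byrow = TRUE)
  s2 <- matrix(s^2, n, K)
  shrink <- sd2 / (sd2 + s2)
  mu <- shrink * b          # posterior mean per component
  vv <- shrink * s2          # posterior variance per component
  pneg <- resp * ifelse(sd2 == 0, 0, pnorm(0, mu, sqrt(pmax(vv, 1e-300))))
  ppos <- resp * ifelse(sd2 == 0, 0, 1 - pnorm(0, mu, sqrt(pmax(vv, 1e-300))))
  pzero <- resp[, 1]
  lfsr <- pmin(rowSums(pneg) + pzero, rowSums(ppos) + pzero)
  list(lfsr = lfsr, pi = setNames(pi_k, paste0("sd=", signif(sds, 4))),
       sd = sds, post_mean = rowSums(resp * mu), loglik = ll_trace)
}

#' Select strong associations
#'
#' Runs univariate adaptive shrinkage per condition and keeps rows whose
#' minimum lfsr across conditions is strictly below the threshold.
#'
#' @param stats a `scqtl_mcstats`.
#' @param lfsr_threshold strong-set threshold.
#' @param lfsr optional precomputed association x condition lfsr matrix
#'   (skips the per-condition shrinkage fits).
#' @return integer vector of selected row indices (attribute `lfsr` holds
#'   the per-row minimum lfsr).
#' @export
select_strong <- function(stats, lfsr_threshold = 0.1, lfsr = NULL) {
  stopifnot(inherits(stats, "scqtl_mcstats"))
  n <- nrow(stats$Bhat)
  min_lfsr <- rep(Inf, n)
  if (!is.null(lfsr)) {
    assert_that(nrow(lfsr) == n, "select_strong: lfsr shape mismatch")
    min_lfsr <- apply(lfsr, 1, min, na.rm = TRUE)
  } else for (j in seq_len(ncol(stats$Bhat))) {
    ok <- is.finite(stats$Shat[, j])
    if (sum(ok) < 3) next
    a <- ash_univariate(stats$Bhat[ok, j], stats$Shat[ok, j])
    min_lfsr[ok] <- pmin(min_lfsr[ok], a$lfsr)
  }
  idx <- which(min_lfsr < lfsr_threshold)
  if (length(idx) == 0)
    stop("select_strong: empty strong set; consider relaxing lfsr_threshold")
  attr(idx, "lfsr") <- min_lfsr[idx]
  idx
}

#' Canonical covariance components
#'
#' Identity (independent equal-variance effects), one singleton per
#' condition (condition-specific effects), and the all-ones matrix
#' (identical effects in every condition).
#'
#' @param R number of conditions (>= 2).
#' @param conditions optional condition names.
#' @return named list of R x R matrices (length `R + 2`).
#' @export
canonical_covariances <- function(R, conditions = NULL) {
  assert_that(R >= 2, "canonical_covariances: need R >= 2")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(R))
  out <- list(identity = diag(R))
  for (r in seq_len(R)) {
    U <- matrix(0, R, R)
    U[r, r] <- 1
    out[[paste0("singleton_", conditions[r])]] <- U
  }
  out$equal_effects <- matrix(1, R, R)
  out
}

#' Data-driven covariance components
#'
#' Principal-component patterns of the strong-set z-scores (per-PC rank-1
#' matrices plus the rank-`n_pcs` reconstruction), refined by an extreme
#' deconvolution EM that re-estimates the covariances accounting for the
#' per-row measurement error.
#'
#' @param Bhat,Shat strong-set effect estimates and standard errors
#'   (rows complete; NAs not supported here).
#' @param n_pcs number of leading PCs (capped at the number of conditions,
#'   with a warning).
#' @param ed_iters extreme-deconvolution EM iterations.
#' @return named list of PSD covariance components.
#' @export
datadriven_covariances <- function(Bhat, Shat, n_pcs = 5, ed_iters = 50) {
  R <- ncol(Bhat)
  n <- nrow(Bhat)
  if (n < 2 * R) warning("datadriven_covariances: strong set is small (< 2R rows)")
  if (n_pcs > R) {
    warning("datadriven_covariances: n_pcs capped at the number of conditions")
    n_pcs <- R
  }
  Z <- Bhat / Shat
  sv <- svd(Z, nu = 0, nv = n_pcs)
  init <- list()
  for (j in seq_len(n_pcs))
    init[[paste0("PC", j)]] <- tcrossprod(sv$v[, j]) * sv$d[j]^2 / n
  init[[sprintf("rank%d", n_pcs)]] <- Reduce(`+`, init[seq_len(n_pcs)])
  init <- lapply(init, make_psd)
  ed <- extreme_deconvolution(Bhat, Shat, init, iters = ed_iters)
  ed$U
}

#' Extreme deconvolution EM
#'
#' Estimates mixture covariances of true effects from noisy observations
#' `b_i ~ N(beta_i, diag(s_i^2))`, `beta_i ~ sum_k pi_k N(0, U_k)`.
#' Covariances are projected to PSD (eigenvalue clipping at 1e-8) each
#' step; the objective is checked to be non-decreasing.
#'
#' @param Bhat,Shat n x R observation and standard-error matrices.
#' @param Uinit named list of initial covariances.
#' @param iters number of EM iterations.
#' @return list with `U` (updated components), `pi`, and `objective` trace.
#' @export
extreme_deconvolution <- function(Bhat, Shat, Uinit, iters = 50) {
  n <- nrow(Bhat); R <- ncol(Bhat); K <- length(Uinit)
  U <- lapply(Uinit, make_psd)
  pi_k <- rep(1 / K, K)
  obj <- numeric(0)
  for (it in seq_len(iters)) {
    logl <- matrix(0, n, K)
    mus <- vector("list", K)
    Vs <- vector("list", K)
    for (k in seq_len(K)) {
      mus[[k]] <- matrix(0, n, R)
      Vs[[k]] <- vector("list", n)
      for (i in seq_len(n)) {
        Sig <- U[[k]] + diag(Shat[i, ]^2, R)
        ch <- chol(Sig)
        z <- forwardsolve(t(ch), Bhat[i, ])
        logl[i, k] <- -0.5 * (R * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
        W <- backsolve(ch, forwardsolve(t(ch), U[[k]]))   # Sigma^-1 U
        mus[[k]][i, ] <- as.numeric(crossprod(W, Bhat[i, ]))
        Vs[[k]][[i]] <- U[[k]] - crossprod(W, U[[k]])
      }
    }
    lw <- sweep(logl, 2, log(pmax(pi_k, 1e-300)), `+`)
    m <- apply(lw, 1, max)
    w <- exp(lw - m)
    tot <- rowSums(w)
    ll <- sum(m + log(tot))
    if (length(obj) && ll < tail(obj, 1) - 1e-6)
      stop("extreme_deconvolution: EM objective decreased (internal error)")
    obj <- c(obj, ll)
    gamma <- w / tot
    for (k in seq_len(K)) {
      gk <- gamma[, k]
      sgk <- sum(gk)
      if (sgk < 1e-10) next
      acc <- matrix(0, R, R)
      for (i in seq_len(n))
        acc <- acc + gk[i] * (tcrossprod(mus[[k]][i, ]) + Vs[[k]][[i]])
      U[[k]] <- make_psd(acc / sgk)
      if (any(!is.finite(U[[k]]))) stop("extreme_deconvolution: non-PSD component")
    }
    pi_k <- colSums(gamma) / n
  }
  list(U = U, pi = pi_k, objective = obj)
}

## sqrt(2)-spaced variance grid covering [s_min/10, 2 b_max] (as sds).
mash_auto_grid <- function(Bhat, Shat, gridmult = sqrt(2)) {
  smin <- min(Shat[is.finite(Shat)])
  bmax <- max(abs(Bhat[is.finite(Shat)]), smin)
  lo <- smin / 10
  hi <- max(2 * bmax, lo * gridmult)
  sds <- lo * gridmult^(0:ceiling(log(hi / lo) / log(gridmult)))
  sds^2
}

## scale each covariance so its largest diagonal entry is 1
normalize_cov <- function(Ulist) {
  lapply(Ulist, function(U) {
    m <- max(diag(U))
    if (m > 0) U / m else U
  })
}

#' Fit mixture weights of the multivariate shrinkage model
#'
#' Maximizes `sum_i log sum_{k,l} pi_{k,l} N(b_i; 0, omega_l U_k + S_i)`
#' (plus a null point-mass component) by EM over the weights, on a random
#' subset of associations.
#'
#' @param stats a `scqtl_mcstats`.
#' @param Ulist named list of covariance components (canonical and/or
#'   data-driven); each is rescaled to unit maximum diagonal.
#' @param grid variance scale grid; `NULL` for the automatic grid.
#' @param subset_size number of rows used for fitting (sampled with
#'   `seed`); `NULL` or >= n uses all rows.
#' @param seed seed for the fitting subset.
#' @param tol,maxiter EM convergence controls.
#' @param null_weight Dirichlet pseudo-count on the null component
#'   (null-biased prior, as in the univariate fit).
#' @return an object of class `scqtl_mash`: `Ulist`, `grid`, `pi` (null
#'   weight first), and the (penalized) objective trace `loglik`.
#' @export
fit_mash_weights <- function(stats, Ulist, grid = NULL, subset_size = 10000,
                             seed = 2023, tol = 1e-8, maxiter = 1000,
                             null_weight = 10) {
  stopifnot(inherits(stats, "scqtl_mcstats"))
  n <- nrow(stats$Bhat)
  idx <- seq_len(n)
  if (!is.null(subset_size) && subset_size < n)
    idx <- withr::with_seed(seed, sort(sample(n, subset_size)))
  if (is.null(grid)) grid <- mash_auto_grid(stats$Bhat, stats$Shat)
  Ulist <- normalize_cov(Ulist)
  Lmat <- .mash_loglik_cpp(stats$Bhat[idx, , drop = FALSE],
                           stats$Shat[idx, , drop = FALSE], Ulist, grid)
  nc <- ncol(Lmat)
  pi_k <- rep(1 / nc, nc)
  lambda <- c(null_weight, rep(1, nc - 1))
  trace <- numeric(0)
  m <- apply(Lmat, 1, max)
  W <- exp(Lmat - m)
  for (it in seq_len(maxiter)) {
    rs <- as.numeric(W %*% pi_k)
    ll <- sum(log(rs) + m) + sum((lambda - 1) * log(pmax(pi_k, 1e-300)))
    if (length(trace) && ll < tail(trace, 1) - 1e-6)
      stop("fit_mash_weights: EM objective decreased (internal error)")
    converged <- length(trace) > 0 &&
      abs(ll - tail(trace, 1)) < tol * (1 + abs(ll))
    trace <- c(trace, ll)
    if (converged) break
    pi_k <- pi_k * as.numeric(crossprod(W, 1 / rs)) + lambda - 1
    pi_k <- pi_k / sum(pi_k)
  }
  names(pi_k) <- c("null", paste(rep(names(Ulist), each = length(grid)),
                                 rep(signif(grid, 3), length(Ulist)), sep = ":"))
  out <- list(Ulist = Ulist, grid = grid, pi = pi_k, loglik = trace,
              conditions = stats$conditions, n_fit = length(idx))
  class(out) <- "scqtl_mash"
  out
}

#' Posterior effects and local false sign rates
#'
#' Applies a fitted mixture model to every association: responsibilities
#' over components, mixture-of-normals posterior per condition, and
#' `lfsr = min(P(beta <= 0), P(beta >= 0))` with null mass counted in both
#' signs.
#'
#' @param stats a `scqtl_mcstats`.
#' @param model a fitted `scqtl_mash`.
#' @return an object of class `scqtl_posterior`: matrices `post_mean`,
#'   `post_sd`, `lfsr` (association x condition) plus the id map.
#' @export
mash_posterior <- function(stats, model) {
  stopifnot(inherits(stats, "scqtl_mcstats"), inherits(model, "scqtl_mash"))
  assert_that(identical(stats$conditions, model$conditions),
              "mash_posterior: condition sets differ between stats and model")
  res <- .mash_posterior_cpp(stats$Bhat, stats$Shat, model$Ulist, model$grid,
                             unname(model$pi))
  for (nm in c("post_mean", "post_sd", "lfsr"))
    dimnames(res[[nm]]) <- dimnames(stats$Bhat)
  out <- list(post_mean = res$post_mean, post_sd = res$post_sd,
              lfsr = res$lfsr, map = stats$map, conditions = stats$conditions)
  class(out) <- "scqtl_posterior"
  out
}

#' One-call joint shrinkage analysis
#'
#' Chains [select_strong()], [canonical_covariances()],
#' [datadriven_covariances()], [fit_mash_weights()] and [mash_posterior()]
#' the way the mapping protocol prescribes.
#'
#' @param assoc long association table (single term), or a ready
#'   `scqtl_mcstats`.
#' @param strong_lfsr strong-set threshold.
#' @param n_pcs,ed_iters data-driven covariance controls.
#' @param strong_max cap on the number of strong rows used for the
#'   data-driven covariances (the smallest-lfsr rows are kept).
#' @param subset_size,seed fitting-subset controls.
#' @return list with `posterior` (`scqtl_posterior`), `model`
#'   (`scqtl_mash`), `stats` (`scqtl_mcstats`), and the strong-set indices.
#' @export
run_mash <- function(assoc, strong_lfsr = 0.1, n_pcs = 5, ed_iters = 50,
                     strong_max = 1000, subset_size = 10000, seed = 2023) {
  stats <- if (inherits(assoc, "scqtl_mcstats")) assoc else multi_condition_stats(assoc)
  R <- length(stats$conditions)
  strong <- tryCatch(select_strong(stats, strong_lfsr), error = function(e) integer(0))
  U <- canonical_covariances(R, stats$conditions)
  complete <- rowSums(!is.finite(stats$Shat)) == 0
  strong_c <- intersect(strong, which(complete))
  if (length(strong_c) > strong_max) {
    ord <- order(attr(strong, "lfsr")[match(strong_c, strong)])
    strong_c <- strong_c[ord][seq_len(strong_max)]
  }
  if (length(strong_c) >= R + 2) {
    dd <- datadriven_covariances(stats$Bhat[strong_c, , drop = FALSE],
                                 stats$Shat[strong_c, , drop = FALSE],
                                 n_pcs = min(n_pcs, R), ed_iters = ed_iters)
    names(dd) <- paste0("ED_", names(dd))
    U <- c(U, dd)
  } else {
    warning("run_mash: strong set too small for data-driven covariances; using canonical only")
  }
  model <- fit_mash_weights(stats, U, subset_size = subset_size, seed = seed)
  posterior <- mash_posterior(stats, model)
  list(posterior = posterior, model = model, stats = stats, strong = strong)
}
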