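## Per-cell-type cis-eQTL scans with a two-random-effect linear mixed
## model: V = sigma2_K * K + sigma2_w * diag(1/nCells) + sigma2_e * I.
## Variance components are estimated once per gene under the null by REML
## and reused for every cis SNP (EMMAX-style), with Wald tests on the
## additive dose term or the dose-by-disease interaction term.

#' Rank-based inverse normal transform
#'
#' `y*_i = qnorm((rank_i - 0.5) / n)` with average ranks for ties.
#'
#' @param y numeric vector with at least 3 non-missing values.
#' @return the transformed vector (NAs preserved in place).
#' @export
inverse_normal_transform <- function(y) {
  ok <- !is.na(y)
  assert_that(sum(ok) >= 3, "inverse_normal_transform: need >= 3 non-missing values")
  assert_that(length(unique(y[ok])) > 1, "inverse_normal_transform: all values tied (degenerate)")
  out <- rep(NA_real_, length(y))
  r <- rank(y[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

#' Expression principal components
#'
#' PCs of a column-centered donor x gene matrix via SVD.
#'
#' @param Y donor x gene matrix (transformed expression for one cell type).
#' @param k number of PCs; capped at `min(k, n_donors - 2)`.
#' @return donor x k matrix of PC scores (unit-norm directions scaled by
#'   singular values).
#' @export
expression_pcs <- function(Y, k = 20) {
  assert_that(nrow(Y) >= 5, "expression_pcs: need at least 5 donors")
  k <- min(k, nrow(Y) - 2L, ncol(Y))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  s <- svd(Yc, nu = k, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(Y)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Residualize expression on principal components
#'
#' Ordinary least squares of each gene on an intercept plus the PCs;
#' returns the residuals.
#'
#' @param Y donor x gene matrix.
#' @param PCs donor x k PC score matrix.
#' @return matrix of residuals, same shape as `Y`.
#' @export
residualize <- function(Y, PCs) {
  X <- cbind(1, PCs)
  fit <- lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(Y)
  res
}

#' Genomic relationship (kinship) matrix
#'
#' `K = X_std X_std' / m` over m variants with column-standardized dosages.
#'
#' @param G a `scqtl_genotypes` (ideally post-[filter_variants()]).
#' @return symmetric donor x donor matrix.
#' @export
compute_kinship <- function(G) {
  stopifnot(inherits(G, "scqtl_genotypes"))
  X <- G$dosage
  sds <- apply(X, 2, sd)
  use <- sds > 0
  m <- sum(use)
  assert_that(m > 0, "compute_kinship: no polymorphic variants")
  if (m < 10) warning("compute_kinship: fewer than 10 variants; kinship will be noisy")
  Xs <- scale(X[, use, drop = FALSE])
  K <- tcrossprod(Xs) / m
  (K + t(K)) / 2
}

#' Fit the null covariance of one gene by REML
#'
#' Maximizes the restricted likelihood of `y` under
#' `V = sigma2_K K + sigma2_w diag(w) + sigma2_e I` with fixed effects `X`
#' (default intercept only), optimizing the two variance ratios
#' `lambda_K = sigma2_K / sigma2_e` and `lambda_w = sigma2_w / sigma2_e`
#' with `sigma2_e` profiled out.
#'
#' @param y response vector (transformed, residualized expression).
#' @param K kinship matrix.
#' @param w random-effect weights, typically `1 / nCells`.
#' @param X fixed-effect design matrix (default: intercept).
#' @param max_iter optimizer evaluation budget.
#' @return list with `V` (fitted covariance), `Vinv`, variance components
#'   `sigma2` (named K, w, e), `loglik` (REML), and `converged`.
#' @export
fit_null_covariance <- function(y, K, w, X = NULL, max_iter = 200) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  p <- ncol(X)
  reml <- function(par) {
    lk <- exp(par[1]); lw <- exp(par[2])
    V0 <- lk * K + diag(lw * w + 1, n)
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Vi_y)))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    rss <- sum(r * Vi_r)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * (1 + log(2 * pi * s2)) + logdetV + 2 * sum(log(diag(chx))))
  }
  ## two starts, always including the OLS corner (lambda = 0-ish), so the
  ## optimum can never fall below the no-structure model
  starts <- list(c(-8, -8), c(0, 0))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, reml, method = "L-BFGS-B", lower = -12, upper = 8,
            control = list(maxit = max_iter, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  converged <- !is.null(best) && is.finite(best$value) && best$value < 1e9
  if (!converged) {
    warning("fit_null_covariance: REML did not converge; falling back to OLS covariance")
    best <- list(par = c(-Inf, -Inf), value = reml(c(-20, -20)))
  }
  lk <- exp(best$par[1]); lw <- exp(best$par[2])
  if (!is.finite(lk)) lk <- 0
  if (!is.finite(lw)) lw <- 0
  V0 <- lk * K + diag(lw * w + 1, n)
  ch <- chol(V0)
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, backsolve(ch, forwardsolve(t(ch), y))))
  r <- as.numeric(y - X %*% beta)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Vi_r) / (n - p)
  V <- s2 * V0
  list(V = V, Vinv = chol2inv(chol(V)),
       sigma2 = c(K = s2 * lk, w = s2 * lw, e = s2),
       loglik = -best$value, converged = converged)
}

## cis window of a gene: strand-agnostic, measured from the gene-body ends.
cis_variants <- function(variants, gene_row, window) {
  variants$chrom == gene_row$chrom &
    variants$pos >= gene_row$start - window &
    variants$pos <= gene_row$end + window
}

## GLS of y on [1, g] for many g at once under the correlation structure of
## a fixed V (via Vinv); the residual scale is re-profiled per SNP so the
## K = I, equal-weights case reduces exactly to OLS (beta, se, df = n - 2).
gls_scan <- function(y, Gmat, Vinv) {
  n <- length(y)
  one <- rep(1, n)
  Vi1 <- Vinv %*% one
  Viy <- Vinv %*% y
  a11 <- sum(one * Vi1)
  ViG <- Vinv %*% Gmat
  a12 <- as.numeric(crossprod(Gmat, Vi1))
  a22 <- colSums(Gmat * ViG)
  b1 <- sum(one * Viy)
  b2 <- as.numeric(crossprod(Gmat, Viy))
  yViy <- sum(y * Viy)
  det <- a11 * a22 - a12^2
  det[det <= 0] <- NA
  beta0 <- (a22 * b1 - a12 * b2) / det
  beta <- (a11 * b2 - a12 * b1) / det
  rss <- yViy - 2 * (beta0 * b1 + beta * b2) +
    (beta0^2 * a11 + 2 * beta0 * beta * a12 + beta^2 * a22)
  scale <- pmax(rss, 0) / (n - 2)
  se <- sqrt(scale * a11 / det)
  list(beta = beta, se = se, df = n - 2)
}

#' Additive cis-eQTL scan
#'
#' For every gene of every cell type: inverse-normal transform, regress out
#' expression PCs, fit the null two-random-effect covariance once, then
#' test each cis variant by GLS with the variance components held fixed.
#'
#' @param pb a `scqtl_pseudobulk`.
#' @param G a filtered `scqtl_genotypes`.
#' @param annotation gene annotation data.frame (gene_id, chrom, start, end,
#'   tss, strand).
#' @param kinship donor x donor kinship matrix (dimnames = donor ids).
#' @param window cis window in bp from the gene-body ends.
#' @param n_pcs number of expression PCs to regress out.
#' @return data.frame of association summaries: cell_type, gene, variant,
#'   chrom, pos, term, beta, se, stat, p, tss_dist, n_donors.
#' @export
scan_cis_additive <- function(pb, G, annotation, kinship, window = 1e6, n_pcs = 20) {
  stopifnot(inherits(pb, "scqtl_pseudobulk"))
  res <- list()
  for (ct in names(pb)) {
    slot <- pb[[ct]]
    donors <- intersect(rownames(slot$expr), G$donors)
    Y <- slot$expr[donors, , drop = FALSE]
    ## drop degenerate genes (all-tied values cannot be transformed)
    degen <- apply(Y, 2, function(v) length(unique(v)) < 2)
    Y <- Y[, !degen, drop = FALSE]
    Yt <- apply(Y, 2, inverse_normal_transform)
    PCs <- expression_pcs(Yt, k = n_pcs)
    Yr <- residualize(Yt, PCs)
    Kd <- kinship[donors, donors]
    w <- 1 / slot$ncells[donors]
    X0 <- matrix(1, length(donors), 1)
    for (gene in colnames(Yr)) {
      ga <- annotation[annotation$gene_id == gene, ]
      if (nrow(ga) != 1) next
      sel <- cis_variants(G$variants, ga, window)
      if (!any(sel)) {
        message(sprintf("scan_cis_additive: gene %s has no cis variants; skipped", gene))
        next
      }
      y <- Yr[, gene]
      nf <- fit_null_covariance(y, Kd, w, X = X0)
      Gmat <- G$dosage[donors, sel, drop = FALSE]
      sc <- gls_scan(y, Gmat, nf$Vinv)
      v <- G$variants[sel, ]
      stat <- sc$beta / sc$se
      sign_tss <- if (ga$strand == "-") -1 else 1
      res[[length(res) + 1]] <- data.frame(
        cell_type = ct, gene = gene, variant = v$variant_id,
        chrom = v$chrom, pos = v$pos, term = "additive",
        beta = sc$beta, se = sc$se, stat = stat,
        p = 2 * pt(-abs(stat), df = sc$df),
        tss_dist = sign_tss * (v$pos - ga$tss),
        n_donors = length(donors), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[!is.na(out$beta), , drop = FALSE]
}

## general GLS Wald test of the last column of X under the correlation
## structure of a fixed Vinv, with the residual scale re-profiled.
gls_wald_last <- function(y, X, Vinv) {
  ViX <- Vinv %*% X
  XtViX <- crossprod(X, ViX)
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(c(NA, NA))
  covb <- chol2inv(ch)
  beta <- covb %*% crossprod(X, Vinv %*% y)
  r <- as.numeric(y - X %*% beta)
  q <- sum(r * (Vinv %*% r)) / (length(y) - ncol(X))
  j <- ncol(X)
  c(beta[j], sqrt(q * covb[j, j]))
}

#' Genotype-by-disease interaction cis-eQTL scan
#'
#' Fixed effects `[1, PC1..PCk, dose, disease, dose x disease]` under the
#' gene's fixed null covariance; Wald test on the interaction coefficient.
#' PCs are included as fixed effects (not regressed out) because disease
#' status can correlate with expression PCs. Variants must have MAF >=
#' `group_maf_min` in both disease groups cohort-wide, and rows where the
#' observed per-cell-type per-group MAF is <= `group_maf_min` are dropped
#' post hoc.
#'
#' @param pb a `scqtl_pseudobulk`.
#' @param G a filtered `scqtl_genotypes`.
#' @param annotation gene annotation data.frame.
#' @param kinship donor x donor kinship matrix.
#' @param window cis window in bp.
#' @param n_pcs number of expression PCs used as fixed effects.
#' @param group_maf_min per-disease-group MAF threshold.
#' @param min_group_donors minimum diseased and unaffected donors a cell
#'   type needs to be tested (10 per the mapping protocol; 5 is a common
#'   relaxation).
#' @return data.frame of interaction association summaries with per-group
#'   observed MAFs (`maf_case`, `maf_control`).
#' @export
scan_cis_interaction <- function(pb, G, annotation, kinship, window = 1e6,
                                 n_pcs = 20, group_maf_min = 0.05,
                                 min_group_donors = 10) {
  stopifnot(inherits(pb, "scqtl_pseudobulk"))
  ## cohort-wide per-group MAF pre-filter over all pseudobulk donors
  all_donors <- sort(unique(unlist(lapply(pb, function(s) rownames(s$expr)))))
  all_donors <- intersect(all_donors, G$donors)
  dis_map <- do.call(rbind, lapply(pb, function(s)
    data.frame(donor = names(s$disease), disease = unname(s$disease))))
  dis_map <- dis_map[!duplicated(dis_map$donor), ]
  dis_all <- setNames(dis_map$disease, dis_map$donor)[all_donors]
  grp_maf <- function(dose_mat, case) {
    af <- colMeans(dose_mat[case, , drop = FALSE]) / 2
    pmin(af, 1 - af)
  }
  case_all <- dis_all == "ILD"
  maf_case_cohort <- grp_maf(G$dosage[all_donors, , drop = FALSE], case_all)
  maf_ctrl_cohort <- grp_maf(G$dosage[all_donors, , drop = FALSE], !case_all)
  pass_cohort <- maf_case_cohort >= group_maf_min & maf_ctrl_cohort >= group_maf_min

  res <- list()
  for (ct in names(pb)) {
    slot <- pb[[ct]]
    donors <- intersect(rownames(slot$expr), G$donors)
    dis <- slot$disease[donors] == "ILD"
    if (sum(dis) < min_group_donors || sum(!dis) < min_group_donors) {
      message(sprintf("scan_cis_interaction: %s skipped (%d ILD / %d control donors)",
                      ct, sum(dis), sum(!dis)))
      next
    }
    Y <- slot$expr[donors, , drop = FALSE]
    degen <- apply(Y, 2, function(v) length(unique(v)) < 2)
    Y <- Y[, !degen, drop = FALSE]
    Yt <- apply(Y, 2, inverse_normal_transform)
    PCs <- expression_pcs(Yt, k = n_pcs)
    ## guard against disease being confounded with a PC
    Xbase <- cbind(1, PCs, disease = as.numeric(dis))
    qrX <- qr(Xbase)
    if (qrX$rank < ncol(Xbase)) {
      drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(Xbase)]
      keep_pcs <- setdiff(seq_len(ncol(PCs)) + 1L, drop_idx)
      warning(sprintf("scan_cis_interaction: %s rank-deficient design; dropped %d PC(s)",
                      ct, ncol(PCs) - length(keep_pcs)))
      PCs <- PCs[, keep_pcs - 1L, drop = FALSE]
    }
    Kd <- kinship[donors, donors]
    w <- 1 / slot$ncells[donors]
    d_num <- as.numeric(dis)
    Xnull <- cbind(1, PCs, d_num)
    maf_case_ct <- grp_maf(G$dosage[donors, , drop = FALSE], dis)
    maf_ctrl_ct <- grp_maf(G$dosage[donors, , drop = FALSE], !dis)
    for (gene in colnames(Yt)) {
      ga <- annotation[annotation$gene_id == gene, ]
      if (nrow(ga) != 1) next
      sel <- which(cis_variants(G$variants, ga, window) & pass_cohort)
      ## post-hoc per-cell-type per-group MAF pruning
      sel <- sel[maf_case_ct[sel] > group_maf_min & maf_ctrl_ct[sel] > group_maf_min]
      if (length(sel) == 0) next
      y <- Yt[, gene]
      nf <- fit_null_covariance(y, Kd, w, X = Xnull)
      out <- matrix(NA_real_, length(sel), 2)
      for (i in seq_along(sel)) {
        g <- G$dosage[donors, sel[i]]
        X <- cbind(1, PCs, g, d_num, g * d_num)
        out[i, ] <- gls_wald_last(y, X, nf$Vinv)
      }
      v <- G$variants[sel, ]
      stat <- out[, 1] / out[, 2]
      sign_tss <- if (ga$strand == "-") -1 else 1
      df_resid <- length(donors) - (ncol(PCs) + 4L)
      res[[length(res) + 1]] <- data.frame(
        cell_type = ct, gene = gene, variant = v$variant_id,
        chrom = v$chrom, pos = v$pos, term = "interaction",
        beta = out[, 1], se = out[, 2], stat = stat,
        p = 2 * pt(-abs(stat), df = max(df_resid, 1)),
        tss_dist = sign_tss * (v$pos - ga$tss),
        n_donors = length(donors),
        maf_case = maf_case_ct[sel], maf_control = maf_ctrl_ct[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[!is.na(out$beta), , drop = FALSE]
}
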