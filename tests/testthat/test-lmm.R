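# Mixed-model association scans: transform, PCs, kinship, REML null fit,
# GLS oracle equivalence, and invariances of both scan paths.

test_that("inverse normal transform matches quantile oracle and is rank-invariant", {
  y <- c(3.1, 1.2, 2.0)
  expect_equal(inverse_normal_transform(y),
               qnorm((rank(y) - 0.5) / 3), tolerance = 1e-12)
  expect_equal(inverse_normal_transform(y),
               c(0.9674, -0.9674, 0), tolerance = 1e-4)
  ## median maps to 0 for odd n
  y5 <- c(10, 2, 7, 1, 4)
  expect_equal(inverse_normal_transform(y5)[y5 == 4], 0)
  ## any strictly monotone pre-transform leaves the result unchanged
  expect_equal(inverse_normal_transform(exp(y5)), inverse_normal_transform(y5))
  expect_error(inverse_normal_transform(rep(1, 5)), "tied")
  expect_error(inverse_normal_transform(c(1, 2)), ">= 3")
})

test_that("expression PCs: exact fit on rank-1 data, orthogonal residuals, eigen oracle", {
  set.seed(2)
  u <- rnorm(30); v <- rnorm(8)
  Y1 <- outer(u, v)
  P1 <- expression_pcs(Y1, k = 1)
  R1 <- residualize(Y1, P1)
  expect_lt(max(abs(R1)), 1e-8)

  Y <- matrix(rnorm(30 * 12), 30, 12)
  PCs <- expression_pcs(Y, k = 4)
  res <- residualize(Y, PCs)
  expect_lt(max(abs(crossprod(res, PCs))), 1e-8)
  ## PC variance matches the covariance eigendecomposition
  ev <- eigen(cov(Y), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(apply(PCs, 2, var), ev[1:4], tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(expression_pcs(Y[1:4, ]), "5 donors")
})

test_that("kinship: duplicate donors, symmetry, off-diagonal noise bound", {
  sim <- fx_cohort()
  G <- sim$genotypes
  K <- compute_kinship(G)
  expect_equal(K, t(K), tolerance = 1e-12)
  ## duplicated genotype rows give near-diagonal kinship entries
  G2 <- G
  G2$dosage <- rbind(G$dosage, dup = G$dosage[1, ])
  G2$donors <- c(G$donors, "dup")
  rownames(G2$dosage) <- G2$donors
  K2 <- compute_kinship(G2)
  expect_equal(K2["dup", G$donors[1]],
               mean(c(K2["dup", "dup"], K2[G$donors[1], G$donors[1]])),
               tolerance = 1e-6)
})

test_that("null REML reduces to OLS without structure and recovers planted variance", {
  set.seed(4)
  n <- 80
  donors <- sprintf("D%03d", 1:n)
  K <- diag(n); dimnames(K) <- list(donors, donors)
  y <- rnorm(n)
  nf <- fit_null_covariance(y, K, w = rep(1, n))
  ## per-SNP tests match OLS p within 1e-6
  for (i in 1:5) {
    g <- rbinom(n, 2, 0.4)
    sc <- scqtl:::gls_scan(y, matrix(g, ncol = 1), nf$Vinv)
    f <- summary(lm(y ~ g))$coefficients
    expect_equal(sc$beta, f[2, 1], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(sc$se, f[2, 2], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(2 * pt(-abs(sc$beta / sc$se), sc$df), f[2, 4], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  ## REML objective at the optimum is no worse than at the OLS corner
  ## (variance ratios ~ 0), by construction of the multi-start search
  expect_true(nf$converged)
  expect_lt(nf$sigma2[["K"]] + nf$sigma2[["w"]], 0.5 * nf$sigma2[["e"]])

  ## planted kinship variance: median ratio over replicates inside [0.6, 1.6]
  n2 <- 200
  donors2 <- sprintf("D%03d", 1:n2)
  blocks <- matrix(0.5, 4, 4); diag(blocks) <- 1
  K2 <- as.matrix(Matrix::bdiag(replicate(n2 / 4, blocks, simplify = FALSE)))
  dimnames(K2) <- list(donors2, donors2)
  L <- t(chol(K2))
  ratios <- vapply(1:30, function(r) {
    set.seed(100 + r)
    yy <- as.numeric(L %*% rnorm(n2)) + rnorm(n2)   # sigma2_K = sigma2_e = 1
    f <- fit_null_covariance(yy, K2, w = rep(1, n2))
    f$sigma2[["K"]] / f$sigma2[["e"]]
  }, 0)
  expect_gt(median(ratios), 0.6)
  expect_lt(median(ratios), 1.6)
})

test_that("additive scan matches a closed-form GLS oracle on a 6-donor toy", {
  ## fixed V with unequal weights; compare against direct matrix algebra
  donors <- paste0("D", 1:6)
  w <- c(1, 1/2, 1/5, 1/10, 1/4, 1/8)
  K <- diag(6); dimnames(K) <- list(donors, donors)
  y <- c(0.3, -1.2, 0.5, 2.0, -0.7, 1.1)
  g <- c(0, 1, 2, 1, 0, 2)
  lambda_w <- 3
  V <- diag(lambda_w * w + 1)
  Vinv <- solve(V)
  X <- cbind(1, g)
  XtVX <- solve(t(X) %*% Vinv %*% X)
  beta_o <- XtVX %*% t(X) %*% Vinv %*% y
  r <- y - X %*% beta_o
  q <- as.numeric(t(r) %*% Vinv %*% r) / (6 - 2)
  se_o <- sqrt(q * XtVX[2, 2])
  sc <- scqtl:::gls_scan(y, matrix(g, ncol = 1), Vinv)
  expect_equal(sc$beta, beta_o[2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sc$se, se_o, tolerance = 1e-6, ignore_attr = TRUE)
  ## and the general fixed-effect path agrees with the two-column fast path
  wl <- scqtl:::gls_wald_last(y, X, Vinv)
  expect_equal(wl[1], sc$beta, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(wl[2], sc$se, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("scan windowing excludes variants outside the cis window", {
  fxp <- fx_pipe()
  ann <- fxp$ann
  gene <- colnames(fxp$pb[[1]]$expr)[1]
  ga <- ann[ann$gene_id == gene, ]
  v <- fxp$Gf$variants
  in_10kb <- sum(v$chrom == ga$chrom & v$pos >= ga$start - 10000 &
                   v$pos <= ga$end + 10000)
  aa <- scan_cis_additive(fxp$pb, fxp$Gf, ann[ann$gene_id == gene, ],
                          fxp$kinship, window = 10000, n_pcs = 5)
  expect_true(all(aa$pos >= ga$start - 10000 & aa$pos <= ga$end + 10000))
  expect_identical(length(unique(aa$variant)), in_10kb)
})

test_that("allele relabeling flips beta only; disease recoding keeps |stat|", {
  fxp <- fx_pipe()
  sub_ann <- fxp$ann[1:4, ]
  aa1 <- scan_cis_additive(fxp$pb, fxp$Gf, sub_ann, fxp$kinship, n_pcs = 5)
  Gflip <- fxp$Gf
  Gflip$dosage <- 2 - Gflip$dosage
  aa2 <- scan_cis_additive(fxp$pb, Gflip, sub_ann, fxp$kinship, n_pcs = 5)
  expect_equal(aa1$beta, -aa2$beta, tolerance = 1e-8)
  expect_equal(aa1$p, aa2$p, tolerance = 1e-8)

  ai1 <- scan_cis_interaction(fxp$pb, fxp$Gf, sub_ann, fxp$kinship,
                              n_pcs = 5, min_group_donors = 5)
  ## swap the disease coding by relabeling groups in the pseudobulk
  pb_sw <- fxp$pb
  for (ct in names(pb_sw))
    pb_sw[[ct]]$disease[] <- ifelse(pb_sw[[ct]]$disease == "ILD", "control", "ILD")
  class(pb_sw) <- "scqtl_pseudobulk"
  ai2 <- scan_cis_interaction(pb_sw, fxp$Gf, sub_ann, fxp$kinship,
                              n_pcs = 5, min_group_donors = 5)
  m <- merge(ai1, ai2, by = c("cell_type", "gene", "variant"))
  expect_gt(nrow(m), 0)
  expect_equal(abs(m$stat.x), abs(m$stat.y), tolerance = 1e-6)
})

test_that("interaction scan enforces the per-group MAF and donor rules", {
  fxp <- fx_pipe()
  sub_ann <- fxp$ann[1:4, ]
  ai <- scan_cis_interaction(fxp$pb, fxp$Gf, sub_ann, fxp$kinship,
                             n_pcs = 5, min_group_donors = 5)
  expect_true(all(ai$maf_case > 0.05 & ai$maf_control > 0.05))
  ## a cell type lacking enough donors in either group is skipped
  pb_small <- fxp$pb["CT1"]
  class(pb_small) <- "scqtl_pseudobulk"
  keep <- names(pb_small$CT1$disease)[c(which(pb_small$CT1$disease == "ILD")[1:3],
                                        which(pb_small$CT1$disease == "control"))]
  pb_small$CT1$expr <- pb_small$CT1$expr[keep, ]
  pb_small$CT1$ncells <- pb_small$CT1$ncells[keep]
  pb_small$CT1$disease <- pb_small$CT1$disease[keep]
  expect_message(
    out <- scan_cis_interaction(pb_small, fxp$Gf, sub_ann, fxp$kinship,
                                n_pcs = 5, min_group_donors = 10),
    "skipped")
  expect_null(out)
})
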