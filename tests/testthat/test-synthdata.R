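# Generator properties: determinism, kinship structure, LD calibration,
# recoverability of planted effects by simple OLS oracles, fixture I/O.

test_that("identical seed reproduces genotypes, kinship and cells exactly", {
  cfg <- sim_config(n_donors = 20, n_genes = 4, snps_per_gene = 6, seed = 42,
                    cell_types = c("A", "B"), cells_per_donor = c(10, 6),
                    donor_dropout = c(0, 0.1))
  a <- simulate_cohort(cfg, n_per_pattern = c(global = 1))
  b <- simulate_cohort(cfg, n_per_pattern = c(global = 1))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$kinship, b$kinship)
  expect_identical(as.matrix(a$cells$counts), as.matrix(b$cells$counts))
  expect_identical(a$cells$cell_meta, b$cells$cell_meta)
})

test_that("zero relatedness yields identity kinship; families raise it", {
  cfg0 <- sim_config(n_donors = 30, n_genes = 10, snps_per_gene = 20,
                     n_families = 5, family_size = 2, relatedness = 0, seed = 8)
  sg0 <- simulate_genotypes(cfg0)
  expect_equal(sg0$kinship, diag(30), ignore_attr = TRUE)
  ## empirical GRM close to identity: off-diagonals O(1/sqrt(m))
  K <- compute_kinship(sg0$genotypes)
  off <- K[upper.tri(K)]
  expect_lt(max(abs(off)), 6 / sqrt(ncol(sg0$genotypes$dosage)))

  cfgr <- sim_config(n_donors = 80, n_genes = 25, snps_per_gene = 20,
                     n_families = 20, family_size = 2, relatedness = 0.5, seed = 9)
  sgr <- simulate_genotypes(cfgr)
  Kr <- compute_kinship(sgr$genotypes)
  fam_pairs <- vapply(seq_len(20), function(f) Kr[2 * f - 1, 2 * f], 0)
  unrel <- Kr[61:70, 71:80]
  expect_gt(mean(fam_pairs), mean(unrel) + 0.2)
  ## returned expected kinship is symmetric PSD with unit diagonal
  expect_true(isSymmetric(sgr$kinship))
  expect_gte(min(eigen(sgr$kinship, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(mean(diag(sgr$kinship)), 1)
})

test_that("adjacent within-block dosage r^2 matches the configured LD", {
  cfg <- sim_config(n_donors = 500, n_genes = 10, snps_per_gene = 20,
                    ld_block_size = 5, ld_r = 0.9, n_families = 0, seed = 77)
  sg <- simulate_genotypes(cfg)
  si <- sg$genotypes$sim_info
  r2 <- c()
  for (b in unique(si$block)) {
    j <- which(si$block == b)
    if (length(j) < 2) next
    for (k in seq_len(length(j) - 1)) {
      r <- suppressWarnings(cor(sg$genotypes$dosage[, j[k]],
                                sg$genotypes$dosage[, j[k + 1]]))
      if (is.finite(r)) r2 <- c(r2, r^2)
    }
  }
  expect_equal(mean(r2), 0.81, tolerance = 0.1 / 0.81)
  ## dosages are hard calls with coordinates and alleles
  expect_true(all(sg$genotypes$dosage %in% 0:2))
  expect_true(all(c("chrom", "pos", "ref", "alt") %in% names(sg$genotypes$variants)))
})

test_that("planted additive effect is recovered by a pseudo-bulk OLS oracle", {
  cfg <- sim_config(n_donors = 100, n_genes = 6, snps_per_gene = 8,
                    cell_types = "CT1", cells_per_donor = 50, donor_dropout = 0,
                    baseline_log_range = log(c(20, 20)), n_families = 0, seed = 5)
  sg <- simulate_genotypes(cfg)
  design <- plant_effects(sg$genotypes, cfg, c(unique = 1), beta = 1)
  cells <- simulate_cells(sg$genotypes, sg$kinship, design, cfg)
  gene <- design$effects$gene[1]
  dose <- sg$genotypes$dosage[, design$effects$variant[1]]
  ## oracle: per-donor mean of log counts, OLS on dose (natural-log scale)
  lg <- log(as.numeric(cells$counts[, gene]) + 1)
  pbk <- tapply(lg, cells$cell_meta$donor, mean)
  slope <- coef(lm(pbk ~ dose[names(pbk)]))[2]
  expect_equal(unname(slope), 1, tolerance = 0.15)
})

test_that("interaction-only effects show group-specific dose slopes", {
  cfg <- sim_config(n_donors = 120, n_genes = 6, snps_per_gene = 8,
                    cell_types = "CT1", cells_per_donor = 50, donor_dropout = 0,
                    baseline_log_range = log(c(20, 20)), n_families = 0, seed = 6)
  sg <- simulate_genotypes(cfg)
  design <- plant_effects(sg$genotypes, cfg, c(interaction_only = 1),
                          beta_gd = 1, beta_disease = 0)
  cells <- simulate_cells(sg$genotypes, sg$kinship, design, cfg)
  gene <- design$effects$gene[1]
  dose <- sg$genotypes$dosage[, design$effects$variant[1]]
  lg <- log(as.numeric(cells$counts[, gene]) + 1)
  pbk <- tapply(lg, cells$cell_meta$donor, mean)
  dis <- setNames(cells$donor_meta$disease, cells$donor_meta$donor)[names(pbk)]
  s_ctrl <- coef(lm(pbk[dis == "control"] ~ dose[names(pbk)][dis == "control"]))[2]
  s_ild <- coef(lm(pbk[dis == "ILD"] ~ dose[names(pbk)][dis == "ILD"]))[2]
  expect_equal(unname(s_ctrl), 0, tolerance = 0.15)
  expect_equal(unname(s_ild - s_ctrl), 1, tolerance = 0.2)
})

test_that("design invariants reject inconsistent patterns", {
  sim <- fx_cohort()
  d <- sim$design
  expect_true(all(vapply(seq_len(nrow(d$effects)), function(i) {
    b <- d$beta[d$effects$gene[i], ]
    switch(d$effects$pattern[i],
           global = all(b != 0),
           multi = sum(b != 0) >= 2 && sum(b != 0) < length(b),
           unique = sum(b != 0) == 1,
           sign_flip = any(b > 0) && any(b < 0),
           interaction_only = all(b == 0) &&
             any(d$beta_gd[d$effects$gene[i], ] != 0))
  }, TRUE)))
  ## broken design is rejected
  bad <- d
  bad$beta[bad$effects$gene[bad$effects$pattern == "unique"][1], ] <- 1
  expect_error(scqtl:::validate_design(bad), "invariant")
})

test_that("GWAS simulator modes behave as designed and report valid se", {
  cfg <- sim_config(n_donors = 200, n_genes = 2, snps_per_gene = 60,
                    ld_block_size = 6, n_families = 0, seed = 33)
  sg <- simulate_genotypes(cfg)
  cv <- sg$genotypes$sim_info$variant_id[30]
  ## null mode: one z per LD block over replicates behaves as N(0,1)
  zs <- c()
  for (s in 1:25) {
    gw <- simulate_gwas_stats(sg$genotypes, cv, n_gwas = 600, mode = "null", seed = s)
    first <- !duplicated(sg$genotypes$sim_info$block[
      match(gw$variant, sg$genotypes$sim_info$variant_id)])
    zs <- c(zs, (gw$beta / gw$se)[first])
    expect_true(all(gw$se > 0))
  }
  expect_gt(ks.test(zs, "pnorm")$p.value, 0.01)
  ## shared mode with strong signal: top hit in high LD with the causal
  gw <- simulate_gwas_stats(sg$genotypes, cv, n_gwas = 5000, h2_snp = 0.05,
                            mode = "shared", seed = 4)
  top <- gw$variant[which.max(abs(gw$beta / gw$se))]
  r2 <- cor(sg$genotypes$dosage[, top], sg$genotypes$dosage[, cv])^2
  expect_gt(r2, 0.8)
  expect_error(simulate_gwas_stats(sg$genotypes, "nope", mode = "null"), "unknown variant")
})

test_that("fixtures round-trip losslessly and the VCF parses as VCFv4.2", {
  sim <- fx_cohort()
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim, dir)
  G <- read_genotypes(paths[["vcf"]])
  d0 <- sim$genotypes$dosage
  expect_equal(G$dosage[rownames(d0), colnames(d0)], d0, ignore_attr = TRUE)
  cells <- read_cell_counts(paths[["mtx"]], paths[["cells"]], paths[["genes"]])
  expect_equal(as.matrix(cells$counts), as.matrix(sim$cells$counts))
  expect_identical(nrow(read.delim(paths[["cells"]])), nrow(sim$cells$cell_meta))
  ## external format check
  if (nzchar(Sys.which("bcftools"))) {
    n_rec <- length(system2("bcftools", c("view", "-H", paths[["vcf"]]),
                            stdout = TRUE))
    expect_identical(n_rec, nrow(sim$genotypes$variants))
  }
  v <- vcfR::read.vcfR(paths[["vcf"]], verbose = FALSE)
  expect_identical(nrow(v@fix), nrow(sim$genotypes$variants))
})
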