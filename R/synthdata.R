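## Synthetic cohort generator: genotypes with LD-block and family structure,
## cell-level negative-binomial counts with planted cis / disease-interaction
## effects, and GWAS summary statistics driven through the same LD panel.
## The generative model mirrors the assumptions of the downstream mixed model:
## log-scale additive allelic effects plus a donor random effect whose
## covariance is the kinship matrix.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort. Defaults emulate the study
#' design the pipeline targets: ~116 donors, 58% diseased, several cell
#' types with unequal donor coverage and per-donor cell counts, cis-SNPs in
#' LD blocks, and a minority of donors in close-kin families.
#'
#' @param n_donors number of donors.
#' @param frac_diseased fraction of donors carrying the disease label.
#' @param cell_types character vector of cell type names.
#' @param cells_per_donor mean cells per donor for each cell type (recycled).
#' @param donor_dropout per-cell-type probability that a donor contributes no
#'   cells of that type (recycled).
#' @param n_genes number of genes.
#' @param snps_per_gene cis-SNPs simulated per gene.
#' @param maf_range length-2 numeric in (0, 0.5], range of block minor allele
#'   frequencies.
#' @param ld_block_size number of adjacent SNPs per LD block.
#' @param ld_r target correlation of adjacent SNP dosages within a block.
#' @param n_families number of close-kin donor families.
#' @param family_size donors per family.
#' @param relatedness expected kinship coefficient within a family.
#' @param nb_dispersion negative-binomial dispersion (1/size) of counts.
#' @param re_sd standard deviation (log scale) of the donor random effect.
#' @param baseline_log_range range of per-gene baseline log mean counts.
#' @param mito_beta length-2 shape parameters of the Beta distribution of
#'   per-cell mitochondrial read fractions.
#' @param seed mandatory integer random seed.
#' @return an object of class `scqtl_sim_config` (a validated list).
#' @export
sim_config <- function(n_donors = 116,
                       frac_diseased = 0.58,
                       cell_types = paste0("CT", 1:6),
                       cells_per_donor = c(80, 50, 40, 25, 15, 8),
                       donor_dropout = c(0, 0, 0.05, 0.1, 0.15, 0.25),
                       n_genes = 50,
                       snps_per_gene = 20,
                       maf_range = c(0.1, 0.5),
                       ld_block_size = 5,
                       ld_r = 0.9,
                       n_families = 10,
                       family_size = 2,
                       relatedness = 0.25,
                       nb_dispersion = 0.5,
                       re_sd = 0.2,
                       baseline_log_range = log(c(0.5, 5)),
                       mito_beta = c(2, 20),
                       seed = NULL) {
  assert_that(!is.null(seed) && is.finite(seed), "sim_config: `seed` is mandatory")
  assert_that(n_donors >= 2 && n_genes >= 1 && snps_per_gene >= 1,
              "sim_config: dimensions must be positive")
  assert_that(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2],
              "sim_config: maf_range must lie in (0, 0.5]")
  assert_that(frac_diseased >= 0 && frac_diseased <= 1, "sim_config: frac_diseased in [0,1]")
  assert_that(ld_r >= 0 && ld_r < 1, "sim_config: ld_r in [0,1)")
  assert_that(n_families * family_size <= n_donors,
              "sim_config: families cannot exceed donor count")
  cfg <- list(
    n_donors = as.integer(n_donors), frac_diseased = frac_diseased,
    cell_types = cell_types,
    cells_per_donor = rep_len(cells_per_donor, length(cell_types)),
    donor_dropout = rep_len(donor_dropout, length(cell_types)),
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    ld_r = ld_r, n_families = as.integer(n_families),
    family_size = as.integer(family_size), relatedness = relatedness,
    nb_dispersion = nb_dispersion, re_sd = re_sd,
    baseline_log_range = baseline_log_range, mito_beta = mito_beta,
    seed = as.integer(seed))
  class(cfg) <- "scqtl_sim_config"
  cfg
}

## Deterministic gene annotation layout: genes cycle over 6 autosomes with
## 4 Mb spacing so default 1 Mb cis windows never overlap neighbours.
sim_gene_annotation <- function(config) {
  n <- config$n_genes
  i <- seq_len(n)
  chrom <- paste0("chr", ((i - 1L) %% 6L) + 1L)
  idx <- (i - 1L) %/% 6L
  start <- 1e6 + idx * 4e6
  len <- 10000
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  tss <- ifelse(strand == "+", start, start + len)
  data.frame(gene_id = sprintf("G%04d", i), chrom = chrom,
             start = start, end = start + len, tss = tss, strand = strand,
             stringsAsFactors = FALSE)
}

## One LD block of haplotype alleles: a shared-uniform copying chain gives
## adjacent-variant correlation `t` exactly when the block MAF is constant.
sim_hap_block <- function(n_snps, n_hap, maf, t) {
  U <- matrix(0, n_snps, n_hap)
  U[1, ] <- runif(n_hap)
  if (n_snps > 1) {
    for (j in 2:n_snps) {
      keep <- runif(n_hap) < t
      fresh <- runif(n_hap)
      U[j, ] <- ifelse(keep, U[j - 1, ], fresh)
    }
  }
  (U < maf) * 1L
}

#' Simulate donor genotypes and kinship
#'
#' Draws haplotypes from a block-structured copying model (constant allele
#' frequency within a block, adjacent-SNP correlation `ld_r`), assembles
#' donor dosages as the sum of two haplotypes, and induces family
#' relatedness by letting family members copy founder haplotypes with
#' probability `sqrt(relatedness)`.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a `scqtl_genotypes` object, see
#'   [genotype_matrix()]) and `kinship` (the expected donor relatedness
#'   matrix: unit diagonal, `relatedness` within families).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "scqtl_sim_config"))
  withr::with_seed(derive_seed(config$seed, 11L), {
    ann <- sim_gene_annotation(config)
    n_d <- config$n_donors
    donors <- sprintf("D%03d", seq_len(n_d))
    m_per <- config$snps_per_gene
    blocks_per_gene <- ceiling(m_per / config$ld_block_size)

    ## family copying structure
    fam <- rep(NA_integer_, n_d)
    if (config$n_families > 0 && config$family_size > 1)
      fam[seq_len(config$n_families * config$family_size)] <-
        rep(seq_len(config$n_families), each = config$family_size)
    q <- sqrt(config$relatedness)

    variant_list <- vector("list", config$n_genes)
    dosage_list <- vector("list", config$n_genes)
    geneid_list <- vector("list", config$n_genes)
    block_list <- vector("list", config$n_genes)
    maf_list <- vector("list", config$n_genes)
    bases <- c("A", "C", "G", "T")

    for (g in seq_len(config$n_genes)) {
      pos <- sort(sample(seq(ann$start[g] - 50000, ann$end[g] + 50000), m_per))
      block <- rep(seq_len(blocks_per_gene), each = config$ld_block_size)[seq_len(m_per)]
      maf_b <- runif(blocks_per_gene, config$maf_range[1], config$maf_range[2])
      mafs <- maf_b[block]
      ## haplotypes: per donor two own draws, plus two founder draws per family;
      ## a family member's haplotype is the founder's with probability q.
      H <- matrix(0L, m_per, 0)
      hap_own <- vector("list", blocks_per_gene)
      for (b in seq_len(blocks_per_gene)) {
        k <- sum(block == b)
        hap_own[[b]] <- sim_hap_block(k, 2L * n_d + 2L * max(config$n_families, 1L),
                                      maf_b[b], config$ld_r)
      }
      own <- do.call(rbind, hap_own)   # m_per x (2 n_d + 2 n_fam)
      h1 <- own[, seq_len(n_d), drop = FALSE]
      h2 <- own[, n_d + seq_len(n_d), drop = FALSE]
      if (config$n_families > 0 && config$family_size > 1) {
        F1 <- own[, 2L * n_d + seq_len(config$n_families), drop = FALSE]
        F2 <- own[, 2L * n_d + config$n_families + seq_len(config$n_families), drop = FALSE]
        for (d in which(!is.na(fam))) {
          f <- fam[d]
          if (runif(1) < q) h1[, d] <- F1[, f]
          if (runif(1) < q) h2[, d] <- F2[, f]
        }
      }
      dose <- t(h1 + h2)               # donors x m_per
      ref <- sample(bases, m_per, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      vid <- sprintf("%s_%d_%s_%s", ann$chrom[g], pos, ref, alt)
      variant_list[[g]] <- data.frame(variant_id = vid, chrom = ann$chrom[g],
                                      pos = pos, ref = ref, alt = alt,
                                      stringsAsFactors = FALSE)
      dosage_list[[g]] <- dose
      geneid_list[[g]] <- rep(ann$gene_id[g], m_per)
      block_list[[g]] <- sprintf("%s_b%d", ann$gene_id[g], block)
      maf_list[[g]] <- mafs
    }

    variants <- do.call(rbind, variant_list)
    dosage <- do.call(cbind, dosage_list)
    rownames(dosage) <- donors
    colnames(dosage) <- variants$variant_id
    G <- genotype_matrix(dosage, variants, donors)
    G$sim_info <- data.frame(variant_id = variants$variant_id,
                             gene = unlist(geneid_list),
                             block = unlist(block_list),
                             true_maf = unlist(maf_list),
                             stringsAsFactors = FALSE)
    G$sim_ld_r <- config$ld_r
    G$gene_annotation <- ann

    K <- diag(n_d)
    if (config$n_families > 0 && config$family_size > 1)
      for (f in seq_len(config$n_families)) {
        idx <- which(fam == f)
        K[idx, idx] <- config$relatedness
        diag(K)[idx] <- 1
      }
    dimnames(K) <- list(donors, donors)
    list(genotypes = G, kinship = K)
  })
}

#' Plant eQTL effects
#'
#' Builds an effect design: a set of genes each assigned one causal cis
#' variant and a per-cell-type true effect vector following one of five
#' sharing patterns.
#'
#' @param genotypes a `scqtl_genotypes` object from [simulate_genotypes()].
#' @param config the [sim_config()] used to generate it.
#' @param n_per_pattern named integer vector giving the number of genes per
#'   pattern; names from `global`, `multi`, `unique`, `sign_flip`,
#'   `interaction_only`. Remaining genes stay null.
#' @param beta absolute additive effect size (log-expression per allele dose).
#' @param beta_gd genotype-by-disease interaction effect size.
#' @param beta_disease disease main effect applied to genes with planted
#'   interaction effects.
#' @return an object of class `scqtl_design`: a data.frame `effects`
#'   (gene, variant, pattern) plus matrices `beta`, `beta_gd`,
#'   `disease_main` (gene x cell type, rows for all genes).
#' @export
plant_effects <- function(genotypes, config,
                          n_per_pattern = c(global = 3, multi = 3, unique = 3,
                                            sign_flip = 3, interaction_only = 3),
                          beta = 1, beta_gd = 1, beta_disease = 0.3) {
  stopifnot(inherits(genotypes, "scqtl_genotypes"))
  pats <- c("global", "multi", "unique", "sign_flip", "interaction_only")
  assert_that(all(names(n_per_pattern) %in% pats), "plant_effects: unknown pattern name")
  total <- sum(n_per_pattern)
  ann <- genotypes$gene_annotation
  assert_that(total <= nrow(ann), "plant_effects: more planted genes than simulated genes")
  R <- length(config$cell_types)
  withr::with_seed(derive_seed(config$seed, 23L), {
    genes <- sample(ann$gene_id, total)
    pattern <- rep(names(n_per_pattern), times = n_per_pattern)
    ## causal variant: the median-position cis SNP of the gene
    causal <- vapply(genes, function(g) {
      ids <- genotypes$sim_info$variant_id[genotypes$sim_info$gene == g]
      ids[ceiling(length(ids) / 2)]
    }, "")
    B <- matrix(0, nrow(ann), R, dimnames = list(ann$gene_id, config$cell_types))
    Bgd <- B; Dmain <- B
    for (i in seq_along(genes)) {
      g <- genes[i]
      switch(pattern[i],
        global = { B[g, ] <- beta },
        multi = {
          k <- max(2L, min(R - 1L, ceiling(R / 2)))
          B[g, sample(R, k)] <- beta
        },
        unique = { B[g, sample(R, 1)] <- beta },
        sign_flip = {
          s <- rep(c(1, -1), length.out = R)
          B[g, ] <- beta * sample(s)
        },
        interaction_only = {
          Bgd[g, ] <- beta_gd
          Dmain[g, ] <- beta_disease
        })
    }
    design <- list(effects = data.frame(gene = genes, variant = unname(causal),
                                        pattern = pattern, stringsAsFactors = FALSE),
                   beta = B, beta_gd = Bgd, disease_main = Dmain,
                   cell_types = config$cell_types)
    class(design) <- "scqtl_design"
    validate_design(design)
    design
  })
}

validate_design <- function(design) {
  eff <- design$effects
  for (i in seq_len(nrow(eff))) {
    b <- design$beta[eff$gene[i], ]
    nz <- sum(b != 0)
    ok <- switch(eff$pattern[i],
      global = nz == length(b),
      unique = nz == 1L,
      multi = nz >= 2L && nz < length(b),
      sign_flip = any(b > 0) && any(b < 0),
      interaction_only = nz == 0L && any(design$beta_gd[eff$gene[i], ] != 0))
    assert_that(isTRUE(ok), "design invariant violated for gene %s (pattern %s)",
                eff$gene[i], eff$pattern[i])
  }
  invisible(design)
}

#' Simulate single-cell counts with planted effects
#'
#' Per cell, counts are negative binomial around
#' `exp(baseline + beta_c * dose + beta_d * disease + beta_gd * dose * disease + u)`,
#' where `u` is a per-gene donor random effect drawn from
#' `MVN(0, re_sd^2 * K)`. Some donors contribute fewer than 5 cells of a
#' type (or none), exercising the downstream inclusion filters.
#'
#' @param genotypes,kinship output of [simulate_genotypes()].
#' @param design a [plant_effects()] design (or `NULL` for a null cohort).
#' @param config the [sim_config()].
#' @return an object of class `scqtl_cells`: sparse counts (cells x genes),
#'   `cell_meta` (cell_id, donor, cell_type, disease, mito_frac),
#'   `donor_meta` (donor, disease), and the gene annotation.
#' @export
simulate_cells <- function(genotypes, kinship, design, config) {
  stopifnot(inherits(genotypes, "scqtl_genotypes"))
  ann <- genotypes$gene_annotation
  if (!is.null(design)) {
    stopifnot(inherits(design, "scqtl_design"))
    assert_that(all(design$effects$gene %in% ann$gene_id) &&
                  all(design$effects$variant %in% genotypes$variants$variant_id),
                "simulate_cells: design references genes/variants absent from the panel")
  }
  withr::with_seed(derive_seed(config$seed, 37L), {
    donors <- genotypes$donors
    n_d <- length(donors)
    n_dis <- round(config$frac_diseased * n_d)
    disease <- rep("control", n_d)
    disease[sample(n_d, n_dis)] <- "ILD"
    names(disease) <- donors
    d_ind <- as.numeric(disease == "ILD")

    R <- length(config$cell_types)
    ## cell layout
    meta_list <- list()
    for (t in seq_len(R)) {
      present <- runif(n_d) >= config$donor_dropout[t]
      ncell <- ifelse(present, rpois(n_d, config$cells_per_donor[t]), 0L)
      keep <- ncell > 0
      if (!any(keep)) next
      meta_list[[t]] <- data.frame(
        donor = rep(donors[keep], ncell[keep]),
        cell_type = config$cell_types[t], stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta_list)
    n_cells <- nrow(meta)
    meta$cell_id <- sprintf("%s_%s_c%06d", meta$donor, meta$cell_type, seq_len(n_cells))
    meta$disease <- disease[meta$donor]
    meta$mito_frac <- rbeta(n_cells, config$mito_beta[1], config$mito_beta[2])
    meta <- meta[, c("cell_id", "donor", "cell_type", "disease", "mito_frac")]

    baseline <- runif(nrow(ann), config$baseline_log_range[1], config$baseline_log_range[2])
    L <- t(chol(kinship + diag(1e-8, n_d)))
    size <- 1 / max(config$nb_dispersion, 1e-8)
    donor_idx <- match(meta$donor, donors)
    type_idx <- match(meta$cell_type, config$cell_types)

    counts <- matrix(0L, n_cells, nrow(ann))
    for (g in seq_len(nrow(ann))) {
      gid <- ann$gene_id[g]
      ## independent donor random effect per cell type, matching the
      ## per-cell-type mixed model fitted downstream
      u <- config$re_sd * (L %*% matrix(rnorm(n_d * R), n_d, R))
      eta <- baseline[g] + u[cbind(donor_idx, type_idx)]
      if (!is.null(design)) {
        i <- match(gid, design$effects$gene)
        if (!is.na(i)) {
          dose <- genotypes$dosage[, design$effects$variant[i]]
          bc <- design$beta[gid, type_idx]
          bgd <- design$beta_gd[gid, type_idx]
          bd <- design$disease_main[gid, type_idx]
          eta <- eta + bc * dose[donor_idx] +
            bd * d_ind[donor_idx] + bgd * dose[donor_idx] * d_ind[donor_idx]
        }
      }
      counts[, g] <- rnbinom(n_cells, size = size, mu = exp(eta))
    }
    dimnames(counts) <- list(meta$cell_id, ann$gene_id)
    out <- list(counts = Matrix::Matrix(counts, sparse = TRUE),
                cell_meta = meta,
                donor_meta = data.frame(donor = donors, disease = disease,
                                        stringsAsFactors = FALSE),
                gene_annotation = ann)
    class(out) <- "scqtl_cells"
    out
  })
}

#' Simulate GWAS summary statistics
#'
#' Draws a fresh panel of unrelated individuals from the same LD law as the
#' eQTL genotype panel, generates a quantitative trait driven by a chosen
#' causal variant, and reports per-variant marginal association statistics
#' for the causal variant's cis region.
#'
#' @param genotypes a `scqtl_genotypes` from [simulate_genotypes()].
#' @param causal_variant variant id anchoring the region; in `shared` mode it
#'   is also the trait's causal variant.
#' @param n_gwas GWAS sample size.
#' @param h2_snp trait variance explained by the causal variant.
#' @param mode `"shared"` (causal = `causal_variant`), `"distinct"` (causal
#'   is a variant in a different LD block of the same region) or `"null"`
#'   (no signal).
#' @param seed integer seed.
#' @return data.frame: variant, chrom, pos, ref, alt, beta, se, p, n,
#'   case_fraction (NA: quantitative trait), maf.
#' @export
simulate_gwas_stats <- function(genotypes, causal_variant, n_gwas = 5000,
                                h2_snp = 0.01, mode = c("shared", "distinct", "null"),
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(genotypes, "scqtl_genotypes"))
  si <- genotypes$sim_info
  assert_that(causal_variant %in% si$variant_id,
              "simulate_gwas_stats: unknown variant id %s", causal_variant)
  gene <- si$gene[si$variant_id == causal_variant]
  region <- si[si$gene == gene, , drop = FALSE]
  vmeta <- genotypes$variants[match(region$variant_id, genotypes$variants$variant_id), ]
  withr::with_seed(derive_seed(seed, 53L), {
    ## fresh unrelated panel under the same block-copying law
    blocks <- unique(region$block)
    dose <- matrix(0L, n_gwas, nrow(region))
    for (b in blocks) {
      idx <- which(region$block == b)
      maf <- region$true_maf[idx[1]]
      h <- sim_hap_block(length(idx), 2L * n_gwas, maf, genotypes$sim_ld_r)
      dose[, idx] <- t(h[, seq_len(n_gwas), drop = FALSE] +
                         h[, n_gwas + seq_len(n_gwas), drop = FALSE])
    }
    colnames(dose) <- region$variant_id

    causal <- switch(mode,
      shared = causal_variant,
      distinct = {
        other <- region$variant_id[region$block != region$block[region$variant_id == causal_variant]]
        assert_that(length(other) > 0, "simulate_gwas_stats: no distinct LD block available")
        other[ceiling(length(other) / 2)]
      },
      null = NA_character_)
    y <- rnorm(n_gwas)
    if (!is.na(causal)) {
      g <- dose[, causal]
      vg <- var(g)
      assert_that(vg > 0, "simulate_gwas_stats: causal variant is monomorphic in panel")
      b <- sqrt(h2_snp / vg)
      y <- b * g + rnorm(n_gwas, sd = sqrt(max(1 - h2_snp, 1e-6)))
    }
    ## marginal OLS per variant
    gc <- scale(dose, scale = FALSE)
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    sxx[sxx == 0] <- NA
    beta <- colSums(gc * yc) / sxx
    res_var <- (sum(yc^2) - beta^2 * sxx) / (n_gwas - 2)
    se <- sqrt(res_var / sxx)
    z <- beta / se
    data.frame(variant = region$variant_id, chrom = vmeta$chrom, pos = vmeta$pos,
               ref = vmeta$ref, alt = vmeta$alt,
               beta = beta, se = se, p = 2 * pnorm(-abs(z)),
               n = n_gwas, case_fraction = NA_real_,
               maf = pmin(colMeans(dose) / 2, 1 - colMeans(dose) / 2),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Write a simulated cohort to disk as standard plain-text formats
#'
#' Genotypes as VCFv4.2 (GT, one sample per donor), counts as MatrixMarket
#' (genes x cells) with `genes.tsv` and `cells.tsv`, gene annotation,
#' kinship, the truth design, and any GWAS tables.
#'
#' @param sim list with elements `genotypes`, `kinship`, `cells`, and
#'   optionally `design` and `gwas` (named list of GWAS data.frames).
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  G <- sim$genotypes
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             mtx = file.path(dir, "counts.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "cells.tsv"),
             kinship = file.path(dir, "kinship.tsv"))
  write_vcf(G, paths[["vcf"]])
  cells <- sim$cells
  Matrix::writeMM(Matrix::t(cells$counts), paths[["mtx"]])
  write_tsv(cells$gene_annotation, paths[["genes"]])
  write_tsv(cells$cell_meta, paths[["cells"]])
  K <- as.data.frame(sim$kinship)
  K <- cbind(donor = rownames(sim$kinship), K)
  write_tsv(K, paths[["kinship"]])
  if (!is.null(sim$design)) {
    paths[["truth"]] <- file.path(dir, "truth_design.tsv")
    eff <- sim$design$effects
    bt <- as.data.frame(sim$design$beta[eff$gene, , drop = FALSE])
    names(bt) <- paste0("beta_", names(bt))
    bg <- as.data.frame(sim$design$beta_gd[eff$gene, , drop = FALSE])
    names(bg) <- paste0("beta_gd_", names(bg))
    write_tsv(cbind(eff, bt, bg), paths[["truth"]])
  }
  for (nm in names(sim$gwas %||% list())) {
    p <- file.path(dir, sprintf("gwas_%s.tsv", nm))
    paths[[paste0("gwas_", nm)]] <- p
    write_tsv(sim$gwas[[nm]], p)
  }
  invisible(paths)
}

## VCFv4.2 writer: biallelic SNPs, GT field only, unphased.
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=scqtl-synthdata", con)
  for (ch in unique(G$variants$chrom))
    writeLines(sprintf("##contig=<ID=%s>", ch), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$donors), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  v <- G$variants
  ## order records by chromosome then position
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    dose <- round(G$dosage[, j])
    gt <- ifelse(is.na(dose), "./.", gt_code[dose + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper chaining [simulate_genotypes()], [plant_effects()]
#' and [simulate_cells()].
#'
#' @param config a [sim_config()].
#' @param n_per_pattern passed to [plant_effects()]; `NULL` for a null cohort.
#' @param beta,beta_gd,beta_disease passed to [plant_effects()].
#' @return list with `genotypes`, `kinship`, `design`, `cells`.
#' @export
simulate_cohort <- function(config, n_per_pattern = NULL, beta = 1, beta_gd = 1,
                            beta_disease = 0.3) {
  sg <- simulate_genotypes(config)
  design <- NULL
  if (!is.null(n_per_pattern) && sum(n_per_pattern) > 0)
    design <- plant_effects(sg$genotypes, config, n_per_pattern,
                            beta = beta, beta_gd = beta_gd,
                            beta_disease = beta_disease)
  cells <- simulate_cells(sg$genotypes, sg$kinship, design, config)
  list(genotypes = sg$genotypes, kinship = sg$kinship, design = design,
       cells = cells)
}
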