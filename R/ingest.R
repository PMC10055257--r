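## Genotype and single-cell count ingestion, QC filters matching the
## mapping protocol (mito fraction, gene expression filters, MAF/HWE/LD
## variant filters), normalization, and per-cell-type pseudo-bulk
## aggregation.

#' Construct a genotype matrix object
#'
#' @param dosage numeric donor x variant matrix with values in \[0, 2\]
#'   (alt-allele dosages; fractional dosages allowed).
#' @param variants data.frame with columns variant_id, chrom, pos, ref, alt.
#' @param donors character vector of donor ids (rows of `dosage`).
#' @return an object of class `scqtl_genotypes` with per-variant `maf` and
#'   Hardy-Weinberg exact-test p-values (`hwe_p`, computed from rounded
#'   genotype classes) annotated on `variants`.
#' @export
genotype_matrix <- function(dosage, variants, donors = rownames(dosage)) {
  assert_that(nrow(dosage) == length(donors), "genotype_matrix: donor mismatch")
  assert_that(ncol(dosage) == nrow(variants), "genotype_matrix: variant mismatch")
  assert_that(!anyDuplicated(variants$variant_id), "genotype_matrix: duplicate variant ids")
  assert_that(all(is.na(dosage) | (dosage >= 0 & dosage <= 2)),
              "genotype_matrix: dosages must lie in [0, 2]")
  rownames(dosage) <- donors
  colnames(dosage) <- variants$variant_id
  af <- colMeans(dosage, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  gt <- round(dosage)
  variants$hwe_p <- vapply(seq_len(ncol(gt)), function(j) {
    x <- gt[, j]; x <- x[!is.na(x)]
    hwe_exact_p(sum(x == 1), sum(x == 2), sum(x == 0))
  }, 0)
  out <- list(donors = donors, variants = variants, dosage = dosage)
  class(out) <- "scqtl_genotypes"
  out
}

#' Hardy-Weinberg exact test
#'
#' Exact test for deviation from Hardy-Weinberg proportions conditional on
#' the observed allele counts (sum over heterozygote configurations no more
#' probable than the observed one).
#'
#' @param n_het,n_hom_alt,n_hom_ref genotype class counts.
#' @param midp if `TRUE`, apply the mid-p correction (half weight on the
#'   observed configuration).
#' @return the exact p-value.
#' @export
hwe_exact_p <- function(n_het, n_hom_alt, n_hom_ref, midp = FALSE) {
  n <- n_het + n_hom_alt + n_hom_ref
  if (n == 0) return(1)
  n_a <- n_het + 2 * n_hom_alt   # minor-ish allele count; fold below
  if (n_a > n) n_a <- 2 * n - n_a
  ## possible heterozygote counts share parity with n_a
  hets <- seq(n_a %% 2, n_a, by = 2)
  ## log P(n_het = h | allele count) via lgamma
  logp <- vapply(hets, function(h) {
    homr <- (n_a - h) / 2          # rare-allele homozygotes
    homc <- n - h - homr
    h * log(2) + lgamma(n + 1) - lgamma(h + 1) - lgamma(homr + 1) -
      lgamma(homc + 1) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - logsumexp(logp))
  obs_het <- if (n_het + 2 * n_hom_alt <= n) n_het else n_het  # het count invariant to folding
  i <- match(obs_het, hets)
  if (is.na(i)) return(0)  # impossible configuration given alleles
  sel <- p <= p[i] * (1 + 1e-12)
  out <- sum(p[sel])
  if (midp) out <- out - 0.5 * p[i]
  min(max(out, 0), 1)
}

#' Read donor genotypes
#'
#' Reads a VCF (GT genotypes, one sample per donor) or a dosage TSV
#' (columns variant_id, chrom, pos, ref, alt, then one column per donor).
#' Multi-allelic VCF records are skipped with a warning; missing genotypes
#' are imputed to the per-variant mean dosage (with a message).
#'
#' @param path file path; format chosen by extension (`.vcf` vs `.tsv`).
#' @return a `scqtl_genotypes` object (see [genotype_matrix()]).
#' @export
read_genotypes <- function(path) {
  assert_that(file.exists(path), "read_genotypes: no such file %s", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi))
      warning(sprintf("read_genotypes: skipped %d multi-allelic record(s)", sum(multi)))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    assert_that(ncol(gt) > 0, "read_genotypes: zero donors in VCF")
    dose <- matrix(NA_real_, nrow(gt), ncol(gt))
    known <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
               "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
    dose[] <- known[gt]
    variants <- data.frame(variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                               paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = "_"),
                                               fix$ID),
                           chrom = fix$CHROM, pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
    dose <- t(dose)   # donors x variants
    rownames(dose) <- colnames(gt)
  } else {
    tab <- read_tsv(path)
    meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
    assert_that(all(meta_cols %in% names(tab)),
                "read_genotypes: dosage TSV must have columns %s", paste(meta_cols, collapse = ", "))
    variants <- tab[, meta_cols]
    dose <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
    assert_that(nrow(dose) > 0, "read_genotypes: zero donors in dosage table")
  }
  n_miss <- sum(is.na(dose))
  if (n_miss > 0) {
    message(sprintf("read_genotypes: imputed %d missing genotype(s) to per-variant mean dosage", n_miss))
    for (j in which(colSums(is.na(dose)) > 0)) {
      m <- mean(dose[, j], na.rm = TRUE)
      dose[is.na(dose[, j]), j] <- if (is.finite(m)) m else 0
    }
  }
  genotype_matrix(dose, variants, rownames(dose))
}

#' Filter variants by MAF, Hardy-Weinberg and LD pruning
#'
#' Retains variants with minor allele frequency strictly above `maf_min`
#' and Hardy-Weinberg exact p strictly above `hwe_p_min`, then greedily
#' prunes one of each highly correlated pair (r-squared > `ld_r2`) within
#' sliding windows of `ld_window` variants advanced by `ld_step` (the
#' variant-count dialect of plink's `--indep-pairwise`). Of a correlated
#' pair, the variant with the lower MAF is removed (ties: the later one).
#'
#' @param G a `scqtl_genotypes`.
#' @param maf_min,hwe_p_min,ld_window,ld_step,ld_r2 filter parameters.
#' @return the filtered `scqtl_genotypes` (possibly empty, with a warning).
#' @export
filter_variants <- function(G, maf_min = 0.05, hwe_p_min = 1e-6,
                            ld_window = 250, ld_step = 50, ld_r2 = 0.9) {
  stopifnot(inherits(G, "scqtl_genotypes"))
  assert_that(nrow(G$variants) > 0, "filter_variants: empty genotype set")
  keep <- G$variants$maf > maf_min & G$variants$hwe_p > hwe_p_min
  v <- G$variants[keep, , drop = FALSE]
  X <- G$dosage[, keep, drop = FALSE]
  ## LD pruning per chromosome, windows in variant counts along position order
  pruned <- logical(nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    start <- 1
    while (start <= length(idx)) {
      win <- idx[start:min(start + ld_window - 1, length(idx))]
      win <- win[!pruned[win]]
      if (length(win) > 1) {
        r2 <- suppressWarnings(cor(X[, win, drop = FALSE]))^2
        for (a in seq_len(length(win) - 1)) {
          if (pruned[win[a]]) next
          for (b in (a + 1):length(win)) {
            if (pruned[win[b]]) next
            if (is.finite(r2[a, b]) && r2[a, b] > ld_r2) {
              drop <- if (v$maf[win[a]] < v$maf[win[b]]) win[a] else win[b]
              pruned[drop] <- TRUE
              if (drop == win[a]) break
            }
          }
        }
      }
      if (start + ld_window - 1 >= length(idx)) break
      start <- start + ld_step
    }
  }
  v <- v[!pruned, , drop = FALSE]
  X <- X[, !pruned, drop = FALSE]
  if (nrow(v) == 0) warning("filter_variants: no variants pass filters")
  out <- G
  out$variants <- v
  out$dosage <- X
  if (!is.null(out$sim_info))
    out$sim_info <- out$sim_info[match(v$variant_id, out$sim_info$variant_id), , drop = FALSE]
  out
}

#' Read cell-level counts written by [write_fixtures()]
#'
#' @param mtx MatrixMarket file (genes x cells).
#' @param cells_tsv per-cell metadata (cell_id, donor, cell_type, disease,
#'   mito_frac).
#' @param genes_tsv gene annotation (gene_id, chrom, start, end, tss, strand).
#' @return a `scqtl_cells` object (cells x genes sparse counts).
#' @export
read_cell_counts <- function(mtx, cells_tsv, genes_tsv) {
  m <- Matrix::readMM(mtx)
  cells <- read_tsv(cells_tsv)
  genes <- read_tsv(genes_tsv)
  assert_that(nrow(m) == nrow(genes) && ncol(m) == nrow(cells),
              "read_cell_counts: matrix dims (%d x %d) do not match metadata", nrow(m), ncol(m))
  counts <- Matrix::t(m)
  dimnames(counts) <- list(cells$cell_id, genes$gene_id)
  donor_meta <- unique(cells[, c("donor", "disease")])
  donor_meta <- donor_meta[order(donor_meta$donor), ]
  rownames(donor_meta) <- NULL
  out <- list(counts = methods::as(counts, "CsparseMatrix"), cell_meta = cells,
              donor_meta = donor_meta, gene_annotation = genes)
  class(out) <- "scqtl_cells"
  out
}

#' Remove cells with high mitochondrial read fraction
#'
#' Cells with a mitochondrial fraction strictly above `mito_max` are
#' removed; everything else is untouched.
#'
#' @param cells a `scqtl_cells`.
#' @param mito_max maximum tolerated mitochondrial read fraction.
#' @return the filtered `scqtl_cells`.
#' @export
qc_cells <- function(cells, mito_max = 0.20) {
  stopifnot(inherits(cells, "scqtl_cells"))
  assert_that("mito_frac" %in% names(cells$cell_meta) &&
                !anyNA(cells$cell_meta$mito_frac),
              "qc_cells: mito_frac missing from cell metadata")
  keep <- cells$cell_meta$mito_frac <= mito_max
  cells$counts <- cells$counts[keep, , drop = FALSE]
  cells$cell_meta <- cells$cell_meta[keep, , drop = FALSE]
  rownames(cells$cell_meta) <- NULL
  cells
}

#' Select genes passing expression filters
#'
#' Retains genes expressed (count > 0) in at least `min_cell_frac` of all
#' post-QC cells, with mean count across all cells at least
#' `min_mean_count`, and not on any exclusion list (e.g. mitochondrial and
#' ribosomal-protein gene symbols).
#'
#' @param cells a post-QC `scqtl_cells`.
#' @param min_cell_frac minimum fraction of cells expressing the gene.
#' @param min_mean_count minimum mean count across all cells.
#' @param exclude_lists character vector of gene ids, or paths to
#'   single-column TSV files of gene ids, to exclude.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(cells, min_cell_frac = 0.10, min_mean_count = 0.1,
                         exclude_lists = NULL) {
  stopifnot(inherits(cells, "scqtl_cells"))
  excl <- character()
  for (x in exclude_lists) {
    if (length(x) == 1 && file.exists(x)) {
      v <- readLines(x)
      v <- v[nzchar(v)]
      excl <- c(excl, v)
    } else excl <- c(excl, x)
  }
  n <- nrow(cells$counts)
  frac_expr <- Matrix::colSums(cells$counts > 0) / n
  mean_count <- Matrix::colSums(cells$counts) / n
  keep <- frac_expr >= min_cell_frac & mean_count >= min_mean_count &
    !(colnames(cells$counts) %in% excl)
  colnames(cells$counts)[keep]
}

#' Normalize and log-transform counts
#'
#' Per-cell size factors are library sizes scaled by their geometric mean;
#' when at least `pool_min_cells` cells are available they are refined by a
#' pool-and-deconvolve step over donor-level pools (a robust median-ratio
#' estimate of each donor pool's total scale, redistributed over the pool's
#' cells in proportion to library size). Size factors are rescaled to mean
#' one and expression is `log2(count / sf + 1)`.
#'
#' @param cells a post-QC `scqtl_cells`.
#' @param genes gene ids to keep (e.g. from [filter_genes()]); `NULL` keeps all.
#' @param pool_min_cells minimum number of cells before the deconvolution
#'   refinement is applied (below it, plain library-size factors are used).
#' @return list with `norm` (dense cells x genes matrix of log2 normalized
#'   expression), `size_factors`, and the retained `cell_meta`.
#' @export
normalize_log <- function(cells, genes = NULL, pool_min_cells = 100) {
  stopifnot(inherits(cells, "scqtl_cells"))
  counts <- cells$counts
  if (!is.null(genes)) counts <- counts[, genes, drop = FALSE]
  lib <- Matrix::rowSums(counts)
  if (any(lib == 0)) {
    warning(sprintf("normalize_log: dropped %d cell(s) with zero library size", sum(lib == 0)))
    keep <- lib > 0
    counts <- counts[keep, , drop = FALSE]
    cells$cell_meta <- cells$cell_meta[keep, , drop = FALSE]
    lib <- lib[keep]
  }
  sf <- lib / geometric_mean(lib)
  if (nrow(counts) >= pool_min_cells) {
    ## donor-level pool-and-deconvolve refinement: the median ratio of the
    ## donor's pooled profile to the all-cell reference estimates the pool's
    ## average cell scale; the pool total is deconvolved onto cells
    ## proportionally to their library-size factors.
    ref <- Matrix::colMeans(counts)
    use <- ref > 0
    donor <- cells$cell_meta$donor
    for (d in unique(donor)) {
      idx <- which(donor == d)
      pooled <- Matrix::colSums(counts[idx, , drop = FALSE])
      theta <- stats::median(pooled[use] / (length(idx) * ref[use]))
      if (is.finite(theta) && theta > 0)
        sf[idx] <- sf[idx] * (theta * length(idx) / sum(sf[idx]))
    }
  }
  sf <- sf / mean(sf)
  norm <- log2(as.matrix(counts) / sf + 1)
  list(norm = norm, size_factors = sf, cell_meta = cells$cell_meta)
}

#' Aggregate normalized expression into per-cell-type pseudo-bulk
#'
#' Per (cell type, donor, gene): the arithmetic mean of normalized values
#' over that donor's cells of that type. Donor-type combinations with fewer
#' than `min_cells` cells are dropped, and cell types with fewer than
#' `min_donors` qualifying donors are dropped entirely.
#'
#' @param norm cells x genes matrix of normalized expression.
#' @param cell_meta per-cell metadata aligned with `norm` rows.
#' @param min_cells minimum cells per donor per cell type.
#' @param min_donors minimum qualifying donors per cell type.
#' @return an object of class `scqtl_pseudobulk`: per retained cell type a
#'   list with `expr` (donor x gene), `ncells` (named), `disease` (named).
#' @export
pseudobulk_aggregate <- function(norm, cell_meta, min_cells = 5, min_donors = 40) {
  assert_that(nrow(norm) == nrow(cell_meta), "pseudobulk_aggregate: metadata misaligned")
  out <- list()
  dropped <- character()
  for (ct in sort(unique(cell_meta$cell_type))) {
    idx <- which(cell_meta$cell_type == ct)
    donor <- cell_meta$donor[idx]
    tab <- table(donor)
    qual <- names(tab)[tab >= min_cells]
    if (length(qual) < min_donors) {
      dropped <- c(dropped, sprintf("%s (%d qualifying donors)", ct, length(qual)))
      next
    }
    keep <- idx[donor %in% qual]
    grp <- factor(cell_meta$donor[keep], levels = sort(qual))
    sums <- rowsum(norm[keep, , drop = FALSE], grp)
    ncells <- as.integer(table(grp))
    expr <- sums / ncells
    names(ncells) <- levels(grp)
    dis <- cell_meta$disease[keep][match(levels(grp), cell_meta$donor[keep])]
    names(dis) <- levels(grp)
    out[[ct]] <- list(expr = expr, ncells = ncells, disease = dis)
  }
  if (length(out) == 0)
    stop("pseudobulk_aggregate: no cell type survives the donor threshold; dropped: ",
         paste(dropped, collapse = "; "))
  class(out) <- "scqtl_pseudobulk"
  attr(out, "dropped") <- dropped
  out
}

#' Read gene annotation TSV
#' @param path TSV with columns gene_id, chrom, start, end, tss, strand.
#' @return data.frame.
#' @export
read_gene_annotation <- function(path) {
  ann <- read_tsv(path)
  need <- c("gene_id", "chrom", "tss", "strand")
  assert_that(all(need %in% names(ann)),
              "read_gene_annotation: required columns %s", paste(need, collapse = ", "))
  if (is.null(ann$start)) ann$start <- ann$tss
  if (is.null(ann$end)) ann$end <- ann$tss
  ann
}
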