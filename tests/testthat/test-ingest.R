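# Ingest and QC: genotype encodings, MAF/HWE/LD variant filters, cell and
# gene filters, normalization, pseudo-bulk aggregation, and the module's
# idempotence/conservation/order-invariance properties.

write_mini_vcf <- function(path, records, donors = c("D1", "D2", "D3")) {
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", donors), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

test_that("GT parsing: het dosage, mean imputation of missing, multi-allelic skip", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, c(
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
    "chr1\t200\tv2\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.\t1/1",
    "chr1\t300\tv3\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"))
  expect_warning(G <- read_genotypes(f), "multi-allelic")
  expect_identical(nrow(G$variants), 2L)           # triallelic absent
  expect_equal(unname(G$dosage[, "v1"]), c(1, 0, 2))
  ## missing imputed to the mean of observed dosages (1 + 2)/2
  expect_equal(unname(G$dosage["D2", "v2"]), 1.5)
  expect_error(read_genotypes(file.path(tempdir(), "absent.vcf")), "no such file")
})

test_that("Hardy-Weinberg exact test matches an independent enumeration oracle", {
  ## oracle: enumerate heterozygote counts with direct choose() arithmetic
  hwe_oracle <- function(het, hom_a, hom_r) {
    n <- het + hom_a + hom_r
    na <- het + 2 * min(hom_a, hom_r)
    if (het + 2 * hom_a > n) { t <- hom_a; hom_a <- hom_r; hom_r <- t }
    hets <- seq(na %% 2, na, 2)
    pr <- vapply(hets, function(h) {
      ha <- (na - h) / 2; hr <- n - h - ha
      exp(h * log(2) + lchoose(n, h) + lchoose(n - h, ha))
    }, 0)
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(het, hets)] * (1 + 1e-12)])
  }
  cases <- list(c(25, 10, 65), c(4, 1, 95), c(50, 25, 25), c(0, 50, 50))
  for (cs in cases)
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  ## extreme heterozygote deficit: AA=50, Aa=0, aa=50
  expect_lt(hwe_exact_p(0, 50, 50), 1e-6)
  expect_identical(hwe_exact_p(0, 0, 0), 1)
})

test_that("variant filters apply strict MAF/HWE bounds and r2 pruning", {
  n <- 100
  mk <- function(n_het, n_alt) c(rep(1, n_het), rep(2, n_alt), rep(0, n - n_het - n_alt))
  dose <- cbind(maf05 = mk(10, 0),      # MAF exactly 0.05 -> removed
                maf06 = mk(12, 0),      # MAF 0.06 -> kept
                hwe_bad = mk(0, 50),    # all-hom split -> HWE p < 1e-6
                keep1 = mk(40, 10))
  dose <- cbind(dose, dup = dose[, "keep1"])   # identical variant, r2 = 1
  variants <- data.frame(variant_id = colnames(dose), chrom = "chr1",
                         pos = c(100, 200, 300, 400, 500),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  G <- genotype_matrix(dose, variants, sprintf("D%03d", 1:n))
  Gf <- filter_variants(G, maf_min = 0.05, hwe_p_min = 1e-6, ld_r2 = 0.9)
  expect_false("maf05" %in% Gf$variants$variant_id)
  expect_true("maf06" %in% Gf$variants$variant_id)
  expect_false("hwe_bad" %in% Gf$variants$variant_id)
  ## exactly one of the identical pair survives
  expect_identical(sum(c("keep1", "dup") %in% Gf$variants$variant_id), 1L)
  ## filter idempotence
  Gf2 <- filter_variants(Gf)
  expect_identical(Gf$variants$variant_id, Gf2$variants$variant_id)
})

test_that("cell QC removes > 20% mito cells and keeps the boundary", {
  counts <- matrix(1:12, 4, 3)
  cells <- make_cells(counts, donor = rep("D1", 4), cell_type = "A",
                      disease = "control", mito = c(0.05, 0.20, 0.21, 0.5))
  out <- qc_cells(cells, mito_max = 0.20)
  expect_identical(nrow(out$counts), 2L)
  expect_true(all(out$cell_meta$mito_frac <= 0.20))
  ## idempotent; empty in -> empty out
  expect_identical(nrow(qc_cells(out)$counts), 2L)
  empty <- make_cells(counts[0, , drop = FALSE], character(), character(),
                      character(), numeric())
  expect_identical(nrow(qc_cells(empty)$counts), 0L)
  cells$cell_meta$mito_frac[1] <- NA
  expect_error(qc_cells(cells), "mito_frac")
})

test_that("gene filters: expressed fraction, mean count, exclusion lists", {
  n <- 1000
  counts <- cbind(
    sparse99 = c(rep(1, 99), rep(0, n - 99)),       # 9.9% of cells -> removed
    frac10 = c(rep(1, 100), rep(0, n - 100)),       # exactly 10%, mean 0.1 -> kept
    ribo = rep(1, n),
    highmean = rep(2, n))
  cells <- make_cells(counts, donor = rep("D1", n), cell_type = "A",
                      disease = "control", mito = rep(0.01, n))
  ribo_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ribo", ribo_file)
  keep <- filter_genes(cells, min_cell_frac = 0.10, min_mean_count = 0.1,
                       exclude_lists = list(ribo_file))
  expect_false("sparse99" %in% keep)
  expect_true("frac10" %in% keep)          # boundary: exactly 10% and mean 0.1
  expect_false("ribo" %in% keep)
  expect_true("highmean" %in% keep)
})

test_that("normalization: symmetric case, scale invariance, hand-computed toy", {
  counts <- matrix(c(2, 4, 8,
                     2, 4, 8,
                     2, 4, 8), 3, 3, byrow = TRUE)
  cells <- make_cells(counts, donor = rep("D1", 3), cell_type = "A",
                      disease = "control", mito = rep(0, 3))
  nl <- normalize_log(cells)
  expect_equal(nl$size_factors, rep(1, 3), ignore_attr = TRUE)
  expect_equal(nl$norm, log2(counts + 1), ignore_attr = TRUE)

  ## doubling one cell's counts doubles its size factor relative to the
  ## others; count/size-factor ratios are invariant up to the one global
  ## mean-1 rescale of the factors
  counts2 <- counts
  counts2[2, ] <- counts2[2, ] * 2
  nl2 <- normalize_log(make_cells(counts2, donor = rep("D1", 3), cell_type = "A",
                                  disease = "control", mito = rep(0, 3)))
  expect_equal(nl2$size_factors[2] / nl2$size_factors[1],
               2 * nl$size_factors[2] / nl$size_factors[1], tolerance = 1e-12)
  ratio <- (counts2 / nl2$size_factors) / (counts / nl$size_factors)
  expect_lt(diff(range(ratio)), 1e-12)

  ## 3-cell toy against hand computation of lib-size factors
  cts <- matrix(c(1, 1,
                  2, 2,
                  4, 4), 3, 2, byrow = TRUE)
  lib <- rowSums(cts)
  sf <- lib / exp(mean(log(lib)))
  sf <- sf / mean(sf)
  nl3 <- normalize_log(make_cells(cts, donor = rep("D1", 3), cell_type = "A",
                                  disease = "control", mito = rep(0, 3)))
  expect_equal(nl3$norm, log2(cts / sf + 1), ignore_attr = TRUE)
  ## zero-library cell dropped with a warning
  cts0 <- rbind(cts, 0)
  expect_warning(
    nl0 <- normalize_log(make_cells(cts0, donor = rep("D1", 4), cell_type = "A",
                                    disease = "control", mito = rep(0, 4))),
    "zero library")
  expect_identical(nrow(nl0$norm), 3L)
})

test_that("pseudo-bulk aggregation: means, inclusion rules, conservation, order", {
  ## donor D1 has 2 cells (values 2 and 4 -> mean 3) but <5 cells: excluded;
  ## D2..D6 have 5 cells each
  donor <- c(rep("D1", 2), rep(paste0("D", 2:6), each = 5))
  norm <- matrix(0, length(donor), 2, dimnames = list(NULL, c("g1", "g2")))
  norm[1:2, 1] <- c(2, 4)
  norm[donor == "D2", 1] <- c(2, 4, 6, 8, 10)   # mean 6
  meta <- data.frame(cell_id = sprintf("c%02d", seq_along(donor)), donor = donor,
                     cell_type = "A", disease = "control",
                     mito_frac = 0, stringsAsFactors = FALSE)
  pb <- pseudobulk_aggregate(norm, meta, min_cells = 5, min_donors = 5)
  expect_false("D1" %in% rownames(pb$A$expr))
  expect_equal(pb$A$expr["D2", "g1"], 6)
  expect_equal(sum(pb$A$ncells), sum(donor != "D1"))

  ## a donor with exactly 2 cells and mean (2, 4) -> 3 when min_cells = 2
  pb2 <- pseudobulk_aggregate(norm, meta, min_cells = 2, min_donors = 5)
  expect_equal(pb2$A$expr["D1", "g1"], 3)

  ## 4-donor cell type dropped under a 5-donor rule (duplicate the cells
  ## into a second, thinner cell type)
  norm_b <- rbind(norm, norm[donor %in% c("D2", "D3", "D4", "D5"), ])
  meta_b <- rbind(meta, transform(meta[meta$donor %in% c("D2", "D3", "D4", "D5"), ],
                                  cell_type = "B"))
  pb3 <- pseudobulk_aggregate(norm_b, meta_b, min_cells = 5, min_donors = 5)
  expect_false("B" %in% names(pb3))
  expect_true("A" %in% names(pb3))
  expect_error(pseudobulk_aggregate(norm, meta, min_cells = 5, min_donors = 10),
               "no cell type survives")

  ## order invariance
  perm <- sample(nrow(norm))
  pb_p <- pseudobulk_aggregate(norm[perm, , drop = FALSE], meta[perm, ],
                               min_cells = 5, min_donors = 5)
  expect_equal(pb_p$A$expr, pb$A$expr)
  expect_equal(pb_p$A$ncells, pb$A$ncells)
})
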