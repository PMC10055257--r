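# Shared fixtures, memoized so expensive simulations run once per session.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_env[[name]])) assign(name, builder(), envir = .fx_env)
  .fx_env[[name]]
}

# mid-sized cohort with planted effects, reused across modules
fx_cohort <- function() fx("cohort", function() {
  cfg <- sim_config(n_donors = 60, n_genes = 24, snps_per_gene = 10,
                    cell_types = paste0("CT", 1:3),
                    cells_per_donor = c(40, 25, 10),
                    donor_dropout = c(0, 0.05, 0.2),
                    seed = 101)
  sim <- simulate_cohort(cfg, n_per_pattern = c(global = 2, multi = 2,
                                                unique = 2, sign_flip = 2,
                                                interaction_only = 2))
  sim$config <- cfg
  sim
})

# pseudobulk + filtered genotypes derived from fx_cohort
fx_pipe <- function() fx("pipe", function() {
  sim <- fx_cohort()
  cells <- qc_cells(sim$cells)
  genes <- filter_genes(cells, min_cell_frac = 0.05, min_mean_count = 0.05)
  nl <- normalize_log(cells, genes)
  pb <- pseudobulk_aggregate(nl$norm, nl$cell_meta, min_cells = 5, min_donors = 20)
  Gf <- filter_variants(sim$genotypes)
  list(sim = sim, cells = cells, pb = pb, Gf = Gf,
       kinship = compute_kinship(Gf), ann = sim$cells$gene_annotation)
})

# build a scqtl_posterior object directly (for rule-logic tests)
make_posterior <- function(post_mean, lfsr, genes, variants,
                           post_sd = NULL) {
  ids <- paste(genes, variants, sep = ":")
  if (is.null(colnames(lfsr))) colnames(lfsr) <- paste0("CT", seq_len(ncol(lfsr)))
  colnames(post_mean) <- colnames(lfsr)
  rownames(post_mean) <- rownames(lfsr) <- ids
  if (is.null(post_sd)) post_sd <- post_mean * 0 + 1
  out <- list(post_mean = post_mean, post_sd = post_sd, lfsr = lfsr,
              map = data.frame(id = ids, gene = genes, variant = variants,
                               stringsAsFactors = FALSE),
              conditions = colnames(post_mean))
  class(out) <- "scqtl_posterior"
  out
}

# build a scqtl_top object directly
make_top <- function(genes, variants, beta, lfsr, mask) {
  n_sig <- rowSums(mask)
  cls <- if (ncol(mask) >= 3) classify_specificity(pmax(n_sig, 1), ncol(mask))
         else rep("multi", length(genes))
  tab <- data.frame(gene = genes, variant = variants,
                    id = paste(genes, variants, sep = ":"),
                    n_sig = as.integer(n_sig),
                    class = cls,
                    top_in = 1L, stringsAsFactors = FALSE)
  out <- list(table = tab, beta = beta, lfsr = lfsr, mask = mask)
  class(out) <- "scqtl_top"
  out
}

# tiny in-memory cells object for filter unit tests
make_cells <- function(counts, donor, cell_type, disease, mito) {
  meta <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(counts))),
                     donor = donor, cell_type = cell_type,
                     disease = disease, mito_frac = mito,
                     stringsAsFactors = FALSE)
  rownames(counts) <- meta$cell_id
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%04d", seq_len(ncol(counts)))
  dm <- unique(meta[, c("donor", "disease")])
  out <- list(counts = Matrix::Matrix(counts, sparse = TRUE),
              cell_meta = meta,
              donor_meta = dm,
              gene_annotation = data.frame(gene_id = colnames(counts)))
  class(out) <- "scqtl_cells"
  out
}
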