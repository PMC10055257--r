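## End-to-end orchestration: one validated config drives ingest, both
## association scans, joint shrinkage, classification, colocalization and
## enrichment, with per-stage artifacts, a manifest, and full determinism
## given (config, inputs, seed).

pipeline_defaults <- function() {
  list(
    inputs = list(vcf = NULL, mtx = NULL, cells = NULL, genes = NULL,
                  gwas = list(), exclude_gene_lists = list()),
    stages = list(additive = TRUE, interaction = TRUE, mash = TRUE,
                  classify = TRUE, coloc = TRUE, enrich = TRUE, de = TRUE),
    qc = list(mito_max = 0.20, min_cell_frac = 0.10, min_mean_count = 0.1,
              maf_min = 0.05, hwe_p_min = 1e-6,
              ld_window = 250, ld_step = 50, ld_r2 = 0.9),
    pseudobulk = list(min_cells = 5, min_donors = 40, pool_min_cells = 100),
    mapping = list(window = 1e6, n_pcs = 20,
                   interaction_min_group_donors = 10, group_maf_min = 0.05),
    mash = list(strong_lfsr = 0.1, n_pcs = 5, ed_iters = 50,
                subset_size = 10000),
    classify = list(primary = 0.05, secondary = 0.1, buffer = 2,
                    share_factor = 0.5, prune_dist = 0.2),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, min_shared = 100,
                 pp4_threshold = 0.6),
    enrich = list(gwas_p = 1e-6, null_size = NULL),
    de = list(adj_threshold = 0.1),
    seed = 2023)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults for every missing
#' field, rejects unknown keys, and checks ranges and units (the cis
#' window is in bp).
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return the normalized config list (class `scqtl_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    assert_that(file.exists(config), "validate_config: no such file %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  def <- pipeline_defaults()
  merge_lists <- function(d, u, path = "") {
    unknown <- setdiff(names(u), names(d))
    assert_that(length(unknown) == 0, "validate_config: unknown key(s): %s",
                paste0(path, unknown, collapse = ", "))
    for (k in names(u)) {
      if (is.list(d[[k]]) && !k %in% c("gwas", "exclude_gene_lists")) {
        d[[k]] <- merge_lists(d[[k]], u[[k]] %||% list(), paste0(path, k, "."))
      } else d[k] <- list(u[[k]])   # keeps explicit NULLs
    }
    d
  }
  cfg <- merge_lists(def, config)
  num_fields <- list(c("qc", "mito_max"), c("qc", "min_cell_frac"),
                     c("qc", "maf_min"), c("classify", "primary"),
                     c("classify", "secondary"), c("classify", "share_factor"))
  for (f in num_fields) {
    v <- as.numeric(cfg[[f[1]]][[f[2]]])
    assert_that(is.finite(v) && v >= 0 && v <= 1,
                "validate_config: %s.%s out of [0,1]", f[1], f[2])
    cfg[[f[1]]][[f[2]]] <- v
  }
  cfg$mapping$window <- as.numeric(cfg$mapping$window)
  assert_that(is.finite(cfg$mapping$window) && cfg$mapping$window > 0,
              "validate_config: mapping.window must be a positive bp count")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "scqtl_config"
  cfg
}

pipeline_log <- function(con, stage, msg, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(msg, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

## serialize a posterior set as three TSVs keyed by gene/variant
write_posterior <- function(post, dir, prefix) {
  for (nm in c("post_mean", "post_sd", "lfsr")) {
    df <- data.frame(gene = post$map$gene, variant = post$map$variant,
                     as.data.frame(post[[nm]]), check.names = FALSE)
    write_tsv(df, file.path(dir, sprintf("%s_%s.tsv", prefix, nm)))
  }
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing one TSV per artifact into
#' `out_dir` plus a `manifest.json` recording inputs, parameters, seed,
#' per-stage row counts and artifact checksums. Reruns with identical
#' config and inputs reproduce identical artifacts.
#'
#' @param config a [validate_config()] result, config list, or YAML path.
#' @param out_dir run directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "scqtl_config")) config else validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), "w")
  on.exit(close(logcon))
  manifest <- list(parameters = unclass(cfg), seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("scqtl")),
                   counts = list(), artifacts = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  }
  fail_stage <- function(stage, e) {
    manifest$status <<- sprintf("failed at %s: %s", stage, conditionMessage(e))
    write_manifest()
    stop(sprintf("run_pipeline: stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  ## ---- ingest ----
  tryCatch({
    inp <- cfg$inputs
    for (f in c("vcf", "mtx", "cells", "genes"))
      assert_that(!is.null(inp[[f]]) && file.exists(inp[[f]]),
                  "run_pipeline: missing input '%s'", f)
    G <- read_genotypes(inp$vcf)
    Gf <- filter_variants(G, maf_min = cfg$qc$maf_min, hwe_p_min = cfg$qc$hwe_p_min,
                          ld_window = cfg$qc$ld_window, ld_step = cfg$qc$ld_step,
                          ld_r2 = cfg$qc$ld_r2)
    kinship <- compute_kinship(Gf)
    ann <- read_gene_annotation(inp$genes)
    cells <- read_cell_counts(inp$mtx, inp$cells, inp$genes)
    cells <- qc_cells(cells, mito_max = cfg$qc$mito_max)
    genes_keep <- filter_genes(cells, min_cell_frac = cfg$qc$min_cell_frac,
                               min_mean_count = cfg$qc$min_mean_count,
                               exclude_lists = inp$exclude_gene_lists)
    nl <- normalize_log(cells, genes = genes_keep,
                        pool_min_cells = cfg$pseudobulk$pool_min_cells)
    pb <- pseudobulk_aggregate(nl$norm, nl$cell_meta,
                               min_cells = cfg$pseudobulk$min_cells,
                               min_donors = cfg$pseudobulk$min_donors)
    manifest$counts$variants_raw <- nrow(G$variants)
    manifest$counts$variants_filtered <- nrow(Gf$variants)
    manifest$counts$cells_post_qc <- nrow(cells$counts)
    manifest$counts$genes_tested <- length(genes_keep)
    manifest$counts$cell_types <- length(pb)
    pipeline_log(logcon, "ingest",
                 "%d variants (%d post-filter), %d cells, %d genes, %d cell types",
                 nrow(G$variants), nrow(Gf$variants), nrow(cells$counts),
                 length(genes_keep), length(pb))
  }, error = function(e) fail_stage("ingest", e))

  assoc_add <- NULL; assoc_int <- NULL
  if (isTRUE(cfg$stages$additive)) tryCatch({
    assoc_add <- scan_cis_additive(pb, Gf, ann, kinship,
                                   window = cfg$mapping$window,
                                   n_pcs = cfg$mapping$n_pcs)
    write_tsv(assoc_add, file.path(out_dir, "assoc_additive.tsv"))
    manifest$counts$assoc_additive <- nrow(assoc_add)
    pipeline_log(logcon, "additive", "%d association tests", nrow(assoc_add))
  }, error = function(e) fail_stage("additive", e))

  if (isTRUE(cfg$stages$interaction)) tryCatch({
    assoc_int <- scan_cis_interaction(pb, Gf, ann, kinship,
                                      window = cfg$mapping$window,
                                      n_pcs = cfg$mapping$n_pcs,
                                      group_maf_min = cfg$mapping$group_maf_min,
                                      min_group_donors = cfg$mapping$interaction_min_group_donors)
    if (!is.null(assoc_int)) {
      write_tsv(assoc_int, file.path(out_dir, "assoc_interaction.tsv"))
      manifest$counts$assoc_interaction <- nrow(assoc_int)
      pipeline_log(logcon, "interaction", "%d interaction tests", nrow(assoc_int))
    } else pipeline_log(logcon, "interaction", "no cell type met the donor rule")
  }, error = function(e) fail_stage("interaction", e))

  post_add <- NULL; post_int <- NULL
  if (isTRUE(cfg$stages$mash) && !is.null(assoc_add)) tryCatch({
    m <- run_mash(assoc_add, strong_lfsr = cfg$mash$strong_lfsr,
                  n_pcs = cfg$mash$n_pcs, ed_iters = cfg$mash$ed_iters,
                  subset_size = cfg$mash$subset_size,
                  seed = derive_seed(cfg$seed, 101L))
    post_add <- m$posterior
    write_posterior(post_add, out_dir, "mash_additive")
    saveRDS_free_model(m$model, file.path(out_dir, "mash_additive_model.json"))
    manifest$counts$mash_additive_strong <- length(m$strong)
    pipeline_log(logcon, "mash", "additive: %d associations, %d strong",
                 nrow(post_add$lfsr), length(m$strong))
    if (!is.null(assoc_int)) {
      mi <- run_mash(assoc_int, strong_lfsr = cfg$mash$strong_lfsr,
                     n_pcs = cfg$mash$n_pcs, ed_iters = cfg$mash$ed_iters,
                     subset_size = cfg$mash$subset_size,
                     seed = derive_seed(cfg$seed, 102L))
      post_int <- mi$posterior
      write_posterior(post_int, out_dir, "mash_interaction")
      pipeline_log(logcon, "mash", "interaction: %d associations", nrow(post_int$lfsr))
    }
  }, error = function(e) fail_stage("mash", e))

  top <- NULL
  if (isTRUE(cfg$stages$classify) && !is.null(post_add)) tryCatch({
    tssd <- setNames(assoc_add$tss_dist, paste(assoc_add$gene, assoc_add$variant, sep = ":"))
    top <- select_top(post_add, primary = cfg$classify$primary,
                      secondary = cfg$classify$secondary,
                      buffer = cfg$classify$buffer, tss_dist = tssd)
    if (!is.null(top)) {
      write_tsv(top$table, file.path(out_dir, "top_eqtl.tsv"))
      sh <- pairwise_sharing(top, factor = cfg$classify$share_factor)
      write_tsv(cbind(cell_type = rownames(sh), as.data.frame(sh)),
                file.path(out_dir, "sharing_matrix.tsv"))
      pruned <- prune_top(top, dist_threshold = cfg$classify$prune_dist)
      write_tsv(pruned$table, file.path(out_dir, "pruned_top_eqtl.tsv"))
      manifest$counts$top_eqtl <- nrow(top$table)
      manifest$counts$pruned_top_eqtl <- nrow(pruned$table)
      pipeline_log(logcon, "classify", "%d top eQTL (%d after pruning); classes: %s",
                   nrow(top$table), nrow(pruned$table),
                   paste(names(table(top$table$class)), table(top$table$class),
                         sep = "=", collapse = ", "))
    } else pipeline_log(logcon, "classify", "no significant eQTL")
    if (!is.null(post_int)) {
      top_int <- select_top(post_int, primary = cfg$classify$primary,
                            secondary = cfg$classify$secondary,
                            buffer = cfg$classify$buffer)
      if (!is.null(top_int)) {
        write_tsv(top_int$table, file.path(out_dir, "top_int_eqtl.tsv"))
        manifest$counts$top_int_eqtl <- nrow(top_int$table)
      }
    }
  }, error = function(e) fail_stage("classify", e))

  if (isTRUE(cfg$stages$coloc) && length(cfg$inputs$gwas) > 0 && !is.null(top)) tryCatch({
    rows <- list()
    for (gw in names(cfg$inputs$gwas)) {
      gwas <- read_tsv(cfg$inputs$gwas[[gw]])
      for (i in seq_len(nrow(top$table))) {
        gene <- top$table$gene[i]
        ct <- colnames(top$lfsr)[which.min(top$lfsr[i, ])]
        sel <- which(post_add$map$gene == gene)
        vinfo <- Gf$variants[match(post_add$map$variant[sel], Gf$variants$variant_id), ]
        eq <- data.frame(variant = post_add$map$variant[sel],
                         chrom = vinfo$chrom, pos = vinfo$pos,
                         ref = vinfo$ref, alt = vinfo$alt, maf = vinfo$maf,
                         beta = post_add$post_mean[sel, ct],
                         se = pmax(post_add$post_sd[sel, ct], 1e-8),
                         stringsAsFactors = FALSE)
        row <- data.frame(gene = gene, cell_type = ct, gwas = gw,
                          nsnps = 0L, PP0 = NA_real_, PP1 = NA_real_,
                          PP2 = NA_real_, PP3 = NA_real_, PP4 = NA_real_,
                          top_shared = NA_character_, colocalized = FALSE,
                          skip = "", stringsAsFactors = FALSE)
        cres <- tryCatch(
          coloc_abf(eq, gwas, p1 = cfg$coloc$p1, p2 = cfg$coloc$p2,
                    p12 = cfg$coloc$p12, min_shared = cfg$coloc$min_shared),
          error = function(e) conditionMessage(e))
        if (is.character(cres)) {
          row$skip <- cres
        } else {
          row$nsnps <- cres$nsnps
          row[paste0("PP", 0:4)] <- as.list(unname(cres$pp))
          row$top_shared <- cres$top_shared
          row$colocalized <- isTRUE(cres$pp[["PP4"]] >= cfg$coloc$pp4_threshold)
          row$skip <- cres$skip %||% ""
        }
        rows[[length(rows) + 1]] <- row
      }
    }
    coloc_tab <- do.call(rbind, rows)
    write_tsv(coloc_tab, file.path(out_dir, "coloc_results.tsv"))
    manifest$counts$coloc_tests <- sum(coloc_tab$skip == "")
    manifest$counts$coloc_hits <- sum(coloc_tab$colocalized, na.rm = TRUE)
    pipeline_log(logcon, "coloc", "%d tests (%d skipped), %d colocalized (PP4 >= %.2f)",
                 sum(coloc_tab$skip == ""), sum(coloc_tab$skip != ""),
                 sum(coloc_tab$colocalized, na.rm = TRUE), cfg$coloc$pp4_threshold)
  }, error = function(e) fail_stage("coloc", e))

  if (isTRUE(cfg$stages$enrich) && length(cfg$inputs$gwas) > 0 &&
      !is.null(top) && !is.null(assoc_add)) tryCatch({
    rows <- list()
    for (gw in names(cfg$inputs$gwas)) {
      gwas <- read_tsv(cfg$inputs$gwas[[gw]])
      universe <- intersect(unique(assoc_add$variant), gwas$variant)
      hits <- gwas$variant[gwas$p < cfg$enrich$gwas_p]
      for (cl in unique(top$table$class)) {
        fg <- intersect(top$table$variant[top$table$class == cl], universe)
        if (length(fg) == 0) next
        fe <- fisher_enrichment(fg, hits, universe)
        rows[[length(rows) + 1]] <- data.frame(
          gwas = gw, set = cl, n_fg = length(fg),
          n_overlap = fe$table[1, 1], odds_ratio = fe$odds_ratio, p = fe$p,
          stringsAsFactors = FALSE)
      }
      ## TSS-distance-matched null set of non-significant associations
      sig_ids <- paste(top$table$gene, top$table$variant, sep = ":")
      aa <- assoc_add[!duplicated(paste(assoc_add$gene, assoc_add$variant, sep = ":")), ]
      aa_id <- paste(aa$gene, aa$variant, sep = ":")
      pool <- abs(aa$tss_dist[!aa_id %in% sig_ids])
      names(pool) <- aa$variant[!aa_id %in% sig_ids]
      tgt <- abs(top$table$tss_dist)
      n_null <- cfg$enrich$null_size %||% min(length(tgt), floor(length(pool) / 2))
      null_set <- tryCatch(
        matched_null(pool, tgt, n = n_null, seed = derive_seed(cfg$seed, 103L)),
        error = function(e) NULL)
      if (!is.null(null_set)) {
        fg <- intersect(unique(null_set), universe)
        fe <- fisher_enrichment(fg, hits, universe)
        rows[[length(rows) + 1]] <- data.frame(
          gwas = gw, set = "matched_null", n_fg = length(fg),
          n_overlap = fe$table[1, 1], odds_ratio = fe$odds_ratio, p = fe$p,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0) {
      write_tsv(do.call(rbind, rows), file.path(out_dir, "enrichment.tsv"))
      manifest$counts$enrichment_tests <- length(rows)
      pipeline_log(logcon, "enrich", "%d enrichment tests", length(rows))
    }
  }, error = function(e) fail_stage("enrich", e))

  if (isTRUE(cfg$stages$de)) tryCatch({
    rows <- list()
    for (ct in names(pb)) {
      slot <- pb[[ct]]
      grp <- slot$disease
      if (sum(grp == "ILD") >= 3 && sum(grp != "ILD") >= 3) {
        de <- wilcoxon_de(slot$expr, factor(grp == "ILD", c(TRUE, FALSE),
                                            c("ILD", "control")),
                          adj_threshold = cfg$de$adj_threshold)
        de <- cbind(cell_type = ct, de)
        rows[[length(rows) + 1]] <- de
      }
    }
    if (length(rows) > 0) {
      de_tab <- do.call(rbind, rows)
      write_tsv(de_tab, file.path(out_dir, "de_results.tsv"))
      manifest$counts$de_genes <- sum(de_tab$de)
      pipeline_log(logcon, "de", "%d DE gene calls across cell types", sum(de_tab$de))
    }
  }, error = function(e) fail_stage("de", e))

  arts <- setdiff(list.files(out_dir), c("manifest.json", "pipeline.log"))
  manifest$artifacts <- as.list(tools::md5sum(file.path(out_dir, arts)))
  names(manifest$artifacts) <- arts
  manifest$status <- "complete"
  write_manifest()
  invisible(manifest)
}

## store a fitted shrinkage model as plain JSON (matrices flattened)
saveRDS_free_model <- function(model, path) {
  obj <- list(conditions = model$conditions, grid = model$grid,
              pi = as.list(model$pi), loglik = model$loglik,
              Ulist = lapply(model$Ulist, function(U) as.data.frame(U)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
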