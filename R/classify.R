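## Significance calling on lfsr, top-eQTL selection, pairwise sharing,
## global/multi/unique specificity classes, majority-sign adjustment, and
## the silhouette-guided pruning of redundant top-eQTL profiles.

#' Call significance from an lfsr matrix
#'
#' A row (association) qualifies if its minimum lfsr across cell types is
#' at or below `primary`; within qualifying rows, a cell type is called
#' significant if its lfsr is at or below the relaxed `secondary`
#' threshold. Non-qualifying rows are all-FALSE.
#'
#' @param lfsr association x cell-type matrix of local false sign rates.
#' @param primary,secondary the two thresholds (0.05 / 0.1).
#' @return logical matrix of the same shape.
#' @export
call_significance <- function(lfsr, primary = 0.05, secondary = 0.1) {
  lf <- as.matrix(lfsr)
  assert_that(all(lf >= 0 & lf <= 1, na.rm = TRUE), "call_significance: lfsr outside [0,1]")
  qual <- apply(lf, 1, function(x) any(x <= primary, na.rm = TRUE))
  mask <- !is.na(lf) & lf <= secondary & qual
  dimnames(mask) <- dimnames(lf)
  mask
}

#' Classify eQTL specificity
#'
#' @param n_sig number of significant cell types (vectorized).
#' @param n_types total number of cell types tested.
#' @param buffer low-power buffer: significant in at least
#'   `n_types - buffer` cell types counts as global.
#' @return character vector in `{"global", "multi", "unique"}`.
#' @export
classify_specificity <- function(n_sig, n_types, buffer = 2) {
  assert_that(n_types >= 3, "classify_specificity: need >= 3 cell types")
  assert_that(all(n_sig > 0), "classify_specificity: associations with 0 significant cell types must be pre-filtered")
  ifelse(n_sig >= n_types - buffer, "global",
         ifelse(n_sig == 1, "unique", "multi"))
}

#' Select top eQTL per gene and cell type
#'
#' For each (gene, cell type), the significant association with the lowest
#' lfsr; ties broken by larger absolute posterior effect, then by
#' lexicographic variant id. The returned table holds the union of
#' selected gene-variant pairs with their full cross-cell-type posterior
#' profiles and specificity class.
#'
#' @param posterior a `scqtl_posterior` (see [mash_posterior()]).
#' @param primary,secondary significance thresholds for [call_significance()].
#' @param buffer passed to [classify_specificity()].
#' @param tss_dist optional named vector (by `gene:variant` id) of signed
#'   TSS distances to carry through.
#' @return an object of class `scqtl_top`: `table` (gene, variant, id,
#'   n_sig, class, top_in = number of cell types whose argmin it is),
#'   plus matrices `beta`, `lfsr`, `mask` over those ids.
#' @export
select_top <- function(posterior, primary = 0.05, secondary = 0.1, buffer = 2,
                       tss_dist = NULL) {
  stopifnot(inherits(posterior, "scqtl_posterior"))
  mask <- call_significance(posterior$lfsr, primary, secondary)
  map <- posterior$map
  chosen <- list()
  for (ct in colnames(posterior$lfsr)) {
    sig <- which(mask[, ct])
    if (length(sig) == 0) next
    d <- data.frame(idx = sig, gene = map$gene[sig],
                    lfsr = posterior$lfsr[sig, ct],
                    abeta = abs(posterior$post_mean[sig, ct]),
                    variant = map$variant[sig], stringsAsFactors = FALSE)
    d <- d[order(d$gene, d$lfsr, -d$abeta, d$variant), ]
    d <- d[!duplicated(d$gene), ]
    chosen[[ct]] <- d$idx
  }
  idx <- sort(unique(unlist(chosen)))
  if (length(idx) == 0) return(NULL)
  top_in <- table(factor(unlist(chosen), levels = idx))
  n_sig <- rowSums(mask[idx, , drop = FALSE])
  tab <- data.frame(gene = map$gene[idx], variant = map$variant[idx],
                    id = map$id[idx], n_sig = as.integer(n_sig),
                    class = classify_specificity(n_sig, ncol(mask), buffer),
                    top_in = as.integer(top_in), stringsAsFactors = FALSE)
  if (!is.null(tss_dist)) tab$tss_dist <- unname(tss_dist[tab$id])
  out <- list(table = tab,
              beta = posterior$post_mean[idx, , drop = FALSE],
              lfsr = posterior$lfsr[idx, , drop = FALSE],
              mask = mask[idx, , drop = FALSE])
  class(out) <- "scqtl_top"
  out
}

#' Pairwise sharing of top eQTL between cell types
#'
#' For each cell-type pair, among top eQTL significant in both, the
#' fraction whose effects have the same sign and magnitudes within a
#' factor of `factor` (min/max ratio at least `factor`).
#'
#' @param top a `scqtl_top`.
#' @param factor sharing factor (0.5).
#' @return symmetric cell-type x cell-type matrix with unit diagonal; NA
#'   where no eQTL is significant in both members of a pair.
#' @export
pairwise_sharing <- function(top, factor = 0.5) {
  stopifnot(inherits(top, "scqtl_top"))
  cts <- colnames(top$mask)
  R <- length(cts)
  M <- matrix(NA_real_, R, R, dimnames = list(cts, cts))
  diag(M) <- 1
  for (a in seq_len(R - 1)) for (b in (a + 1):R) {
    both <- top$mask[, a] & top$mask[, b]
    if (!any(both)) {
      message(sprintf("pairwise_sharing: no eQTL jointly significant in %s and %s",
                      cts[a], cts[b]))
      next
    }
    ba <- top$beta[both, a]; bb <- top$beta[both, b]
    same <- sign(ba) == sign(bb) & ba != 0 & bb != 0
    ratio <- pmin(abs(ba), abs(bb)) / pmax(abs(ba), abs(bb))
    M[a, b] <- M[b, a] <- mean(same & ratio >= factor)
  }
  M
}

#' Majority-sign adjustment of effect profiles
#'
#' If the majority sign among significant cell types is negative, the whole
#' profile is flipped so that positive means the common direction; an exact
#' tie leaves the profile unchanged.
#'
#' @param beta association x cell-type effect matrix.
#' @param mask logical significance matrix of the same shape.
#' @return the sign-adjusted effect matrix (attribute `flipped`: logical
#'   per row).
#' @export
sign_adjust <- function(beta, mask) {
  beta <- as.matrix(beta)
  flipped <- logical(nrow(beta))
  for (i in seq_len(nrow(beta))) {
    s <- sign(beta[i, mask[i, ]])
    if (sum(s < 0) > sum(s > 0)) {
      beta[i, ] <- -beta[i, ]
      flipped[i] <- TRUE
    }
  }
  attr(beta, "flipped") <- flipped
  beta
}

## mean silhouette width of a clustering given a dist matrix (as matrix)
mean_silhouette <- function(D, cl) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Prune redundant top eQTL per gene
#'
#' Profiles are the centered absolute posterior effects across cell types
#' (non-significant entries set to zero before taking absolute values and
#' centering). A single top eQTL is kept as is; two are both kept iff
#' their Euclidean distance exceeds `dist_threshold`, otherwise the one
#' significant in more cell types survives; three or more are kept
#' entirely when all pairwise distances exceed the threshold and are
#' otherwise clustered (complete linkage) with the tree cut at the
#' `k_range` value maximizing the mean silhouette width, keeping per
#' cluster the eQTL significant in the most cell types. All ties resolve
#' deterministically (lower mean lfsr, then variant id).
#'
#' @param top a `scqtl_top`.
#' @param dist_threshold Euclidean distance threshold (0.2).
#' @param k_range candidate cluster counts (2 to 5; capped at m - 1).
#' @return the pruned `scqtl_top`.
#' @export
prune_top <- function(top, dist_threshold = 0.2, k_range = 2:5) {
  stopifnot(inherits(top, "scqtl_top"))
  keep <- logical(nrow(top$table))
  pick_best <- function(rows) {
    ## rows: indices; most significant cell types, then lower mean lfsr,
    ## then lexicographic variant id
    ns <- top$table$n_sig[rows]
    ml <- rowMeans(top$lfsr[rows, , drop = FALSE], na.rm = TRUE)
    vid <- top$table$variant[rows]
    rows[order(-ns, ml, vid)][1]
  }
  for (g in unique(top$table$gene)) {
    rows <- which(top$table$gene == g)
    m <- length(rows)
    if (m == 1) { keep[rows] <- TRUE; next }
    prof <- abs(top$beta[rows, , drop = FALSE] * top$mask[rows, , drop = FALSE])
    prof <- prof - rowMeans(prof)
    D <- as.matrix(dist(prof))
    if (m == 2) {
      if (D[1, 2] > dist_threshold) keep[rows] <- TRUE
      else keep[pick_best(rows)] <- TRUE
      next
    }
    if (all(D[upper.tri(D)] > dist_threshold)) { keep[rows] <- TRUE; next }
    hc <- hclust(as.dist(D), method = "complete")
    ks <- k_range[k_range <= m - 1]
    if (length(ks) == 0) ks <- 2L
    sil <- vapply(ks, function(k) mean_silhouette(D, cutree(hc, k)), 0)
    k_best <- ks[which.max(sil)]   # which.max returns first maximum: smallest k on ties
    cl <- cutree(hc, k_best)
    for (k in unique(cl)) keep[pick_best(rows[cl == k])] <- TRUE
  }
  out <- list(table = top$table[keep, , drop = FALSE],
              beta = top$beta[keep, , drop = FALSE],
              lfsr = top$lfsr[keep, , drop = FALSE],
              mask = top$mask[keep, , drop = FALSE])
  rownames(out$table) <- NULL
  class(out) <- "scqtl_top"
  out
}
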