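## Approximate-Bayes-factor colocalization of eQTL and GWAS signals,
## Fisher enrichment with TSS-distance-matched null sets, and a
## rank-sum (AUC) differential expression test used for interaction-eGene
## overlap.

#' Wakefield log approximate Bayes factor
#'
#' `r = prior_sd^2 / (prior_sd^2 + se^2)`;
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2` with `z = beta / se`.
#'
#' @param beta,se effect estimate and standard error (se > 0), vectorized.
#' @param prior_sd prior standard deviation of the true effect.
#' @return vector of log ABFs (natural log).
#' @export
wakefield_log_abf <- function(beta, se, prior_sd) {
  assert_that(all(is.finite(beta)) && all(is.finite(se)) && all(se > 0),
              "wakefield_log_abf: beta/se must be finite, se > 0")
  assert_that(all(prior_sd > 0), "wakefield_log_abf: prior_sd must be > 0")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * log(1 - r) + z^2 * r / 2
}

## Harmonize two summary-stat tables. Matching is on variant id when both
## provide one; otherwise on chrom:pos with allele alignment (swap flips
## the sign of beta2; pure strand flips are complemented first; ambiguous
## A/T and C/G variants are dropped with a message).
harmonize_stats <- function(s1, s2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (!is.null(s1$variant) && !is.null(s2$variant) &&
      length(intersect(s1$variant, s2$variant)) > 0) {
    common <- intersect(s1$variant, s2$variant)
    i1 <- match(common, s1$variant)
    i2 <- match(common, s2$variant)
    return(list(s1 = s1[i1, , drop = FALSE], s2 = s2[i2, , drop = FALSE]))
  }
  assert_that(all(c("chrom", "pos", "ref", "alt") %in% names(s1)) &&
                all(c("chrom", "pos", "ref", "alt") %in% names(s2)),
              "harmonize_stats: need variant ids or chrom/pos/ref/alt on both sides")
  k1 <- paste(s1$chrom, s1$pos)
  k2 <- paste(s2$chrom, s2$pos)
  common <- intersect(k1, k2)
  i1 <- match(common, k1); i2 <- match(common, k2)
  a <- s1[i1, , drop = FALSE]; b <- s2[i2, , drop = FALSE]
  ambiguous <- a$ref == comp[a$alt] | b$ref == comp[b$alt]
  if (any(ambiguous))
    message(sprintf("harmonize_stats: dropped %d strand-ambiguous variant(s)", sum(ambiguous)))
  a <- a[!ambiguous, , drop = FALSE]; b <- b[!ambiguous, , drop = FALSE]
  same <- a$ref == b$ref & a$alt == b$alt
  swap <- a$ref == b$alt & a$alt == b$ref
  flip <- comp[a$ref] == b$ref & comp[a$alt] == b$alt
  flipswap <- comp[a$ref] == b$alt & comp[a$alt] == b$ref
  keep <- same | swap | flip | flipswap
  if (any(!keep))
    message(sprintf("harmonize_stats: dropped %d variant(s) with unresolvable alleles", sum(!keep)))
  a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
  sgn <- ifelse((swap | flipswap)[keep], -1, 1)
  b$beta <- b$beta * sgn
  list(s1 = a, s2 = b)
}

#' ABF colocalization of two association signals
#'
#' Enumerates the five causal configurations (no signal, trait-1 only,
#' trait-2 only, two distinct variants, one shared variant) from per-SNP
#' Wakefield log ABFs combined by log-sum-exp.
#'
#' @param stats1,stats2 data.frames over a cis region with columns
#'   `variant`, `beta`, `se` (plus `chrom`, `pos`, `ref`, `alt` for
#'   allele-aware harmonization, and optionally `maf`, `case_fraction`).
#'   For the eQTL side pass posterior means/sds; for GWAS the reported
#'   beta/se.
#' @param p1,p2,p12 prior probabilities of a variant being causal for
#'   trait 1, trait 2, or both.
#' @param min_shared minimum number of shared variable SNPs (MAF strictly
#'   inside (0,1) where a `maf` column is available) to run the test.
#' @param prior_sd1,prior_sd2 effect prior standard deviations; `NULL`
#'   picks 0.15 (quantitative) or 0.2 (case-control, detected from a
#'   finite `case_fraction` column).
#' @return list (class `scqtl_coloc`): `pp` (named PP0..PP4, summing to 1),
#'   `nsnps`, `top_shared` (variant maximizing the joint ABF), and `skip`
#'   reason (non-NULL when not tested).
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      min_shared = 100, prior_sd1 = NULL, prior_sd2 = NULL) {
  h <- harmonize_stats(stats1, stats2)
  s1 <- h$s1; s2 <- h$s2
  variable <- rep(TRUE, nrow(s1))
  if (!is.null(s1$maf)) variable <- variable & s1$maf > 0 & s1$maf < 1
  if (!is.null(s2$maf)) variable <- variable & s2$maf > 0 & s2$maf < 1
  s1 <- s1[variable, , drop = FALSE]
  s2 <- s2[variable, , drop = FALSE]
  n <- nrow(s1)
  if (n == 0) stop("coloc_abf: zero overlapping variants after harmonization")
  out <- list(nsnps = n, pp = setNames(rep(NA_real_, 5), paste0("PP", 0:4)),
              top_shared = NA_character_, skip = NULL)
  class(out) <- "scqtl_coloc"
  if (n < min_shared) {
    out$skip <- sprintf("only %d shared variable SNPs (< %d)", n, min_shared)
    return(out)
  }
  pick_sd <- function(s, given) {
    if (!is.null(given)) return(given)
    if (!is.null(s$case_fraction) && any(is.finite(s$case_fraction))) 0.2 else 0.15
  }
  la1 <- wakefield_log_abf(s1$beta, s1$se, pick_sd(s1, prior_sd1))
  la2 <- wakefield_log_abf(s2$beta, s2$se, pick_sd(s2, prior_sd2))
  ls1 <- logsumexp(la1)
  ls2 <- logsumexp(la2)
  ls12 <- logsumexp(la1 + la2)
  lH <- c(H0 = 0,
          H1 = log(p1) + ls1,
          H2 = log(p2) + ls2,
          H3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
          H4 = log(p12) + ls12)
  pp <- exp(lH - logsumexp(lH))
  out$pp <- setNames(pp / sum(pp), paste0("PP", 0:4))
  out$top_shared <- s1$variant[which.max(la1 + la2)]
  out
}

#' Fisher exact enrichment of one set against another
#'
#' Builds the 2x2 in/out-foreground by in/out-background table over the
#' universe and applies the two-sided Fisher exact test. The odds ratio is
#' the sample OR with Haldane correction (+0.5 per cell) when any cell is
#' zero.
#'
#' @param foreground,background,universe vectors of ids (`foreground` and
#'   `background` subsets of `universe`).
#' @return list (class `scqtl_enrichment`): `table` (2x2), `odds_ratio`,
#'   `p`.
#' @export
fisher_enrichment <- function(foreground, background, universe) {
  assert_that(length(universe) > 0, "fisher_enrichment: empty universe")
  universe <- unique(universe)
  foreground <- unique(intersect(foreground, universe))
  background <- unique(intersect(background, universe))
  a <- length(intersect(foreground, background))
  b <- length(setdiff(foreground, background))
  cc <- length(setdiff(background, foreground))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("fg", "not_fg"), c("bg", "not_bg")))
  p <- fisher.test(tab)$p.value
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  out <- list(table = tab, odds_ratio = or, p = p)
  class(out) <- "scqtl_enrichment"
  out
}

#' Distance-matched null set by rejection sampling
#'
#' Accepts candidates from `pool` with probability proportional to the
#' ratio of a kernel density estimate of the target distribution to one of
#' the pool distribution, so the accepted sample matches the target
#' distribution (e.g. absolute TSS distances of significant eQTL).
#'
#' @param pool named numeric vector of candidate values (names are ids).
#' @param target_values numeric vector defining the target distribution.
#' @param n number of null items to return.
#' @param seed integer seed; identical seeds give identical selections.
#' @return character vector of `n` accepted pool ids (attribute
#'   `acceptance_rate`).
#' @export
matched_null <- function(pool, target_values, n, seed) {
  assert_that(!is.null(names(pool)), "matched_null: pool must be named")
  assert_that(n <= length(pool), "matched_null: n exceeds pool size")
  ## Sheather-Jones bandwidths: the rule-of-thumb default oversmooths
  ## multimodal distance distributions
  kde <- function(x) tryCatch(density(x, bw = "SJ"), error = function(e) density(x))
  ft <- kde(target_values)
  fp <- kde(pool)
  dt <- stats::approx(ft$x, ft$y, xout = pool, yleft = 0, yright = 0)$y
  dp <- stats::approx(fp$x, fp$y, xout = pool, yleft = 0, yright = 0)$y
  w <- ifelse(dp > 0, dt / dp, 0)
  if (max(w) == 0) stop("matched_null: target and pool distributions do not overlap")
  w <- w / max(w)
  withr::with_seed(seed, {
    ord <- sample(length(pool))
    acc <- ord[runif(length(pool)) < w[ord]]
  })
  rate <- length(acc) / length(pool)
  if (rate < 0.01)
    stop(sprintf("matched_null: acceptance rate %.3f%% < 1%%; enlarge the candidate pool",
                 100 * rate))
  assert_that(length(acc) >= n,
              "matched_null: only %d accepted candidates (< n = %d); enlarge the pool",
              length(acc), n)
  out <- names(pool)[acc[seq_len(n)]]
  attr(out, "acceptance_rate") <- rate
  out
}

## exact two-sided rank-sum p by enumeration of group assignments
wilcox_exact_p <- function(r, n1) {
  N <- length(r)
  combs <- utils::combn(N, n1)
  u <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  mean(abs(u - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Rank-sum (AUC) differential expression between two groups
#'
#' Per gene: Mann-Whitney U with AUC effect size `U / (n1 n2)`, two-sided
#' p (exact enumeration when `n1 + n2 <= 12`, otherwise normal
#' approximation with tie correction), group mean difference as logFC,
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param expr observation x gene matrix (log-scale expression).
#' @param group length-`nrow(expr)` factor/vector with two levels; the
#'   first level is the "case" group whose AUC is reported.
#' @param adj_threshold DE call threshold on the adjusted p.
#' @return data.frame: gene, auc, logFC, p, p_adj, de.
#' @export
wilcoxon_de <- function(expr, group, adj_threshold = 0.1) {
  expr <- as.matrix(expr)
  g <- as.factor(group)
  assert_that(nlevels(g) == 2, "wilcoxon_de: exactly two groups required")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  assert_that(n1 >= 3 && n2 >= 3, "wilcoxon_de: each group needs >= 3 observations")
  N <- n1 + n2
  i1 <- which(g == levels(g)[1])
  res <- lapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    if (length(unique(x)) == 1)
      return(c(auc = 0.5, logFC = 0, p = 1))
    r <- rank(x)
    U <- sum(r[i1]) - n1 * (n1 + 1) / 2
    auc <- U / (n1 * n2)
    if (N <= 12) {
      p <- wilcox_exact_p(c(r[i1], r[-i1]), n1)
    } else {
      ties <- table(r)
      tie_term <- sum(ties^3 - ties) / (N * (N - 1))
      v <- n1 * n2 / 12 * ((N + 1) - tie_term)
      z <- (U - n1 * n2 / 2) / sqrt(v)
      p <- 2 * pnorm(-abs(z))
    }
    c(auc = auc, logFC = mean(x[i1]) - mean(x[-i1]), p = min(p, 1))
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(gene = colnames(expr) %||% paste0("g", seq_len(ncol(expr))), out)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$de <- out$p_adj < adj_threshold
  rownames(out) <- NULL
  out
}

#' Overlap of eQTL classes with external association hits
#'
#' Per eQTL class, the count and fraction of eQTL variants that are hits
#' (p below `p_cut`) in an external summary-statistics table.
#'
#' @param eqtl data.frame with columns `variant` and `class`.
#' @param external data.frame with columns `variant` and `p`.
#' @param p_cut external hit threshold.
#' @return data.frame: class, n, n_hit, fraction.
#' @export
threshold_overlap <- function(eqtl, external, p_cut = 1e-6) {
  shared <- intersect(eqtl$variant, external$variant)
  if (length(shared) == 0) {
    warning("threshold_overlap: no shared variants")
    return(data.frame(class = character(), n = integer(), n_hit = integer(),
                      fraction = numeric()))
  }
  hits <- external$variant[external$p < p_cut]
  cls <- split(eqtl$variant, eqtl$class)
  out <- lapply(names(cls), function(k) {
    v <- unique(cls[[k]])
    data.frame(class = k, n = length(v), n_hit = sum(v %in% hits),
               fraction = mean(v %in% hits), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
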