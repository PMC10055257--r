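## Internal helpers shared across modules.

#' @useDynLib scqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm pt rbinom rpois rnbinom rbeta rnorm
#'   runif sd var cor lm.fit density fisher.test p.adjust ks.test hclust
#'   cutree dist optim complete.cases setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, stable.
logdiffexp <- function(a, b) {
  if (b > a) stop("logdiffexp requires a >= b")
  if (b == a) return(-Inf)
  a + log1p(-exp(b - a))
}

## Stop unless condition holds; message formatted with sprintf.
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Derive a stage-specific seed from a global seed by a fixed offset,
## keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% 2147483647)
}

## Symmetrize and clip eigenvalues so a matrix is PSD up to `tol`.
make_psd <- function(M, tol = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, tol)
  U <- e$vectors %*% (vals * t(e$vectors))
  (U + t(U)) / 2
}

geometric_mean <- function(x) exp(mean(log(x)))

## write a data.frame as TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, ...))
}
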