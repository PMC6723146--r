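#' Coordination power from all-pairs log2 correlations
#'
#' Computes the Pearson correlation of log2 gene-level expression across
#' the lambda replicas for every gene pair, and summarises each gene by
#' its coordination power \eqn{CP_i = \overline{\rho_{ij}^2}\,(j \ne i)},
#' the mean squared correlation with every other quantified gene.  The
#' computation streams over gene blocks so the full N x N matrix is
#' never materialised; the result is identical to the dense computation.
#'
#' Genes with zero variance across replicates (correlation undefined)
#' are excluded from N with a warning.
#'
#' @param dataset filtered, normalised dataset with lambda >= 4.
#' @param block_size genes per block; bounds the working set at
#'   `block_size * N` doubles.
#' @return A `CoordinationProfile`: list with `cp` (named vector),
#'   `mean_cp` (grand mean), `n_genes`, `dropped` (excluded symbols).
#' @export
log2_correlation_rows <- function(dataset, block_size = 512L) {
  if (dataset$lambda < 4)
    stop("log2_correlation_rows: lambda must be >= 4")
  g <- gene_expression(dataset)
  if (any(g <= 0))
    stop("log2_correlation_rows: non-positive gene-level expression")
  L <- log2(g)
  ctr <- L - rowMeans(L)
  ss <- rowSums(ctr^2)
  zero <- ss == 0
  dropped <- rownames(L)[zero]
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) excluded from coordination")
    ctr <- ctr[!zero, , drop = FALSE]
    ss <- ss[!zero]
  }
  N <- nrow(ctr)
  if (N < 2)
    stop("log2_correlation_rows: fewer than 2 genes with variance")
  Z <- ctr / sqrt(ss)            # rows unit-norm: ZZ' is the correlation matrix
  cp <- numeric(N)
  for (start in seq(1L, N, by = block_size)) {
    idx <- start:min(start + block_size - 1L, N)
    R <- Z[idx, , drop = FALSE] %*% t(Z)
    cp[idx] <- (rowSums(R^2) - 1) / (N - 1)   # drop the self pair
  }
  names(cp) <- rownames(ctr)
  structure(list(cp = cp, mean_cp = mean(cp), n_genes = N,
                 dropped = dropped),
            class = "CoordinationProfile")
}

#' @export
print.CoordinationProfile <- function(x, ...) {
  cat(sprintf("CoordinationProfile: %d genes, <CP> = %.4f (%d dropped)\n",
              x$n_genes, x$mean_cp, length(x$dropped)))
  invisible(x)
}

#' Critical correlation for lambda replicas
#'
#' The two-sided significance threshold for a Pearson correlation
#' estimated from lambda observations, from the t-distribution with
#' lambda - 2 degrees of freedom:
#' \eqn{\rho_{crit} = t_{1-\alpha/2} / \sqrt{t_{1-\alpha/2}^2 + \lambda - 2}}.
#' At lambda = 4, alpha = 0.05 this is 0.950: with so few replicas only
#' near-perfect pairs reach per-pair significance, which is why genes
#' are summarised by aggregated squared correlations rather than by
#' per-pair tests.
#'
#' @param lambda replicate count, >= 3.
#' @param alpha two-sided significance level.
#' @return critical |rho|.
#' @export
correlation_critical <- function(lambda, alpha = 0.05) {
  if (lambda < 3) stop("correlation_critical: lambda must be >= 3")
  tq <- stats::qt(1 - alpha / 2, df = lambda - 2)
  tq / sqrt(tq^2 + lambda - 2)
}

#' Classify an expression-correlation pair
#'
#' Pairs whose expressions fluctuate in phase beyond the critical
#' correlation are synergistic, in antiphase antagonistic; pairs with
#' near-zero correlation are independently expressed, anything in
#' between is indeterminate.
#'
#' @param rho Pearson correlation(s) in \[-1, 1\] (vectorised).
#' @param lambda replicate count (>= 3).
#' @param alpha significance level for the critical correlation.
#' @param rho_ind below this |rho| a pair counts as independent.
#' @return character vector in `synergistic`, `antagonistic`,
#'   `independent`, `indeterminate`.
#' @export
classify_pair <- function(rho, lambda, alpha = 0.05, rho_ind = 0.05) {
  if (any(abs(rho) > 1 + 1e-12))
    stop("classify_pair: |rho| must be <= 1")
  crit <- correlation_critical(lambda, alpha)
  ifelse(rho >= crit, "synergistic",
         ifelse(rho <= -crit, "antagonistic",
                ifelse(abs(rho) < rho_ind, "independent", "indeterminate")))
}

#' Top correlation partners of a gene
#'
#' Ranks all other quantified genes by |rho| with the target gene
#' (descending, ties broken by gene symbol) and labels each pair.
#'
#' @param dataset filtered, normalised dataset.
#' @param gene target gene symbol.
#' @param top_k number of partners to return (clamped to N - 1).
#' @param alpha,rho_ind passed to [classify_pair()].
#' @return data.frame `partner`, `rho`, `classification`.
#' @export
correlation_partners <- function(dataset, gene, top_k = 20L,
                                 alpha = 0.05, rho_ind = 0.05) {
  L <- log2(gene_expression(dataset))
  if (!gene %in% rownames(L))
    stop("correlation_partners: unknown gene ", gene)
  target <- L[gene, ]
  others <- L[setdiff(rownames(L), gene), , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  keep <- sds > 0
  rho <- as.vector(stats::cor(target, t(others[keep, , drop = FALSE])))
  out <- data.frame(partner = rownames(others)[keep], rho = rho,
                    classification = classify_pair(rho, dataset$lambda,
                                                   alpha, rho_ind),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rho), out$partner), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, min(top_k, nrow(out)))
}
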