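#' Chi-square mid-interval correction coefficient
#'
#' Sample coefficients of variation from few replicates are biased and
#' noisy; the mid-interval estimator averages the two ends of the
#' chi-square confidence interval of the pooled CV:
#' \deqn{c(r,\varepsilon) = \tfrac12\left(
#'   \sqrt{r/\chi^2(r;\,1-\varepsilon/2)} +
#'   \sqrt{r/\chi^2(r;\,\varepsilon/2)}\right)}
#' where \eqn{\chi^2(r;p)} is the quantile at cumulative probability
#' \eqn{p} and \eqn{r = \lambda R - 1} the pooled degrees of freedom.
#' The coefficient exceeds 1 and decreases towards 1 as \eqn{r} grows,
#' so sparsely probed transcripts are penalised the most.
#'
#' @param r degrees of freedom, integer >= 1 (vectorised).
#' @param epsilon significance parameter; one of 0.010, 0.025, 0.050,
#'   0.100 (smaller values are swamped by technical noise).
#' @return numeric vector of correction coefficients.
#' @export
chi2_midinterval_coefficient <- function(r, epsilon = 0.05) {
  eps_grid <- c(0.010, 0.025, 0.050, 0.100)
  if (length(epsilon) != 1 || !any(abs(epsilon - eps_grid) < 1e-12))
    stop("validation error: epsilon must be one of ",
         paste(format(eps_grid), collapse = ", "))
  if (any(r < 1) || any(r != floor(r)))
    stop("validation error: r must be integer >= 1")
  0.5 * (sqrt(r / stats::qchisq(1 - epsilon / 2, df = r)) +
         sqrt(r / stats::qchisq(epsilon / 2, df = r)))
}

#' Relative Expression Variation per gene
#'
#' For every gene pools the per-probe coefficients of variation across
#' the lambda replicates over all \eqn{R_i} redundant probes, and applies
#' the chi-square mid-interval correction with \eqn{r_i = \lambda R_i - 1}
#' degrees of freedom:
#' \deqn{REV_i = c(r_i, \varepsilon)\,
#'   \sqrt{\tfrac{1}{R_i}\sum_k (s_{ik}/\mu_{ik})^2}}
#' Sample SDs use the \eqn{\lambda - 1} denominator, consistent with the
#' degrees-of-freedom accounting.  Genes with zero pooled CV get a
#' floored REV (half the smallest positive REV in the dataset) and are
#' flagged, which keeps RES and GCH finite while preserving their
#' most-stable rank.
#'
#' @param dataset filtered, normalised [expression_dataset()].
#' @param epsilon significance parameter, see
#'   [chi2_midinterval_coefficient()].
#' @return A `DatasetSummary`: list with `genes` (data.frame `gene_id`,
#'   `mu`, `R`, `r`, `REV`, `RES` (NA until [res_per_gene()]),
#'   `rev_floored`), `median_rev`, `epsilon`, `lambda`, `condition`.
#' @export
rev_per_gene <- function(dataset, epsilon = 0.05) {
  if (is.null(dataset$expr))
    stop("rev_per_gene: run filter_probes() first")
  keep <- !dataset$probes$is_control
  e <- dataset$expr[keep, , drop = FALSE]
  gene <- dataset$probes$gene_id[keep]
  lam <- dataset$lambda
  mu_ik <- rowMeans(e)
  s_ik <- sqrt(rowSums((e - mu_ik)^2) / (lam - 1))
  bad_gene <- unique(gene[mu_ik <= 0])
  if (length(bad_gene)) {
    warning(length(bad_gene),
            " gene(s) excluded: non-positive probe mean expression")
    drop <- gene %in% bad_gene
    e <- e[!drop, , drop = FALSE]; gene <- gene[!drop]
    mu_ik <- mu_ik[!drop]; s_ik <- s_ik[!drop]
  }
  cv2 <- (s_ik / mu_ik)^2
  R <- as.vector(table(gene))
  gid <- sort(unique(gene))
  pooled <- sqrt(rowsum(cv2, gene)[gid, 1] / R)
  mu <- rowsum(mu_ik, gene)[gid, 1] / R
  r <- lam * R - 1L
  REV <- chi2_midinterval_coefficient(r, epsilon) * pooled
  floored <- REV == 0
  if (any(floored)) {
    if (all(floored))
      stop("rev_per_gene: all genes have zero variance; REV floor undefined")
    REV[floored] <- 0.5 * min(REV[!floored])
  }
  genes <- data.frame(gene_id = gid, mu = mu, R = R, r = r, REV = REV,
                      RES = NA_real_, rev_floored = floored,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes, median_rev = stats::median(REV),
                 epsilon = epsilon, lambda = lam,
                 condition = dataset$condition),
            class = "DatasetSummary")
}

#' @export
print.DatasetSummary <- function(x, ...) {
  cat(sprintf("DatasetSummary '%s': %d genes, lambda = %d, epsilon = %g, <REV> = %.4g\n",
              x$condition, nrow(x$genes), x$lambda, x$epsilon, x$median_rev))
  invisible(x)
}

#' Relative Expression Stability per gene
#'
#' \deqn{RES_i = \ln(\langle REV\rangle / REV_i)} with
#' \eqn{\langle REV\rangle} the median REV over all genes: the median
#' gene scores 0, more stably expressed genes score positive.
#'
#' @param summary a `DatasetSummary` from [rev_per_gene()].
#' @return The summary with the `RES` column filled in.
#' @export
res_per_gene <- function(summary) {
  if (!inherits(summary, "DatasetSummary"))
    stop("res_per_gene expects a DatasetSummary")
  if (!isTRUE(summary$median_rev > 0))
    stop("res_per_gene: median REV must be positive")
  summary$genes$RES <- log(summary$median_rev / summary$genes$REV)
  summary
}

#' Mean stability of a functional pathway
#'
#' Arithmetic mean of RES over the pathway members that were quantified
#' in the dataset, with the member count actually found.
#'
#' @param summary `DatasetSummary` with RES filled in.
#' @param set a gene set from [read_gene_sets_gmt()] (list with `set_id`
#'   and `members`), or a character vector of gene symbols.
#' @return list with `set_id`, `mean_res`, `n_members`.
#' @export
pathway_mean_res <- function(summary, set) {
  members <- if (is.character(set)) set else set$members
  set_id <- if (is.character(set)) NA_character_ else set$set_id
  hit <- summary$genes$RES[summary$genes$gene_id %in% members]
  if (length(hit) == 0 || all(is.na(hit)))
    stop("pathway_mean_res: no quantified members (or RES not computed)")
  list(set_id = set_id, mean_res = mean(hit), n_members = length(hit))
}
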