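#' Signed expression ratio between conditions
#'
#' The fold change convention used throughout: \eqn{x = \mu_c/\mu_n} when
#' the gene is more expressed in the test ("cancer") condition,
#' \eqn{x = -\mu_n/\mu_c} when less, and +1 when exactly equal.  Thus
#' \eqn{|x| \ge 1} always, with the sign carrying the direction.
#'
#' @param mu_cancer,mu_normal strictly positive mean expressions
#'   (vectorised).
#' @return signed ratio(s).
#' @export
signed_fold_change <- function(mu_cancer, mu_normal) {
  if (any(mu_cancer <= 0) || any(mu_normal <= 0))
    stop("validation error: mean expressions must be strictly positive")
  ifelse(mu_cancer >= mu_normal,
         mu_cancer / mu_normal,
         -mu_normal / mu_cancer)
}

#' Gene-specific fold-change cut-off
#'
#' \deqn{CUT = 1 + \sqrt{2\,(REV_c^2 + REV_n^2)}}
#' Each gene's regulation threshold grows with its own measured
#' variability in the two conditions, replacing a uniform 1.5x or 2x
#' cut-off; for well-controlled genes CUT can fall below 1.5.
#'
#' @param REV_cancer,REV_normal non-negative REV scores (vectorised).
#' @return cut-off(s), >= 1.
#' @export
cut_threshold <- function(REV_cancer, REV_normal) {
  if (any(REV_cancer < 0) || any(REV_normal < 0))
    stop("validation error: REV must be non-negative")
  1 + sqrt(2 * (REV_cancer^2 + REV_normal^2))
}

#' Two-sided Welch (heteroscedastic) t-test p-value
#'
#' Operates on per-replicate gene-level expressions (the gene's probes
#' averaged within each replicate): biological replicas are the unit of
#' inference.  Uses the Welch–Satterthwaite degrees of freedom.  When
#' both groups are constant, returns 1 for equal means and 0 otherwise.
#'
#' @param values_cancer,values_normal numeric vectors, >= 2 values each.
#' @return two-sided p-value.
#' @export
welch_p <- function(values_cancer, values_normal) {
  if (length(values_cancer) < 2 || length(values_normal) < 2)
    stop("welch_p: need at least 2 values per group")
  welch_p_rows(matrix(values_cancer, nrow = 1),
               matrix(values_normal, nrow = 1))
}

## Row-wise Welch test for gene x replicate matrices (internal, vectorised)
welch_p_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(nrow(a))
  degenerate <- se2 == 0
  p[degenerate] <- as.numeric(m1[degenerate] == m2[degenerate])
  i <- !degenerate
  if (any(i)) {
    tstat <- (m1[i] - m2[i]) / sqrt(se2[i])
    df <- se2[i]^2 / ((v1[i] / n1)^2 / (n1 - 1) + (v2[i] / n2)^2 / (n2 - 1))
    p[i] <- 2 * stats::pt(-abs(tstat), df)
  }
  p
}

#' Regulation calls for every common gene
#'
#' A gene is called regulated when its absolute signed ratio exceeds its
#' own cut-off, \eqn{|x| > CUT} — the Welch p-value is reported alongside
#' but does not enter the call (it weights the WPR instead).
#'
#' @param summary_cancer,summary_normal `DatasetSummary` objects for the
#'   two conditions (aligned gene universes).
#' @param dataset_cancer,dataset_normal the matching aligned, filtered
#'   datasets (for the replicate-level Welch test).
#' @return data.frame with `gene_id`, `x`, `CUT`, `p` and `call` in
#'   `up` / `down` / `not_significant`.
#' @export
regulation_calls <- function(summary_cancer, summary_normal,
                             dataset_cancer, dataset_normal) {
  gc <- summary_cancer$genes; gn <- summary_normal$genes
  if (!setequal(gc$gene_id, gn$gene_id))
    stop("regulation_calls: unaligned gene universes; use align_conditions()")
  ord <- sort(gc$gene_id)
  gc <- gc[match(ord, gc$gene_id), ]
  gn <- gn[match(ord, gn$gene_id), ]
  ec <- gene_expression(dataset_cancer)
  en <- gene_expression(dataset_normal)
  if (!all(ord %in% rownames(ec)) || !all(ord %in% rownames(en)))
    stop("regulation_calls: datasets do not cover the summary gene universe")
  x <- signed_fold_change(gc$mu, gn$mu)
  CUT <- cut_threshold(gc$REV, gn$REV)
  p <- welch_p_rows(ec[ord, , drop = FALSE], en[ord, , drop = FALSE])
  call <- ifelse(abs(x) > CUT, ifelse(x >= 0, "up", "down"),
                 "not_significant")
  data.frame(gene_id = ord, x = x, CUT = CUT, p = p, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted Pathway Regulation
#'
#' Rather than a percentage of regulated genes, WPR ponders *all*
#' quantified members of a pathway by expression level, regulation
#' magnitude and statistical confidence:
#' \deqn{WPR = \langle \mu^{(normal)}_i\,(|x_i| - 1)\,(1 - p_i)\rangle}
#' The default magnitude term \eqn{|x| - 1} is zero at no change in both
#' directions; `literal_eq4 = TRUE` switches to \eqn{|x - 1|}, which
#' under the signed-ratio convention scores an unchanged down-direction
#' gene as 2 and is kept only for comparison.  `weight = "gch"` replaces
#' the normal-condition mean with supplied per-gene GCH scores.
#'
#' @param records regulation table from [regulation_calls()].
#' @param mu_normal named numeric vector of normal-condition mean
#'   expressions (median units), names = gene symbols.
#' @param set gene set (list with `members`) or character vector; use all
#'   genes in `records` for a transcriptome-wide WPR.
#' @param literal_eq4 use `|x - 1|` instead of `|x| - 1`.
#' @param weight `"mu"` (default) or `"gch"`.
#' @param gch named numeric vector of GCH scores, required when
#'   `weight = "gch"`.
#' @return WPR (non-negative scalar) with attribute `n_members`.
#' @export
wpr <- function(records, mu_normal, set,
                literal_eq4 = FALSE, weight = c("mu", "gch"), gch = NULL) {
  weight <- match.arg(weight)
  members <- if (is.character(set)) set else set$members
  idx <- records$gene_id %in% members
  if (!any(idx))
    stop("wpr: no quantified members in the set")
  g <- records$gene_id[idx]
  mag <- if (literal_eq4) abs(records$x[idx] - 1) else abs(records$x[idx]) - 1
  w <- if (weight == "mu") {
    if (!all(g %in% names(mu_normal)))
      stop("wpr: mu_normal is missing members")
    mu_normal[g]
  } else {
    if (is.null(gch) || !all(g %in% names(gch)))
      stop("wpr: weight = 'gch' requires a named gch vector covering the set")
    gch[g]
  }
  out <- mean(w * mag * (1 - records$p[idx]))
  attr(out, "n_members") <- sum(idx)
  out
}

#' Per-pathway regulation report
#'
#' Convenience wrapper: one row per gene set with the quantified member
#' count, mean RES in the normal condition and WPR.
#'
#' @param records regulation table from [regulation_calls()].
#' @param summary_normal `DatasetSummary` of the normal condition (RES
#'   filled in).
#' @param sets list of gene sets from [read_gene_sets_gmt()].
#' @inheritParams wpr
#' @return data.frame `set_id`, `n_members`, `mean_res`, `WPR`.
#' @export
pathway_report <- function(records, summary_normal, sets,
                           literal_eq4 = FALSE) {
  mu_normal <- stats::setNames(summary_normal$genes$mu,
                               summary_normal$genes$gene_id)
  rows <- lapply(sets, function(s) {
    res <- pathway_mean_res(summary_normal, s)
    w <- wpr(records, mu_normal, s, literal_eq4 = literal_eq4)
    data.frame(set_id = s$set_id, n_members = attr(w, "n_members"),
               mean_res = res$mean_res, WPR = as.numeric(w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
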