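#' Gene Commanding Height scores
#'
#' Combines expression stability and coordination power into the score
#' that defines the gene hierarchy of a phenotype.  Two algebraic forms:
#'
#' * `approx4` (default):
#'   \eqn{GCH_i = (\langle REV\rangle / REV_i)\,\exp(4\,CP_i)} — the
#'   closed form whose scale matches the magnitudes reported for real
#'   phenotypes (top genes of order 40–170);
#' * `exact_ratio`:
#'   \eqn{GCH_i = \exp(RES_i + CP_i/\langle CP\rangle)} — the relative
#'   coordination-power definition.
#'
#' The two coincide only when \eqn{\langle CP\rangle = 1/4}; with
#' lambda = 4 the null expectation of a squared sample correlation is
#' 1/3, so they generally differ (the within-condition *ranking* is
#' nevertheless very similar).
#'
#' @param summary `DatasetSummary` with RES filled ([res_per_gene()]).
#' @param profile `CoordinationProfile` over the same gene universe.
#' @param form `"approx4"` or `"exact_ratio"`.
#' @return data.frame `gene_id`, `GCH`, `rank` (NA until
#'   [rank_genes()]), with attribute `form`.
#' @export
gch_scores <- function(summary, profile, form = c("approx4", "exact_ratio")) {
  form <- match.arg(form)
  genes <- summary$genes
  if (!setequal(genes$gene_id, names(profile$cp)))
    stop("gch_scores: gene universe mismatch between summary and profile")
  cp <- profile$cp[genes$gene_id]
  if (any(genes$REV <= 0))
    stop("gch_scores: non-positive (unfloored) REV")
  gch <- if (form == "approx4") {
    (summary$median_rev / genes$REV) * exp(4 * cp)
  } else {
    if (anyNA(genes$RES))
      stop("gch_scores: RES not computed; run res_per_gene() first")
    exp(genes$RES + cp / profile$mean_cp)
  }
  out <- data.frame(gene_id = genes$gene_id, GCH = as.numeric(gch),
                    rank = NA_integer_, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "form") <- form
  out
}

#' Rank genes by descending GCH
#'
#' Ties are broken by gene symbol (ascending) so the ranking is a
#' deterministic permutation of 1..N regardless of input row order.
#'
#' @param records table from [gch_scores()].
#' @return The table sorted by rank, `rank` filled in.
#' @export
rank_genes <- function(records) {
  if (nrow(records) == 0) stop("rank_genes: empty table")
  ord <- order(-records$GCH, records$gene_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "form") <- attr(records, "form")
  out
}

#' Call the Gene Master Regulator of a condition
#'
#' The GMR is the top-GCH gene; it is *actionable* — a plausible single
#' therapeutic target — when its GCH stands clear of the runner-up by at
#' least `gap_threshold` (ratio of first to second).
#'
#' @param ranked ranked table from [rank_genes()] (>= 2 genes).
#' @param gap_threshold actionability ratio, default 1.5.
#' @param condition optional condition label to record.
#' @return A `GMRCall`: list with `condition`, `gmr_gene`, `top_gch`,
#'   `second_gene`, `second_gch`, `gap_ratio`, `actionable`.
#' @export
gmr_call <- function(ranked, gap_threshold = 1.5, condition = NA_character_) {
  if (nrow(ranked) < 2) stop("gmr_call: need at least 2 genes")
  structure(
    list(condition = condition,
         gmr_gene = ranked$gene_id[1], top_gch = ranked$GCH[1],
         second_gene = ranked$gene_id[2], second_gch = ranked$GCH[2],
         gap_ratio = ranked$GCH[1] / ranked$GCH[2],
         actionable = ranked$GCH[1] / ranked$GCH[2] >= gap_threshold),
    class = "GMRCall")
}

#' @export
print.GMRCall <- function(x, ...) {
  cat(sprintf("GMR of %s: %s (GCH = %.2f); runner-up %s (%.2f), gap %.3f — %s\n",
              x$condition, x$gmr_gene, x$top_gch, x$second_gene,
              x$second_gch, x$gap_ratio,
              if (x$actionable) "actionable" else "not actionable"))
  invisible(x)
}

#' Cross-condition table of top genes
#'
#' For the top `k` genes of every condition, reports their GCH in each
#' condition — the standard layout for contrasting the hierarchies of
#' cancer nuclei, normal tissue and cell lines.  Genes unquantified in a
#' condition get NA (printed as N/A by the CSV writers).
#'
#' @param tables named list (condition -> ranked table from
#'   [rank_genes()]); >= 2 conditions.
#' @param k top genes per condition, default 3.
#' @return data.frame with `gene_id`, `lead_condition` (the condition
#'   whose top-k produced the row) and one GCH column per condition.
#' @export
cross_condition_table <- function(tables, k = 3L) {
  if (length(tables) < 2) stop("cross_condition_table: need >= 2 conditions")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("cross_condition_table: tables must be a named list")
  universes <- lapply(tables, `[[`, "gene_id")
  if (length(Reduce(intersect, universes)) == 0)
    stop("cross_condition_table: no gene overlap across conditions")
  rows <- list()
  seen <- character(0)
  for (cond in names(tables)) {
    top <- utils::head(tables[[cond]], k)
    for (g in top$gene_id) {
      if (g %in% seen) next
      seen <- c(seen, g)
      gch <- vapply(tables, function(t) {
        i <- match(g, t$gene_id)
        if (is.na(i)) NA_real_ else t$GCH[i]
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = g, lead_condition = cond,
                   as.list(gch), stringsAsFactors = FALSE,
                   check.names = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Concordance between GCH hierarchy and perturbation consequences
#'
#' The validation statement of the whole approach: manipulating a gene's
#' expression should have larger transcriptome-wide consequences (WPR)
#' in the cell population where that gene has the higher GCH.  A
#' perturbed gene is *concordant* when
#' `sign(GCH_A - GCH_B) == sign(WPR_A - WPR_B)`.
#'
#' @param gch_a,gch_b named numeric vectors: the perturbed genes' GCH in
#'   conditions A and B.
#' @param wpr_a,wpr_b named numeric vectors: measured (or simulated)
#'   transcriptome WPR after perturbing each gene in A and in B.
#' @return list with `table` (per-gene flags) and `fraction` concordant.
#' @export
concordance_report <- function(gch_a, gch_b, wpr_a, wpr_b) {
  genes <- names(gch_a)
  lens <- lengths(list(gch_a, gch_b, wpr_a, wpr_b))
  if (length(unique(lens)) != 1)
    stop("concordance_report: length mismatch")
  for (v in list(gch_b, wpr_a, wpr_b))
    if (!setequal(names(v), genes))
      stop("concordance_report: perturbed-gene lists differ")
  concordant <- sign(gch_a[genes] - gch_b[genes]) ==
    sign(wpr_a[genes] - wpr_b[genes])
  list(table = data.frame(gene_id = genes,
                          gch_a = as.numeric(gch_a[genes]),
                          gch_b = as.numeric(gch_b[genes]),
                          wpr_a = as.numeric(wpr_a[genes]),
                          wpr_b = as.numeric(wpr_b[genes]),
                          concordant = as.logical(concordant),
                          row.names = NULL, stringsAsFactors = FALSE),
       fraction = mean(concordant))
}
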