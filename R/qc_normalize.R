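#' Apply spot-exclusion rules and compute net expression
#'
#' Removes, in order of precedence: (a) control probes; (b) probes with a
#' flagged (saturated/corrupted) pixel in any replicate; (c) probes whose
#' foreground fluorescence is less than twice the background — or whose
#' net signal would be non-positive — in any of the lambda replicates.
#' Each removed probe is counted once, under the first rule it hits.
#' Survivors get net expression `fg - bg`, strictly positive by rule (c)
#' (the boundary `fg == 2*bg` is retained: the exclusion is a strict
#' inequality).
#'
#' @param dataset raw [expression_dataset()].
#' @return list with `dataset` (filtered, `expr` populated) and `report`,
#'   a `QCReport`: counts removed by reason (`control`, `pixel_flag`,
#'   `low_signal`), `input_probes`, `retained_probes`, `retained_genes`.
#' @export
filter_probes <- function(dataset) {
  fg <- dataset$fg; bg <- dataset$bg; ok <- dataset$ok
  is_ctrl <- dataset$probes$is_control
  bad_pixel <- rowSums(!ok) > 0
  low <- rowSums(fg < 2 * bg | fg - bg <= 0) > 0
  reason <- rep(NA_character_, nrow(dataset$probes))
  reason[low] <- "low_signal"
  reason[bad_pixel] <- "pixel_flag"
  reason[is_ctrl] <- "control"
  keep <- is.na(reason)
  if (!any(keep))
    stop("empty-dataset error: no probes survive QC filtering")
  out <- expression_dataset(dataset$probes[keep, , drop = FALSE],
                            dataset$fg[keep, , drop = FALSE],
                            dataset$bg[keep, , drop = FALSE],
                            dataset$ok[keep, , drop = FALSE],
                            dataset$lambda, dataset$condition)
  out$expr <- out$fg - out$bg
  report <- structure(
    list(control = sum(reason == "control", na.rm = TRUE),
         pixel_flag = sum(reason == "pixel_flag", na.rm = TRUE),
         low_signal = sum(reason == "low_signal", na.rm = TRUE),
         input_probes = nrow(dataset$probes),
         retained_probes = sum(keep),
         retained_genes = length(out$gene_index)),
    class = "QCReport")
  list(dataset = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0("QCReport: %d probes in; removed %d control, %d ",
                     "pixel-flagged, %d low-signal; %d probes / %d genes kept\n"),
              x$input_probes, x$control, x$pixel_flag, x$low_signal,
              x$retained_probes, x$retained_genes))
  invisible(x)
}

#' Median-normalise each replicate
#'
#' Divides every net intensity of a replicate by that replicate's median
#' *gene-level* expression, so that afterwards the median quantified
#' transcript sits at exactly 1 ("median units") in every replicate.
#' Idempotent, and invariant to rescaling any replicate's raw
#' intensities.
#'
#' @param dataset filtered dataset (net intensities present, > 0).
#' @return The dataset with `expr` rescaled and `normalized = TRUE`.
#' @export
normalize_median <- function(dataset) {
  if (is.null(dataset$expr))
    stop("normalize_median: run filter_probes() first")
  med <- apply(gene_expression(dataset), 2, stats::median)
  if (any(!is.finite(med)) || any(med <= 0))
    stop("data error: non-positive per-replicate median expression")
  dataset$expr <- sweep(dataset$expr, 2, med, "/")
  dataset$normalized <- TRUE
  dataset
}

#' Restrict two conditions to their common gene universe
#'
#' QC is per condition, so each condition keeps its own probe survivors;
#' cross-condition statistics need a shared set of gene symbols.  Probe
#' order is never assumed shared — only symbols are matched.
#'
#' @param a,b filtered (and normally normalised) datasets.
#' @return list of the two datasets restricted to the intersection of
#'   their gene symbols.
#' @export
align_conditions <- function(a, b) {
  common <- intersect(names(a$gene_index), names(b$gene_index))
  if (length(common) == 0)
    stop("align_conditions: empty gene intersection")
  list(restrict_genes(a, common), restrict_genes(b, common))
}

restrict_genes <- function(x, genes) {
  keep <- !x$probes$is_control & x$probes$gene_id %in% genes
  out <- expression_dataset(x$probes[keep, , drop = FALSE],
                            x$fg[keep, , drop = FALSE],
                            x$bg[keep, , drop = FALSE],
                            x$ok[keep, , drop = FALSE],
                            x$lambda, x$condition,
                            expr = x$expr[keep, , drop = FALSE],
                            normalized = x$normalized)
  out
}
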