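#' Global run configuration
#'
#' Bundles every tunable the pipeline exposes, with the defaults used
#' throughout: epsilon = 0.05 and lambda = 4 (the standard profiling
#' design), the `approx4` GCH form, actionability gap 1.5, top 3 genes
#' per condition in comparison tables.
#'
#' @param epsilon REV significance parameter.
#' @param lambda replicate count expected in inputs.
#' @param form GCH form, `"approx4"` or `"exact_ratio"`.
#' @param gap_threshold GMR actionability ratio.
#' @param top_k genes per condition in cross-condition tables.
#' @param weight WPR weighting, `"mu"` or `"gch"`.
#' @param literal_eq4 use the `|x - 1|` WPR magnitude variant.
#' @param block_size correlation block size.
#' @param normalize median-normalise inputs (see [gch_pipeline()]).
#' @param seed optional seed recorded for synthesis steps.
#' @return `RunConfig` list.
#' @export
run_config <- function(epsilon = 0.05, lambda = 4L,
                       form = c("approx4", "exact_ratio"),
                       gap_threshold = 1.5, top_k = 3L,
                       weight = c("mu", "gch"), literal_eq4 = FALSE,
                       block_size = 512L, normalize = TRUE, seed = NULL) {
  structure(list(epsilon = epsilon, lambda = as.integer(lambda),
                 form = match.arg(form), gap_threshold = gap_threshold,
                 top_k = as.integer(top_k), weight = match.arg(weight),
                 literal_eq4 = isTRUE(literal_eq4),
                 block_size = as.integer(block_size),
                 normalize = isTRUE(normalize), seed = seed),
            class = "RunConfig")
}

#' Run the stability + coordination + GCH pipeline on one dataset
#'
#' QC-filters and median-normalises a raw dataset (already-filtered
#' datasets are passed through), then computes REV/RES, coordination
#' power and the ranked GCH table.
#'
#' @param dataset raw or filtered `ExpressionDataset`.
#' @param epsilon,form,block_size see [run_config()].
#' @param gap_threshold actionability ratio for the GMR call.
#' @param normalize median-normalise after filtering (default).  Set to
#'   `FALSE` for data already on a common replicate scale — e.g. the
#'   synthetic generator's output, where at a few hundred genes the
#'   median's own sampling jitter would otherwise be re-injected into
#'   every gene's replicate CV (real arrays quantify >10k transcripts,
#'   where that jitter is negligible).
#' @return list with `dataset` (filtered, normalised), `qc` (QCReport or
#'   NULL if input was pre-filtered), `summary`, `profile`, `ranked`,
#'   `call` (GMRCall).
#' @export
gch_pipeline <- function(dataset, epsilon = 0.05,
                         form = c("approx4", "exact_ratio"),
                         block_size = 512L, gap_threshold = 1.5,
                         normalize = TRUE) {
  form <- match.arg(form)
  qc <- NULL
  if (is.null(dataset$expr)) {
    f <- filter_probes(dataset)
    dataset <- f$dataset
    qc <- f$report
  }
  if (normalize && !dataset$normalized) dataset <- normalize_median(dataset)
  summary <- res_per_gene(rev_per_gene(dataset, epsilon))
  profile <- log2_correlation_rows(dataset, block_size)
  if (length(profile$dropped)) {
    keep <- !summary$genes$gene_id %in% profile$dropped
    summary$genes <- summary$genes[keep, , drop = FALSE]
  }
  ranked <- rank_genes(gch_scores(summary, profile, form))
  list(dataset = dataset, qc = qc, summary = summary, profile = profile,
       ranked = ranked,
       call = gmr_call(ranked, gap_threshold, dataset$condition))
}

load_input <- function(input, lambda) {
  if (inherits(input, "ExpressionDataset")) input
  else read_probe_table(input, lambda)
}

run_manifest <- function(inputs, config, outdir) {
  hashes <- lapply(inputs, function(x)
    if (is.character(x)) unname(tools::md5sum(x)) else "in-memory")
  manifest <- list(
    inputs = lapply(seq_along(inputs), function(i)
      list(input = if (is.character(inputs[[i]])) inputs[[i]] else
             inputs[[i]]$condition,
           md5 = hashes[[i]])),
    config = unclass(config),
    package = "gmrank",
    version = as.character(utils::packageVersion("gmrank")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Rank the genes of one condition and write the report files
#'
#' Chains QC, normalisation, stability, coordination and GCH ranking and
#' writes `qc.json`, `summary.csv`, `gch.csv`, `gmr_call.json` and
#' `manifest.json` into `outdir`.  Reruns with an identical manifest
#' produce byte-identical CSV bodies.
#'
#' @param input probe-table path or raw `ExpressionDataset`.
#' @param outdir output directory (created if needed).
#' @param config [run_config()].
#' @return The [gch_pipeline()] result, invisibly.
#' @export
run_rank <- function(input, outdir, config = run_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dataset <- load_input(input, config$lambda)
  message(sprintf("[rank] condition '%s': %d probes in",
                  dataset$condition, nrow(dataset$probes)))
  res <- gch_pipeline(dataset, config$epsilon, config$form,
                      config$block_size, config$gap_threshold,
                      normalize = config$normalize)
  if (!is.null(res$qc)) {
    message(sprintf("[rank] QC kept %d probes / %d genes",
                    res$qc$retained_probes, res$qc$retained_genes))
    jsonlite::write_json(unclass(res$qc), file.path(outdir, "qc.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  write_report_csv(res$summary$genes, file.path(outdir, "summary.csv"))
  write_report_csv(res$ranked, file.path(outdir, "gch.csv"))
  jsonlite::write_json(unclass(res$call), file.path(outdir, "gmr_call.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_manifest(list(input), config, outdir)
  message(sprintf("[rank] GMR: %s (GCH %.2f, gap %.2f)",
                  res$call$gmr_gene, res$call$top_gch, res$call$gap_ratio))
  invisible(res)
}

#' Compare conditions: cross-condition GCH table, regulation and WPR
#'
#' The first input is the reference ("normal") condition.  Writes
#' `comparison.csv` (top `top_k` genes of every condition with their GCH
#' everywhere, NA where unquantified), and per non-reference condition
#' `regulation_<cond>.csv` plus, when `gmt` is given,
#' `wpr_<cond>.csv`.
#'
#' @param inputs list (>= 2) of probe-table paths or raw datasets.
#' @param outdir output directory.
#' @param config [run_config()].
#' @param gmt optional GMT path for pathway-level WPR.
#' @return list with `tables` (ranked per condition), `comparison`,
#'   `regulation` (per condition), `wpr` (per condition), invisibly.
#' @export
run_compare <- function(inputs, outdir, config = run_config(), gmt = NULL) {
  if (length(inputs) < 2)
    stop("usage error: run_compare needs at least 2 inputs")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  datasets <- lapply(inputs, load_input, lambda = config$lambda)
  runs <- lapply(datasets, gch_pipeline, epsilon = config$epsilon,
                 form = config$form, block_size = config$block_size,
                 gap_threshold = config$gap_threshold,
                 normalize = config$normalize)
  conds <- vapply(runs, function(r) r$dataset$condition, "")
  if (anyDuplicated(conds))
    conds <- make.unique(conds)
  tables <- stats::setNames(lapply(runs, `[[`, "ranked"), conds)
  comparison <- cross_condition_table(tables, config$top_k)
  write_report_csv(comparison, file.path(outdir, "comparison.csv"))
  sets <- if (!is.null(gmt)) read_gene_sets_gmt(gmt) else NULL
  regulation <- list(); wpr_out <- list()
  normal <- runs[[1]]
  for (i in seq_along(runs)[-1]) {
    al <- align_conditions(runs[[i]]$dataset, normal$dataset)
    sc <- res_per_gene(rev_per_gene(al[[1]], config$epsilon))
    sn <- res_per_gene(rev_per_gene(al[[2]], config$epsilon))
    rc <- regulation_calls(sc, sn, al[[1]], al[[2]])
    regulation[[conds[i]]] <- rc
    write_report_csv(rc, file.path(outdir,
                                   paste0("regulation_", conds[i], ".csv")))
    message(sprintf("[compare] %s vs %s: %d genes, %d regulated",
                    conds[i], conds[1], nrow(rc),
                    sum(rc$call != "not_significant")))
    if (!is.null(sets)) {
      pr <- pathway_report(rc, sn, sets, literal_eq4 = config$literal_eq4)
      wpr_out[[conds[i]]] <- pr
      write_report_csv(pr, file.path(outdir, paste0("wpr_", conds[i], ".csv")))
    }
  }
  run_manifest(inputs, config, outdir)
  invisible(list(tables = tables, comparison = comparison,
                 regulation = regulation, wpr = wpr_out))
}

#' Two-cell-line crossed perturbation experiment
#'
#' Desk-scale analogue of the transfection validation design: two
#' simulated cell lines share their transcriptome parameters, but four
#' target genes are crossed — two are tightly controlled and highly
#' coordinated ("strong") in line A and ordinary in line B, two the
#' reverse — while all four share the same baseline expression.  Each
#' target is perturbed by `delta` log2 units in each line and the
#' transcriptome-wide WPR of the perturbation measured; the report says
#' whether the line with the higher GCH for a gene also shows the
#' larger WPR.
#'
#' @param seed root seed.
#' @param delta log2 perturbation strength (default 2 = 4-fold).
#' @param n_genes transcriptome size per line.
#' @param lambda replicates per line.
#' @return [concordance_report()] result plus `targets`.
#' @export
crossed_perturbation_experiment <- function(seed, delta = 2, n_genes = 300L,
                                            lambda = 4L) {
  ## the contrast is deliberately strong, and both variants are probed
  ## redundantly so the REV estimates (3 df per probe at lambda = 4) do
  ## not flip the GCH ordering by sampling luck
  strong <- function(i) list(index = i, mean_multiplier = 4,
                             residual_sd = 0.02, loading = 0.8,
                             probe_count = 12L)
  weak <- function(i) list(index = i, mean_multiplier = 4,
                           residual_sd = 0.5, loading = 0.05,
                           probe_count = 12L)
  cfg_a <- synthetic_config(n_genes = n_genes, lambda = lambda, seed = seed,
                            planted = list(strong(1L), strong(2L),
                                           weak(3L), weak(4L)))
  cfg_b <- synthetic_config(n_genes = n_genes, lambda = lambda, seed = seed,
                            planted = list(weak(1L), weak(2L),
                                           strong(3L), strong(4L)))
  targets <- sprintf("G%04d", 1:4)
  measure <- function(cfg, stream, label) {
    d <- generate_dataset(cfg, label, noise_stream = stream)
    d <- normalize_median(filter_probes(d)$dataset)
    summary <- res_per_gene(rev_per_gene(d))
    profile <- log2_correlation_rows(d)
    gch <- rank_genes(gch_scores(summary, profile))
    mu <- stats::setNames(summary$genes$mu, summary$genes$gene_id)
    wprs <- vapply(targets, function(g) {
      pert <- simulate_perturbation(d, g, delta)
      sp <- res_per_gene(rev_per_gene(pert))
      rc <- regulation_calls(sp, summary, pert, d)
      as.numeric(wpr(rc, mu, summary$genes$gene_id))
    }, numeric(1))
    list(gch = stats::setNames(gch$GCH[match(targets, gch$gene_id)], targets),
         wpr = wprs)
  }
  a <- measure(cfg_a, 2L, "lineA")
  b <- measure(cfg_b, 3L, "lineB")
  out <- concordance_report(a$gch, b$gch, a$wpr, b$wpr)
  out$targets <- targets
  out
}
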