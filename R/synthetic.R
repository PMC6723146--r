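#' Configure the synthetic probe-level data generator
#'
#' Emulates a two-colour expression array experiment with lambda
#' biological replicas: redundant probes per transcript (1..28),
#' log-normal gene abundance, heterogeneous per-gene replicate noise and
#' a shared latent replicate factor that induces coexpression.  On the
#' log2 scale, gene i in replicate j is
#' \deqn{b_i + \sigma_i\,(w_i F_j + \sqrt{1 - w_i^2}\, z_{ij})}
#' with \eqn{F_j} standard normal per replicate: the loading
#' \eqn{w_i \in [-1,1]} is the (signed) fraction of the gene's replicate
#' SD \eqn{\sigma_i} carried by the shared factor — loaded genes draw a
#' random sign, so partners fluctuate in phase or in antiphase — and a
#' gene's total variability is \eqn{\sigma_i} regardless of loading,
#' while the population correlation of two loaded genes is
#' \eqn{w_i w_j}.  Probe k
#' adds a fixed affinity offset (constant across replicates, which
#' therefore never enters the CV) plus a small per-measurement noise.
#'
#' A planted master regulator gets a large baseline, tiny residual SD
#' and high loading, making it simultaneously top-stability and
#' top-coordination; it is probed with high redundancy so its REV is
#' estimated with many degrees of freedom.
#'
#' @param n_genes number of genes.
#' @param lambda biological replicas (>= 4).
#' @param probe_count_probs probabilities for probe redundancy R = 1..28
#'   (default geometric-like decay, mean about 1.8 probes/gene).
#' @param baseline_log2_sd SD of log2 baseline abundance across genes.
#' @param loaded_fraction fraction of background genes loaded on the
#'   shared factor.
#' @param loading_range loading range for loaded background genes.
#' @param residual_sd_range per-gene replicate log2 SD range for
#'   background genes.
#' @param probe_noise_sd per-measurement probe noise SD (log2).
#' @param probe_offset_sd probe affinity offset SD (log2, fixed across
#'   replicates).
#' @param planted `NULL`, a list (one planted gene) or list of lists,
#'   each with `index`, `mean_multiplier`, `residual_sd`, `loading`,
#'   `probe_count`.
#' @param seed root seed; every random draw derives from it via
#'   per-gene stream splitting, so adding genes does not reshuffle
#'   existing ones.
#' @return `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 500L, lambda = 4L,
                             probe_count_probs = 0.45^(0:27),
                             baseline_log2_sd = 1.5,
                             loaded_fraction = 0.3,
                             loading_range = c(0.2, 0.8),
                             residual_sd_range = c(0.2, 0.6),
                             probe_noise_sd = 0.01,
                             probe_offset_sd = 0.25,
                             planted = list(index = 1L, mean_multiplier = 20,
                                            residual_sd = 0.02, loading = 0.8,
                                            probe_count = 12L),
                             seed = 1L) {
  if (lambda < 4) stop("validation error: lambda must be >= 4")
  if (n_genes < 2) stop("validation error: n_genes must be >= 2")
  if (length(probe_count_probs) != 28 || any(probe_count_probs < 0) ||
      sum(probe_count_probs) <= 0)
    stop("validation error: probe_count_probs must be 28 non-negative weights")
  if (any(c(probe_noise_sd, probe_offset_sd, residual_sd_range,
            baseline_log2_sd) < 0))
    stop("validation error: SDs must be >= 0")
  if (loaded_fraction < 0 || loaded_fraction > 1 ||
      any(loading_range < 0) || any(loading_range > 1))
    stop("validation error: fractions/loadings must lie in [0, 1]")
  if (!is.null(planted) && !is.null(planted$index))
    planted <- list(planted)
  for (p in planted) {
    if (is.null(p$index) || p$index < 1 || p$index > n_genes)
      stop("validation error: planted index out of range")
    if (p$loading < 0 || p$loading > 1 || p$residual_sd < 0)
      stop("validation error: invalid planted parameters")
    if (p$probe_count < 1 || p$probe_count > 28)
      stop("validation error: planted probe_count must be in 1..28")
  }
  structure(list(n_genes = as.integer(n_genes), lambda = as.integer(lambda),
                 probe_count_probs = probe_count_probs / sum(probe_count_probs),
                 baseline_log2_sd = baseline_log2_sd,
                 loaded_fraction = loaded_fraction,
                 loading_range = loading_range,
                 residual_sd_range = residual_sd_range,
                 probe_noise_sd = probe_noise_sd,
                 probe_offset_sd = probe_offset_sd,
                 planted = planted, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Gene symbol of a planted master regulator
#' @param config `SyntheticConfig`.
#' @param which planted entry (default first).
#' @return gene symbol, e.g. `"G0001"`.
#' @export
planted_gene_id <- function(config, which = 1L) {
  if (is.null(config$planted)) stop("no planted gene in this config")
  sprintf("G%04d", config$planted[[which]]$index)
}

## deterministic stream splitting: one substream per (gene, stream) pair
derive_seed <- function(seed, gene, stream) {
  M <- 2147483647
  s <- (as.double(seed) %% M) * 48271 + as.double(gene) * 16807 +
    as.double(stream) * 69621
  as.integer(s %% M)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

## per-gene generative parameters (stream 1; shared across conditions)
realize_params <- function(config) {
  n <- config$n_genes
  R <- integer(n); b <- numeric(n); w <- numeric(n); sigma <- numeric(n)
  offsets <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i, 1L))
    R[i] <- sample.int(28L, 1L, prob = config$probe_count_probs)
    b[i] <- stats::rnorm(1, 0, config$baseline_log2_sd)
    loaded <- stats::runif(1) < config$loaded_fraction
    ## loading sign is random: coexpressed partners fluctuate in phase or
    ## in antiphase, and the factor's net pull on the per-replicate median
    ## cancels instead of being re-injected by normalisation
    w[i] <- if (loaded)
      sample(c(-1, 1), 1) *
        stats::runif(1, config$loading_range[1], config$loading_range[2]) else 0
    sigma[i] <- stats::runif(1, config$residual_sd_range[1],
                             config$residual_sd_range[2])
    offsets[[i]] <- stats::rnorm(28, 0, config$probe_offset_sd)
  }
  for (p in config$planted) {
    i <- p$index
    R[i] <- as.integer(p$probe_count)
    b[i] <- b[i] + log2(p$mean_multiplier)
    w[i] <- p$loading
    sigma[i] <- p$residual_sd
  }
  list(R = R, b = b, w = w, sigma = sigma, offsets = offsets,
       gene_id = sprintf("G%04d", seq_len(n)))
}

#' Generate a synthetic probe-level dataset
#'
#' Draws one condition under the configured generative model and
#' returns a raw [expression_dataset()] (run [filter_probes()] and
#' [normalize_median()] as for real data).  Deterministic under a fixed
#' config; `noise_stream` selects an independent replicate-noise
#' realisation while keeping the per-gene generative parameters fixed,
#' which is how paired conditions share a transcriptome.
#'
#' @param config `SyntheticConfig`.
#' @param condition condition label.
#' @param noise_stream integer stream id (>= 2) for the noise draws.
#' @param baseline_shift optional named vector (gene symbol -> log2
#'   shift) applied to baselines, used for planted regulation.
#' @return raw `ExpressionDataset` (foreground intensities in arbitrary
#'   fluorescence units, background 0, all pixels ok).
#' @export
generate_dataset <- function(config, condition = "synthetic",
                             noise_stream = 2L, baseline_shift = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (noise_stream < 2L) stop("noise_stream must be >= 2 (1 holds parameters)")
  par <- realize_params(config)
  lam <- config$lambda
  with_preserved_rng({
    set.seed(derive_seed(config$seed, 0L, noise_stream))
    Fj <- stats::rnorm(lam)
    blocks <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      set.seed(derive_seed(config$seed, i, noise_stream))
      z <- stats::rnorm(lam)
      Ri <- par$R[i]
      eta <- matrix(stats::rnorm(Ri * lam, 0, config$probe_noise_sd), Ri, lam)
      shift <- if (!is.null(baseline_shift) &&
                   par$gene_id[i] %in% names(baseline_shift))
        baseline_shift[[par$gene_id[i]]] else 0
      gene_log2 <- par$b[i] + shift +
        par$sigma[i] * (par$w[i] * Fj + sqrt(1 - par$w[i]^2) * z)
      blocks[[i]] <- matrix(rep(gene_log2, each = Ri), Ri, lam) +
        par$offsets[[i]][seq_len(Ri)] + eta
    }
  })
  log2mat <- do.call(rbind, blocks)
  fg <- 1000 * 2^log2mat
  n_probes <- nrow(fg)
  gene <- rep(par$gene_id, par$R)
  probe_id <- paste0(gene, "_p",
                     unlist(lapply(par$R, seq_len), use.names = FALSE))
  probes <- data.frame(probe_id = probe_id, gene_id = gene,
                       is_control = FALSE, stringsAsFactors = FALSE)
  expression_dataset(probes, fg, matrix(0, n_probes, lam),
                     matrix(TRUE, n_probes, lam), lam, condition)
}

#' Generate a pair of conditions with planted regulation
#'
#' Condition B clones A's generative parameters (same genes, probes,
#' baselines, loadings and noise SDs) but draws independent replicate
#' noise and multiplies a random gene subset's baseline by fold changes
#' from `effect_law`.  Ground-truth labels are returned for
#' sensitivity/false-positive accounting.
#'
#' @param config `SyntheticConfig`.
#' @param regulated_fraction fraction of genes regulated in B.
#' @param effect_law function(n) returning n linear fold changes
#'   (values < 1 mean down-regulation); default 2x up or down with
#'   equal probability.
#' @return list with `a`, `b` (raw datasets, conditions "normal" /
#'   "cancer") and `truth` (data.frame `gene_id`, `regulated`, `fold`).
#' @export
generate_paired_conditions <- function(config, regulated_fraction = 0.1,
                                       effect_law = function(n)
                                         2^sample(c(-1, 1), n, replace = TRUE)) {
  if (regulated_fraction < 0 || regulated_fraction > 1)
    stop("validation error: regulated_fraction must be in [0, 1]")
  n <- config$n_genes
  gene_id <- sprintf("G%04d", seq_len(n))
  n_reg <- round(regulated_fraction * n)
  fold <- rep(1, n)
  if (n_reg > 0) {
    with_preserved_rng({
      set.seed(derive_seed(config$seed, 0L, 5L))
      idx <- sample.int(n, n_reg)
      fold[idx] <- effect_law(n_reg)
    })
  }
  shift <- stats::setNames(log2(fold), gene_id)
  a <- generate_dataset(config, "normal", noise_stream = 2L)
  b <- generate_dataset(config, "cancer", noise_stream = 3L,
                        baseline_shift = shift[fold != 1])
  list(a = a, b = b,
       truth = data.frame(gene_id = gene_id, regulated = fold != 1,
                          fold = fold, stringsAsFactors = FALSE))
}

#' Simulate an expression perturbation of one gene
#'
#' Shifts the target's log2 expression by `delta` and propagates the
#' shift to every other gene along the regression slope of its log2
#' expression on the target's: gene j moves by
#' \eqn{\rho_{tj}\,\delta\,(s_j/s_t)} with s the replicate SD of log2
#' gene-level expression.  This propagation rule is the package's own
#' minimal model of a transfection experiment — it makes the
#' GCH-versus-consequence claim testable in software; it is not an
#' empirical result.
#'
#' Propagated shifts are clamped to ±30 log2 units (a nine-orders-of-
#' magnitude fold change, far beyond any biological response): the slope
#' \eqn{s_j/s_t} is unbounded when the target is very tightly
#' controlled, and unclamped shifts overflow the linear intensity scale.
#'
#' @param dataset filtered (normalised) dataset.
#' @param target gene symbol to perturb.
#' @param delta log2 shift, non-zero.
#' @return The dataset with `expr` shifted (probe-level, all replicates
#'   of a gene scaled by its 2^shift).
#' @export
simulate_perturbation <- function(dataset, target, delta) {
  if (delta == 0) stop("simulate_perturbation: delta must be non-zero")
  L <- log2(gene_expression(dataset))
  if (!target %in% rownames(L))
    stop("simulate_perturbation: unknown target ", target)
  ctr <- L - rowMeans(L)
  s <- sqrt(rowSums(ctr^2) / (ncol(L) - 1))
  if (s[target] == 0)
    stop("simulate_perturbation: target has zero replicate variance")
  rho <- as.vector(ctr %*% ctr[target, ]) / (s * s[target] * (ncol(L) - 1))
  rho[s == 0] <- 0
  shift <- rho * delta * s / s[target]
  shift[!is.finite(shift)] <- 0
  shift <- pmin(pmax(shift, -30), 30)
  names(shift) <- rownames(L)
  shift[target] <- delta
  keep <- !dataset$probes$is_control
  fac <- rep(1, nrow(dataset$probes))
  fac[keep] <- 2^shift[dataset$probes$gene_id[keep]]
  dataset$expr <- dataset$expr * fac
  dataset
}
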