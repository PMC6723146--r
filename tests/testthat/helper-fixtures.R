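# Fixtures are built in code: linear intensity matrices with background 0
# and all pixels ok, so QC passes everything through with net = fg.

make_probe_dataset <- function(values, genes, condition = "test",
                               controls = rep(FALSE, nrow(values)),
                               ok = NULL, bg = NULL) {
  values <- as.matrix(values)
  lambda <- ncol(values)
  if (is.null(ok)) ok <- matrix(TRUE, nrow(values), lambda)
  if (is.null(bg)) bg <- matrix(0, nrow(values), lambda)
  probes <- data.frame(probe_id = sprintf("p%03d", seq_len(nrow(values))),
                       gene_id = genes, is_control = controls,
                       stringsAsFactors = FALSE)
  expression_dataset(probes, values, bg, ok, lambda, condition)
}

as_filtered <- function(x) filter_probes(x)$dataset

# single probe per gene, rows given on the log2 scale
make_log2_dataset <- function(log2rows, genes = sprintf("g%02d", seq_len(nrow(log2rows))),
                              condition = "test") {
  as_filtered(make_probe_dataset(2^as.matrix(log2rows), genes, condition))
}

random_probe_dataset <- function(n_genes, lambda = 4, max_probes = 3,
                                 seed = 1, condition = "test") {
  set.seed(seed)
  R <- sample.int(max_probes, n_genes, replace = TRUE)
  genes <- rep(sprintf("g%02d", seq_len(n_genes)), R)
  vals <- matrix(2^stats::rnorm(length(genes) * lambda, 6, 1),
                 length(genes), lambda)
  make_probe_dataset(vals, genes, condition)
}

## independent textbook implementations used as oracles ---------------------

oracle_c <- function(r, eps = 0.05)
  (sqrt(r / stats::qchisq(1 - eps / 2, r)) +
     sqrt(r / stats::qchisq(eps / 2, r))) / 2

oracle_rev <- function(dataset, eps = 0.05) {
  keep <- !dataset$probes$is_control
  genes <- sort(unique(dataset$probes$gene_id[keep]))
  sapply(genes, function(g) {
    rows <- which(keep & dataset$probes$gene_id == g)
    cvs <- sapply(rows, function(i) {
      v <- dataset$expr[i, ]
      stats::sd(v) / mean(v)
    })
    R <- length(rows)
    oracle_c(dataset$lambda * R - 1, eps) * sqrt(mean(cvs^2))
  })
}

oracle_cp <- function(dataset) {
  L <- log2(gene_expression(dataset))
  n <- nrow(L)
  cp <- numeric(n)
  for (i in seq_len(n)) {
    r2 <- sapply(setdiff(seq_len(n), i),
                 function(j) stats::cor(L[i, ], L[j, ])^2)
    cp[i] <- mean(r2)
  }
  stats::setNames(cp, rownames(L))
}
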