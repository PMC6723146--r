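#' Construct an ExpressionDataset
#'
#' The container shared by every analysis stage: probe annotation plus
#' probe-by-replicate intensity matrices for one condition.  Raw datasets
#' carry foreground/background intensities and pixel-quality flags;
#' [filter_probes()] populates the net `expr` matrix and
#' [normalize_median()] brings it to median units (the per-replicate
#' median of gene-level expression equals 1).
#'
#' @param probes data.frame with columns `probe_id`, `gene_id`,
#'   `is_control`.  `probe_id` must be unique.
#' @param fg,bg numeric matrices, probes x lambda, foreground and
#'   background fluorescence (arbitrary units, >= 0).
#' @param ok logical matrix, probes x lambda; `FALSE` flags saturated or
#'   corrupted pixels.
#' @param lambda integer number of biological replicas; at least 4.
#' @param condition condition label.
#' @param expr optional probes x lambda matrix of net intensities
#'   (normally left to [filter_probes()]).
#' @param normalized logical; whether `expr` is in median units.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `condition`, `lambda`, `probes`, `fg`, `bg`, `ok`, `expr`,
#'   `normalized` and `gene_index` (gene symbol -> row indices of its
#'   probes; controls are not indexed).
#' @export
expression_dataset <- function(probes, fg, bg, ok, lambda,
                               condition = "condition",
                               expr = NULL, normalized = FALSE) {
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 4L)
    stop("validation error: lambda must be an integer >= 4, got ", lambda)
  req <- c("probe_id", "gene_id", "is_control")
  miss <- setdiff(req, names(probes))
  if (length(miss))
    stop("format error: missing probe column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(probes$probe_id))
    stop("format error: duplicate probe_id: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]), collapse = ", "))
  n <- nrow(probes)
  for (m in list(fg = fg, bg = bg, ok = ok)) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != lambda)
      stop("validation error: intensity/flag matrices must be ", n, " x ", lambda)
  }
  if (any(fg < 0, na.rm = TRUE) || any(bg < 0, na.rm = TRUE))
    stop("validation error: negative intensities")
  obj <- structure(
    list(condition = as.character(condition), lambda = lambda,
         probes = probes[, req], fg = fg, bg = bg,
         ok = matrix(as.logical(ok), n, lambda),
         expr = expr, normalized = isTRUE(normalized),
         gene_index = NULL),
    class = "ExpressionDataset")
  obj$gene_index <- build_gene_index(obj)
  obj
}

build_gene_index <- function(x) {
  keep <- !x$probes$is_control
  split(which(keep), x$probes$gene_id[keep])
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d probes, %d genes, lambda = %d\n",
              x$condition, nrow(x$probes), length(x$gene_index), x$lambda))
  cat(sprintf("  filtered: %s, normalized: %s\n",
              !is.null(x$expr), x$normalized))
  invisible(x)
}

#' Number of genes indexed in a dataset
#' @param x ExpressionDataset.
#' @return Integer count of distinct non-control gene symbols.
#' @export
n_genes <- function(x) length(x$gene_index)

#' Gene-level expression matrix
#'
#' Averages each gene's probes within every replicate, giving the
#' genes x lambda matrix on which fold changes, Welch tests and the
#' coordination analysis operate.
#'
#' @param x ExpressionDataset that has been through [filter_probes()].
#' @return Numeric matrix, one row per gene (rownames are gene symbols),
#'   one column per replicate.
#' @export
gene_expression <- function(x) {
  if (is.null(x$expr))
    stop("dataset has no net expression; run filter_probes() first")
  keep <- !x$probes$is_control
  g <- x$probes$gene_id[keep]
  m <- rowsum(x$expr[keep, , drop = FALSE], g)
  m / as.vector(table(g)[rownames(m)])
}

#' Read a probe-level expression table
#'
#' Expects a TSV with header columns `probe_id`, `gene_id`, `is_control`,
#' then `fg_1..fg_lambda`, `bg_1..bg_lambda`, `ok_1..ok_lambda`.  No
#' filtering is performed here; all rows are loaded verbatim.  Gene
#' symbols are case-sensitive and taken as-is.
#'
#' @param path file path.
#' @param lambda replicate count (>= 4); must match the column layout.
#' @param condition condition label, default the file base name.
#' @return [expression_dataset()].
#' @export
read_probe_table <- function(path, lambda,
                             condition = sub("\\.[^.]*$", "", basename(path))) {
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 4L)
    stop("validation error: lambda must be >= 4, got ", lambda)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "gene_id", "is_control",
            paste0("fg_", seq_len(lambda)), paste0("bg_", seq_len(lambda)),
            paste0("ok_", seq_len(lambda)))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  num <- function(cols, what) {
    m <- suppressWarnings(
      vapply(cols, function(cl) as.numeric(tab[[cl]]), numeric(nrow(tab))))
    m <- matrix(m, nrow = nrow(tab))
    bad <- which(rowSums(is.na(m)) > 0)
    if (length(bad))
      stop("parse error: non-numeric ", what, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    m
  }
  fg <- num(paste0("fg_", seq_len(lambda)), "foreground intensity")
  bg <- num(paste0("bg_", seq_len(lambda)), "background intensity")
  ok <- matrix(as.logical(type.convert(
    unlist(tab[paste0("ok_", seq_len(lambda))], use.names = FALSE),
    as.is = TRUE)), nrow = nrow(tab))
  ctrl <- as.logical(type.convert(tab$is_control, as.is = TRUE))
  probes <- data.frame(probe_id = tab$probe_id, gene_id = tab$gene_id,
                       is_control = ctrl, stringsAsFactors = FALSE)
  expression_dataset(probes, fg, bg, ok, lambda, condition)
}

#' Write a probe-level expression table
#'
#' Inverse of [read_probe_table()]; raw fg/bg/ok columns are written so
#' that the table round-trips.
#'
#' @param x ExpressionDataset (raw or filtered; raw matrices are written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(x, path) {
  lam <- x$lambda
  tab <- data.frame(x$probes, stringsAsFactors = FALSE)
  add <- function(prefix, m) {
    m <- as.data.frame(m)
    names(m) <- paste0(prefix, "_", seq_len(lam))
    m
  }
  tab <- cbind(tab, add("fg", x$fg), add("bg", x$bg),
               add("ok", x$ok))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member...`.
#' Duplicate members within a set are dropped with a warning giving the
#' total duplicate count.
#'
#' @param path file path.
#' @return A named list of gene sets, each a list with `set_id`, `name`
#'   and `members` (unique, non-empty character vector).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ndup <- 0L
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop("format error: GMT line ", i,
           " has fewer than 3 fields (set, description, members...)")
    members <- f[-(1:2)]
    ndup <- ndup + (length(members) - length(unique(members)))
    sets[[i]] <- list(set_id = f[[1]], name = f[[2]],
                      members = unique(members))
  }
  if (ndup > 0)
    warning(ndup, " duplicate member(s) removed across gene sets")
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  sets
}

#' Write a result table to CSV
#'
#' Numeric columns are rounded to 6 significant digits; the column order
#' of the input is preserved so that [read_report_csv()] round-trips the
#' table.
#'
#' @param records non-empty data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("write_report_csv: records must be a non-empty data.frame")
  out <- records
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read back a CSV written by [write_report_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
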