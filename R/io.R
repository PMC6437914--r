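# Delimiter sniffing is deliberately limited to tab and comma;
# anything else is an error, never a silent guess.
.sniff_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("empty file: ", path)
  if (grepl("\t", first)) return("\t")
  if (grepl(",", first)) return(",")
  stop("cannot determine delimiter (tab or comma) of ", path)
}

#' Read a per-gene statistics table
#'
#' Reads a TSV or CSV with required columns `gene_id`, `effect`, `se`,
#' `df` (extra columns are passed through untouched). Rows whose `se` is
#' not a positive finite number, or with any non-finite required value, are
#' dropped with a warning reporting the count; duplicated gene ids are an
#' error.
#'
#' @param path File path; delimiter (tab or comma) is detected from the
#'   header line. Lines starting with `#` are ignored.
#' @return A data.frame usable by [confects()] and [rank_genes()], with
#'   the number of dropped rows in `attr(, "n_dropped")`.
#' @export
read_stats_table <- function(path) {
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "effect", "se", "df")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("effect", "se", "df")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  bad <- !is.finite(tab$effect) | !is.finite(tab$se) | tab$se <= 0 |
    !is.finite(tab$df) | tab$df <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) dropped (non-finite values or se/df <= 0)")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (anyDuplicated(tab$gene_id))
    stop("duplicated gene ids in ", path)
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- sum(bad)
  tab
}

#' Read a gene-by-sample log-expression matrix
#'
#' First column holds gene ids, header holds sample names; tab- or
#' comma-delimited.
#'
#' @param path File path.
#' @return Numeric matrix with gene ids as row names.
#' @export
read_expression_matrix <- function(path) {
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3) stop("expected gene id column plus >= 2 samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated gene ids in ", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a two-column sample sheet
#'
#' Columns `sample` and `group` (header required); used to assign matrix
#' columns to the two groups.
#'
#' @param path File path.
#' @return Named character vector: group per sample.
#' @export
read_sample_sheet <- function(path) {
  sep <- .sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(tab)))
    stop("sample sheet needs columns 'sample' and 'group'")
  stats::setNames(as.character(tab$group), as.character(tab$sample))
}

#' Write a ranked confects table to CSV
#'
#' Writes columns `rank`, `gene_id`, `confect`, `effect`, `se`, `df`,
#' `p_zero` in rank order; genes without a confect get an empty field. By
#' default a provenance header (package version, parameters) is written as
#' `#`-prefixed comment lines; disable it for strict-CSV consumers.
#'
#' @param object A `confects` fit.
#' @param path Output path.
#' @param provenance Write the `#` comment header (default TRUE).
#' @return `path`, invisibly.
#' @export
write_ranked_csv <- function(object, path, provenance = TRUE) {
  stopifnot(inherits(object, "confects"))
  tab <- object$table[, c("rank", "gene_id", "confect", "effect", "se",
                          "df", "p_zero")]
  con <- file(path, "w")
  on.exit(close(con))
  if (provenance) {
    writeLines(c(
      paste0("# confects ", as.character(utils::packageVersion("confects"))),
      paste0("# fdr=", format(object$fdr), " step=", format(object$step),
             " max_e=", format(object$max_e)),
      paste0("# n_gene=", object$n_gene, " n_with_confect=",
             object$n_with_confect)), con)
  }
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 15,
                                                  format = "g"))
  lines <- paste(tab$rank, tab$gene_id, fmt(tab$confect), fmt(tab$effect),
                 fmt(tab$se), fmt(tab$df), fmt(tab$p_zero), sep = ",")
  writeLines(c("rank,gene_id,confect,effect,se,df,p_zero", lines), con)
  invisible(path)
}

#' Write a benchmark report to CSV
#'
#' Tidy long format: one row per (section, method, k-or-threshold, metric).
#'
#' @param bench A [run_benchmark()] result.
#' @param path Output path.
#' @param provenance Write a `#` comment header (default TRUE).
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(bench, path, provenance = TRUE) {
  stopifnot(inherits(bench, "sim_benchmark"))
  cfg <- bench$config
  tk <- bench$topk
  rows <- data.frame(section = "topk", method = tk$method, at = tk$k,
                     metric = "correct", value = tk$correct)
  rows <- rbind(rows,
                data.frame(section = "topk", method = tk$method, at = tk$k,
                           metric = "fallback_share",
                           value = tk$fallback_share))
  if (!is.null(bench$rates)) {
    rt <- bench$rates
    for (metric in c("fdr", "fcr", "n_true", "n_discoveries")) {
      rows <- rbind(rows, data.frame(section = "rates", method = rt$method,
                                     at = rt$threshold, metric = metric,
                                     value = rt[[metric]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (provenance) {
    writeLines(paste0(
      "# confects ", as.character(utils::packageVersion("confects")),
      " simulate preset=", cfg$preset, " n_gene=", cfg$n_gene,
      " n_rep=", cfg$n_rep, " n_runs=", cfg$n_runs, " seed=", cfg$seed), con)
  }
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
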