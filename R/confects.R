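#' Benjamini-Hochberg largest selected set
#'
#' Returns the largest gene set S satisfying the self-referential condition
#' \eqn{S = \{i : p_i \le |S| q / n\}}, which is exactly the classical
#' Benjamini-Hochberg step-up selection at level `q`: sort the p-values
#' ascending, find the largest k with \eqn{p_{(k)} \le k q / n}, and select
#' those k genes. `n_gene` is the size of the full gene universe and may
#' exceed the number of p-values supplied when some genes are known a priori
#' not to be selectable; the correction is always relative to `n_gene`.
#'
#' @param p P-values in \[0, 1\].
#' @param q Target false discovery rate, in (0, 1).
#' @param n_gene Size of the gene universe (default: `length(p)`).
#'
#' @return Integer indices (ascending) of the selected genes; empty when
#'   nothing is selected.
#'
#' @examples
#' bh_select(c(0.001, 0.02, 0.04, 0.9), q = 0.05)  # selects genes 1 and 2
#' @export
bh_select <- function(p, q, n_gene = length(p)) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1] with no missing values")
  if (length(q) != 1 || q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  if (n_gene < length(p)) stop("'n_gene' must be at least length(p)")
  m <- length(p)
  if (m == 0) return(integer(0))
  o <- order(p)
  ok <- p[o] <= seq_len(m) * q / n_gene
  k <- if (any(ok)) max(which(ok)) else 0L
  sort(o[seq_len(k)])
}

#' Confident effect sizes from a p-value function
#'
#' The engine behind [confects()], operating on an arbitrary threshold-test
#' p-value function rather than on TREAT specifically. `pfun(e)` must return
#' one p-value per gene for the null hypothesis that the gene's absolute
#' effect is at most `e`, non-decreasing in `e`; `NA` marks a gene with no
#' usable statistics.
#'
#' The scan visits thresholds e = 0, step, 2 step, ... and at each finds the
#' largest Benjamini-Hochberg set S(e) with \eqn{p_i(e) \le |S(e)| q /
#' n_{gene}}. Because every \eqn{p_i(e)} is non-decreasing in e, these sets
#' nest, and the scan only re-tests the genes still selected. The confect of
#' gene i is the largest e with \eqn{i \in S(e)}, signed by the sign of the
#' estimated effect. The scan stops when S(e) is empty, or at `max_e`
#' (with a warning; remaining confects are truncated at `max_e`).
#'
#' Ordering of the result: decreasing absolute confect; genes with equal
#' confect by their p-value at the first threshold at which they dropped
#' out of the selection; genes never selected come after all genes with a
#' confect, in order of p(0); genes with unusable statistics last. Remaining
#' ties break on gene id, so the order is a strict total order.
#'
#' @param pfun Function of one threshold returning a p-value per gene.
#' @param effect Estimated signed effect per gene (signs the confects).
#' @param gene_id Gene identifiers (default `names(effect)` or an index).
#' @param fdr Target false discovery rate q, in (0, 1).
#' @param step Grid spacing of the threshold scan, in effect-size units.
#' @param max_e Safety cap on the scan.
#'
#' @return A list with `abs_confect` (per gene, `NA` when none),
#'   `dropout_p`, `order` (indices, best first), `p_zero`, and `capped`.
#' @export
confect_scan <- function(pfun, effect, gene_id = NULL,
                         fdr = 0.05, step = 0.01, max_e = 30) {
  n_gene <- length(effect)
  if (n_gene < 1) stop("need at least one gene")
  if (length(fdr) != 1 || fdr <= 0 || fdr >= 1) stop("'fdr' must be in (0, 1)")
  if (length(step) != 1 || step <= 0) stop("'step' must be positive")
  if (is.null(gene_id)) gene_id <- names(effect)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(n_gene))

  p0 <- pfun(0)
  usable <- is.finite(p0)
  abs_c <- rep(NA_real_, n_gene)
  dropout_p <- p0

  sel <- integer(0)
  if (any(usable)) {
    idx <- which(usable)
    sel <- idx[bh_select(p0[idx], fdr, n_gene = n_gene)]
  }
  capped <- FALSE
  i <- 0L
  while (length(sel) > 0) {
    e <- i * step
    abs_c[sel] <- e
    if (e >= max_e) {
      capped <- TRUE
      warning("confect scan reached max_e = ", max_e,
              " with ", length(sel), " gene(s) still selected")
      break
    }
    i <- i + 1L
    e_next <- i * step
    p <- pfun(e_next)
    # step-up within the current set; the correction stays relative to n_gene,
    # which by nesting gives the same set as a full BH pass
    ps <- p[sel]
    o <- order(ps)
    ok <- ps[o] <= seq_along(ps) * fdr / n_gene
    k <- if (any(ok)) max(which(ok)) else 0L
    keep <- sel[sort(o[seq_len(k)])]
    dropped <- setdiff(sel, keep)
    dropout_p[dropped] <- p[dropped]
    sel <- keep
  }

  has <- !is.na(abs_c)
  id_key <- xtfrm(gene_id)
  ord <- integer(0)
  if (any(has))
    ord <- which(has)[order(-abs_c[has], dropout_p[has], id_key[has])]
  rest <- which(!has & usable)
  if (length(rest)) ord <- c(ord, rest[order(p0[rest], id_key[rest])])
  bad <- which(!usable)
  if (length(bad)) ord <- c(ord, bad[order(id_key[bad])])

  list(abs_confect = abs_c, dropout_p = dropout_p, order = ord,
       p_zero = p0, capped = capped)
}

#' Rank genes by confident log2 fold change
#'
#' Computes per-gene "confects" (confident effect sizes): signed lower
#' confidence bounds on log2 fold change that hold simultaneously at a
#' target false discovery rate. The bound for each gene is the largest
#' threshold e at which the gene remains in the Benjamini-Hochberg selection
#' applied to TREAT p-values \eqn{p_i(e)} (see [treat_pvalue()]), signed by
#' the direction of the estimated change. Selecting all genes with
#' `|confect| >= e`, for any e, yields exactly the TREAT + BH discovery set
#' at threshold e and FDR `fdr`, and the reported bounds for any such
#' selection have a controlled false coverage-statement rate.
#'
#' The method can be applied to a precomputed per-gene statistics table
#' (columns `gene_id`, `effect`, `se`, `df`) or directly to a two-group
#' log2-expression matrix, in which case moderated statistics are computed
#' with [gene_stats()] first.
#'
#' @param x A data.frame of per-gene statistics, or a genes-by-samples
#'   numeric matrix of log2 expression values.
#' @param ... Passed between methods.
#'
#' @return An object of class `confects`: a list with `table` (columns
#'   `rank`, `index`, `gene_id`, `confect`, `effect`, `se`, `df`, `p_zero`;
#'   one row per gene, best first; `confect` is `NA` for genes given no
#'   bound), `n_with_confect`, `fdr`, `step`, `max_e`, `capped`, `n_gene`.
#'
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 8), 100, dimnames = list(paste0("g", 1:100), NULL))
#' x[1:5, 5:8] <- x[1:5, 5:8] + 4   # five genes shifted by 4 log2 units
#' fit <- confects(x, group = rep(c("A", "B"), each = 4))
#' fit
#' @export
confects <- function(x, ...) UseMethod("confects")

#' @rdname confects
#' @param fdr Target false discovery rate, in (0, 1). Default 0.05.
#' @param step Grid spacing of the effect-size scan, in log2 units.
#'   Default 0.01.
#' @param max_e Safety cap on the scan, in log2 units.
#' @export
confects.data.frame <- function(x, fdr = 0.05, step = 0.01, max_e = 30, ...) {
  need <- c("gene_id", "effect", "se", "df")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$gene_id)) stop("gene ids must be unique")
  if (any(!is.finite(x$effect))) stop("'effect' must be finite")
  usable <- is.finite(x$se) & x$se > 0 & is.finite(x$df) & x$df > 0
  eff <- x$effect
  se <- x$se
  df <- x$df
  pfun <- function(e) {
    p <- rep(NA_real_, length(eff))
    if (any(usable))
      p[usable] <- treat_pvalue(eff[usable], se[usable], df[usable], e)
    p
  }
  sc <- confect_scan(pfun, eff, gene_id = x$gene_id,
                     fdr = fdr, step = step, max_e = max_e)
  sgn <- ifelse(eff < 0, -1, 1)
  tab <- data.frame(
    rank = seq_along(sc$order),
    index = sc$order,
    gene_id = x$gene_id[sc$order],
    confect = (sgn * sc$abs_confect)[sc$order],
    effect = eff[sc$order],
    se = se[sc$order],
    df = df[sc$order],
    p_zero = sc$p_zero[sc$order],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  out <- list(table = tab,
              n_with_confect = sum(!is.na(sc$abs_confect)),
              fdr = fdr, step = step, max_e = max_e,
              capped = sc$capped, n_gene = nrow(x),
              call = match.call())
  class(out) <- "confects"
  out
}

#' @rdname confects
#' @inheritParams gene_stats
#' @export
confects.matrix <- function(x, group, fdr = 0.05, step = 0.01, max_e = 30,
                            moderate = TRUE, ...) {
  stats <- gene_stats(x, group, moderate = moderate)
  out <- confects(stats, fdr = fdr, step = step, max_e = max_e)
  out$call <- match.call()
  out
}

#' @export
print.confects <- function(x, n = 10, ...) {
  cat("Confident effect sizes (target FDR ", format(x$fdr), ")\n", sep = "")
  cat(x$n_with_confect, " of ", x$n_gene,
      " genes given a confect; scan step ", format(x$step), "\n", sep = "")
  if (x$capped) cat("NOTE: scan capped at max_e = ", format(x$max_e), "\n",
                    sep = "")
  cat("\n")
  print(utils::head(x$table[, c("rank", "gene_id", "confect", "effect",
                                "se", "p_zero")], n),
        row.names = FALSE, digits = 4)
  if (nrow(x$table) > n) cat("... and", nrow(x$table) - n, "more genes\n")
  invisible(x)
}

#' @export
summary.confects <- function(object, thresholds = c(0, 0.5, 1, 1.5, 2), ...) {
  counts <- vapply(thresholds, function(e)
    length(selected_at(object, e)), integer(1))
  out <- list(fdr = object$fdr, n_gene = object$n_gene,
              n_with_confect = object$n_with_confect,
              selection_sizes = data.frame(threshold = thresholds,
                                           n_selected = counts))
  class(out) <- "summary.confects"
  out
}

#' @export
print.summary.confects <- function(x, ...) {
  cat("Confident effect sizes: ", x$n_with_confect, " of ", x$n_gene,
      " genes bounded at FDR ", format(x$fdr), "\n", sep = "")
  cat("Selection sizes by |confect| threshold:\n")
  print(x$selection_sizes, row.names = FALSE)
  invisible(x)
}

#' Named vector of signed confects
#'
#' @param object A `confects` fit.
#' @param ... Unused.
#' @return Signed confect per gene, in ranked order, named by gene id;
#'   `NA` for genes with no bound.
#' @export
coef.confects <- function(object, ...) {
  stats::setNames(object$table$confect, object$table$gene_id)
}

#' Effect-and-bound plot of the top-ranked genes
#'
#' For each of the top `n` genes, draws the estimated log2 fold change as a
#' point and the confect bound as a line from zero: the true LFC is claimed
#' (at the target FDR) to lie beyond the line's end, on the side of the
#' point.
#'
#' @param x A `confects` fit.
#' @param n Number of top genes to show.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.confects <- function(x, n = 30, ...) {
  tab <- utils::head(x$table, n)
  m <- nrow(tab)
  y <- rev(seq_len(m))
  xl <- range(0, tab$effect, tab$confect, na.rm = TRUE)
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xl, ylim = c(0.5, m + 0.5), yaxt = "n",
                 xlab = "log2 fold change", ylab = "",
                 main = paste0("Top ", m, " genes by confect (FDR ",
                               format(x$fdr), ")"), ...)
  graphics::abline(v = 0, col = "grey70")
  graphics::axis(2, at = y, labels = tab$gene_id, las = 2, cex.axis = 0.7)
  has <- !is.na(tab$confect)
  graphics::segments(0, y[has], tab$confect[has], y[has], lwd = 2,
                     col = "steelblue")
  graphics::points(tab$effect, y, pch = 19)
  invisible(x)
}

#' Genes selected at an effect-size threshold
#'
#' Returns the genes whose absolute confect is at least `e`; by
#' construction this set equals the Benjamini-Hochberg selection applied to
#' the TREAT p-values at threshold `e`. A threshold between grid points is
#' rounded up to the next grid point, so the selection never claims a gene
#' exceeds a threshold it was not tested at.
#'
#' @param object A `confects` fit.
#' @param e Non-negative effect-size threshold (log2 units).
#' @return Character vector of selected gene ids, in rank order.
#' @export
selected_at <- function(object, e) {
  stopifnot(inherits(object, "confects"), length(e) == 1, e >= 0)
  step <- object$step
  e_grid <- ceiling(e / step - 1e-9) * step
  tab <- object$table
  keep <- !is.na(tab$confect) & abs(tab$confect) >= e_grid - step * 1e-9
  tab$gene_id[keep]
}

#' Verify the false coverage-statement rate inequality
#'
#' For confects to act as FCR-controlled confidence bounds on any selection
#' of the form "all genes with |confect| >= e", every selected gene must
#' satisfy \eqn{p_i(|c_i|) \le n_{selected} q / n_{gene}}, where
#' n_selected counts the genes selected with it. By the nesting of the
#' scanned sets it suffices to check each gene against the tightest such
#' selection, the one at e = |c_i|. This function recomputes the TREAT
#' p-value of every bounded gene at its own confect and reports the
#' worst-case slack; it is a self-test that must pass on every fit.
#'
#' @param object A `confects` fit.
#' @param tol Numerical tolerance on the inequality.
#' @return A list with `ok` (all checks passed), `max_slack` (max of
#'   \eqn{p_i(|c_i|) - n_{sel} q / n_{gene}}; negative when satisfied
#'   strictly), and `violations` (data.frame of offending genes, if any).
#' @export
check_fcr <- function(object, tol = 1e-12) {
  stopifnot(inherits(object, "confects"))
  tab <- object$table
  has <- !is.na(tab$confect)
  if (!any(has))
    return(list(ok = TRUE, max_slack = -Inf,
                violations = tab[0, c("gene_id", "confect")]))
  tb <- tab[has, ]
  ac <- abs(tb$confect)
  # genes selected together with gene i at threshold |c_i|
  n_sel <- vapply(ac, function(v) sum(ac >= v - object$step * 1e-9),
                  integer(1))
  p_at <- treat_pvalue(tb$effect, tb$se, tb$df, ac)
  slack <- p_at - n_sel / object$n_gene * object$fdr
  bad <- slack > tol
  list(ok = !any(bad), max_slack = max(slack),
       violations = data.frame(gene_id = tb$gene_id[bad],
                               confect = tb$confect[bad],
                               p_at_confect = p_at[bad],
                               allowed = (n_sel / object$n_gene *
                                            object$fdr)[bad]))
}
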