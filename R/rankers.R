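#' Available gene-ranking methods
#'
#' The seven ranking strategies compared by the simulation benchmark:
#' ordinary moderated-t p-value; confect; inner end of an unadjusted 95%
#' confidence interval; inner end of a Bonferroni-corrected (5% FWER)
#' interval; TREAT p-value at LFC thresholds 1 and 5; and absolute
#' estimated LFC.
#'
#' @return Character vector of method ids accepted by [rank_genes()].
#' @export
ranking_methods <- function() {
  c("pvalue", "confect", "ci_inner", "fwer_ci_inner",
    "treat_p_1", "treat_p_5", "abs_lfc")
}

#' Rank genes by one of seven strategies
#'
#' Produces a total ordering of genes (best candidate first) from a
#' per-gene statistics table, by the chosen method:
#'
#' * `pvalue`: ascending two-sided moderated-t p-value (TREAT at threshold
#'   0); ties by absolute effect, larger first.
#' * `confect`: the ordering of [confects()] at FDR `fdr`. Genes given no
#'   confect fall back to p-value order and are flagged in `fallback`.
#' * `ci_inner`: descending inner end of a two-sided `level` confidence
#'   interval `x +/- t * se`. Intervals spanning zero have no inner bound;
#'   those genes rank after all others, by p-value (flagged `fallback`).
#' * `fwer_ci_inner`: as `ci_inner` with Bonferroni-corrected per-gene
#'   coverage `1 - (1 - level) / n_gene`, holding the family-wise error
#'   rate at `1 - level`.
#' * `treat_p_1`, `treat_p_5`: ascending TREAT p-value at LFC threshold 1
#'   or 5; ties by absolute effect.
#' * `abs_lfc`: descending absolute estimated effect; ties by standard
#'   error, smaller first.
#'
#' Any remaining ties break on gene id, so every method yields a
#' deterministic strict total order. Genes with unusable statistics
#' (missing or non-positive `se`) are ranked last by gene id under every
#' method.
#'
#' @param stats A data.frame with columns `gene_id`, `effect`, `se`, `df`
#'   (as produced by [gene_stats()] or [read_stats_table()]).
#' @param method One of [ranking_methods()].
#' @param fdr Target FDR for the `confect` method.
#' @param level Confidence level for the CI methods.
#'
#' @return An object of class `gene_ranking`: a list with `method`,
#'   `order` (integer indices into `stats`, best first), `bound` (signed
#'   per-gene bound for `confect` and the CI methods, `NA` where none;
#'   `NULL` otherwise), `fallback` (logical per gene: ranked only by the
#'   p-value fallback rule), and `n_gene`.
#' @export
rank_genes <- function(stats, method = ranking_methods(), fdr = 0.05,
                       level = 0.95) {
  method <- match.arg(method)
  n <- nrow(stats)
  usable <- is.finite(stats$se) & stats$se > 0 &
    is.finite(stats$df) & stats$df > 0
  eff <- stats$effect
  id_key <- xtfrm(stats$gene_id)
  p0 <- rep(NA_real_, n)
  p0[usable] <- treat_pvalue(eff[usable], stats$se[usable],
                             stats$df[usable], 0)
  bound <- NULL
  fallback <- rep(FALSE, n)

  order_with_bad_last <- function(keys_usable) {
    u <- which(usable)
    ord <- u[do.call(order, keys_usable)]
    c(ord, which(!usable)[order(id_key[!usable])])
  }

  if (method == "pvalue") {
    ord <- order_with_bad_last(list(p0[usable], -abs(eff[usable]),
                                    id_key[usable]))
  } else if (method == "confect") {
    fit <- confects(stats, fdr = fdr)
    ord <- fit$table$index
    bound <- rep(NA_real_, n)
    bound[fit$table$index] <- fit$table$confect
    fallback <- is.na(bound) & usable
  } else if (method %in% c("ci_inner", "fwer_ci_inner")) {
    if (length(level) != 1 || level <= 0 || level >= 1)
      stop("'level' must be in (0, 1)")
    lev <- if (method == "fwer_ci_inner") 1 - (1 - level) / n else level
    hw <- rep(NA_real_, n)
    hw[usable] <- stats::qt((1 + lev) / 2, df = stats$df[usable]) *
      stats$se[usable]
    inner <- abs(eff) - hw
    excl <- usable & inner > 0
    bound <- rep(NA_real_, n)
    bound[excl] <- (ifelse(eff < 0, -1, 1) * inner)[excl]
    fallback <- usable & !excl
    u1 <- which(excl)
    u2 <- which(fallback)
    ord <- c(u1[order(-inner[u1], id_key[u1])],
             u2[order(p0[u2], id_key[u2])],
             which(!usable)[order(id_key[!usable])])
  } else if (method %in% c("treat_p_1", "treat_p_5")) {
    e <- if (method == "treat_p_1") 1 else 5
    pe <- treat_pvalue(eff[usable], stats$se[usable], stats$df[usable], e)
    ord <- order_with_bad_last(list(pe, -abs(eff[usable]), id_key[usable]))
  } else { # abs_lfc
    ord <- order_with_bad_last(list(-abs(eff[usable]), stats$se[usable],
                                    id_key[usable]))
  }

  out <- list(method = method, order = ord, bound = bound,
              fallback = fallback, n_gene = n)
  class(out) <- "gene_ranking"
  out
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat("Gene ranking by '", x$method, "' (", x$n_gene, " genes)\n", sep = "")
  if (any(x$fallback))
    cat(sum(x$fallback), "gene(s) ranked by the p-value fallback rule\n")
  invisible(x)
}
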