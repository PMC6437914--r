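#' Per-gene two-group mean difference with pooled variance
#'
#' Fits the elementary two-group model to every row of a log2-expression
#' matrix: the effect is the difference of group means (second group minus
#' first), the residual variance is the pooled within-group variance on
#' `n_A + n_B - 2` degrees of freedom, and the standard error of the effect
#' is `sqrt(var * (1/n_A + 1/n_B))`.
#'
#' Rows with zero residual variance are retained but flagged in `zero_var`;
#' whether they can be used downstream depends on variance moderation (see
#' [moderate_variances()]).
#'
#' @param x Numeric matrix, genes in rows, samples in columns, log2 scale.
#'   Row names are gene ids.
#' @param group Group label per column; anything coercible to a two-level
#'   factor. The first level is the reference group A; effects are
#'   mean(B) - mean(A). Groups may be of unequal size but each needs at
#'   least two samples.
#'
#' @return A list with `effect`, `sigma2` (pooled sample variance), `df`
#'   (scalar residual degrees of freedom), `stdev_unscaled`
#'   (`sqrt(1/n_A + 1/n_B)`, so that se = stdev_unscaled * sqrt(variance)),
#'   and `zero_var` (logical).
#' @export
fit_group_difference <- function(x, group) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  group <- as.factor(group)
  if (length(group) != ncol(x))
    stop("'group' must have one label per column of 'x'")
  if (nlevels(droplevels(group)) != 2)
    stop("'group' must have exactly two levels")
  group <- droplevels(group)
  na_row <- rowSums(is.na(x)) > 0
  if (any(na_row))
    stop(sum(na_row), " row(s) contain missing values; remove them first")
  nA <- sum(group == levels(group)[1])
  nB <- sum(group == levels(group)[2])
  if (nA < 2) stop("group '", levels(group)[1], "' has fewer than 2 samples")
  if (nB < 2) stop("group '", levels(group)[2], "' has fewer than 2 samples")
  xa <- x[, group == levels(group)[1], drop = FALSE]
  xb <- x[, group == levels(group)[2], drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2)
  ssb <- rowSums((xb - mb)^2)
  df <- nA + nB - 2
  sigma2 <- (ssa + ssb) / df
  list(
    effect = mb - ma,
    sigma2 = sigma2,
    df = df,
    stdev_unscaled = sqrt(1 / nA + 1 / nB),
    zero_var = sigma2 == 0
  )
}

# moderated df for t evaluation; t with df 1e6 is numerically normal
.df_cap <- 1e6

#' Empirical Bayes moderation of per-gene variances
#'
#' Shrinks per-gene sample variances towards a common prior by fitting a
#' scaled inverse chi-square prior to the observed variances and forming the
#' posterior variance for each gene,
#' \deqn{\tilde{s}^2_g = (d_0 v_0 + d s^2_g) / (d_0 + d),}
#' where `d0` (prior df) and `v0` (prior variance) are estimated by matching
#' moments of the log sample variances against the theoretical log-F
#' moments (digamma/trigamma relations), as implemented in
#' [limma::squeezeVar()]. Moderated degrees of freedom are `d + d0`.
#'
#' If the spread of log variances is no larger than expected under a single
#' common variance, the estimated prior df is infinite and every posterior
#' variance equals the prior variance. For downstream t-distribution
#' evaluation, infinite moderated df is capped at 1e6 (numerically normal).
#'
#' With fewer than `min_genes` genes there is too little information to
#' estimate the prior; moderation is skipped (prior df 0, posterior =
#' sample variances) with a warning.
#'
#' @param sigma2 Per-gene sample variances (>= 0, not all zero).
#' @param df Residual degrees of freedom of each variance (scalar, >= 1).
#' @param min_genes Minimum number of genes required to estimate the prior.
#'
#' @return An object of class `moderation_fit`: a list with `prior_df`
#'   (possibly `Inf`), `prior_var`, `posterior_var` (per gene), `df_total`
#'   (moderated df, capped), and `moderated` (logical).
#' @export
moderate_variances <- function(sigma2, df, min_genes = 10) {
  if (any(!is.finite(sigma2)) || any(sigma2 < 0))
    stop("'sigma2' must be finite and non-negative")
  if (all(sigma2 == 0))
    stop("all sample variances are zero; cannot moderate")
  if (length(df) != 1 || df < 1) stop("'df' must be a scalar >= 1")
  if (length(sigma2) < min_genes) {
    warning("fewer than ", min_genes,
            " genes: variance moderation skipped")
    out <- list(prior_df = 0, prior_var = mean(sigma2),
                posterior_var = sigma2, df_total = df, moderated = FALSE)
    class(out) <- "moderation_fit"
    return(out)
  }
  # zero sample variances are a supported input (the prior rescues them);
  # the fitter's note about offsetting them is part of that contract
  sq <- withCallingHandlers(
    limma::squeezeVar(sigma2, df = df),
    warning = function(w) {
      if (grepl("offset away from zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  d0 <- sq$df.prior
  out <- list(
    prior_df = d0,
    prior_var = sq$var.prior,
    posterior_var = sq$var.post,
    df_total = min(df + d0, .df_cap),
    moderated = TRUE
  )
  class(out) <- "moderation_fit"
  out
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("Empirical Bayes variance moderation\n")
  cat("  prior df:      ", format(x$prior_df), "\n")
  cat("  prior variance:", format(x$prior_var), "\n")
  cat("  moderated df:  ", format(x$df_total), "\n")
  invisible(x)
}

#' Per-gene moderated statistics from a two-group expression matrix
#'
#' Composes [fit_group_difference()] and [moderate_variances()] into the
#' per-gene statistics table consumed by [confects()]: gene id, log2
#' fold-change estimate, its standard error, and degrees of freedom.
#'
#' With `moderate = FALSE` the classical two-sample t inputs are returned
#' (sample variance, residual df). Genes with zero sample variance then have
#' no usable standard error: their `se` is `NA` and they sort last in any
#' downstream ranking, with a warning here. With moderation on, the prior
#' rescues such genes (their posterior variance is positive).
#'
#' @inheritParams fit_group_difference
#' @param moderate Apply empirical Bayes variance moderation (default TRUE).
#'
#' @return A data.frame with columns `gene_id`, `effect`, `se`, `df`, one
#'   row per gene, carrying the `moderation_fit` (or NULL) in
#'   `attr(, "moderation")`.
#'
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(50 * 6), 50, dimnames = list(paste0("g", 1:50), NULL))
#' gs <- gene_stats(x, rep(c("A", "B"), each = 3))
#' head(gs)
#' @export
gene_stats <- function(x, group, moderate = TRUE) {
  fit <- fit_group_difference(x, group)
  ids <- rownames(as.matrix(x))
  if (is.null(ids)) ids <- paste0("gene", seq_along(fit$effect))
  if (anyDuplicated(ids)) stop("gene ids (row names) must be unique")
  if (moderate) {
    mod <- moderate_variances(fit$sigma2, fit$df)
    se <- fit$stdev_unscaled * sqrt(mod$posterior_var)
    df <- rep_len(mod$df_total, length(fit$effect))
  } else {
    mod <- NULL
    se <- fit$stdev_unscaled * sqrt(fit$sigma2)
    df <- rep_len(fit$df, length(fit$effect))
    if (any(fit$zero_var)) {
      warning(sum(fit$zero_var), " gene(s) with zero variance have no ",
              "standard error without moderation; they will rank last")
      se[fit$zero_var] <- NA_real_
    }
  }
  out <- data.frame(
    gene_id = ids,
    effect = unname(fit$effect),
    se = unname(se),
    df = df,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "moderation") <- mod
  out
}
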