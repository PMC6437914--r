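#' Configuration of a two-group simulation experiment
#'
#' Describes the generative model for synthetic two-group expression data
#' with heteroscedastic genes. Per-gene within-group variances follow a
#' scaled inverse chi-square distribution,
#' \eqn{d_{within} s^2_{within} / \sigma^2_i \sim \chi^2_{d_{within}}},
#' and true log2 fold changes follow either a scaled t distribution
#' (`lfc_dist = "scaled_t"`: \eqn{\beta_i / s_{between} \sim
#' t(d_{between})}, power-law tails) or a Laplace distribution
#' (`lfc_dist = "laplace"`: \eqn{\beta_i \sim Laplace(0, s_{between})},
#' exponential tails). No gene has LFC exactly zero.
#'
#' Two presets are provided. `"sim1"` (scaled-t LFCs, `d_within = 2`,
#' `s_within = 0.75`, `d_between = 3`, `s_between = 0.5`) is extremely
#' heteroscedastic, the regime where ranking strategies differ most.
#' `"sim2"` (Laplace LFCs, `d_within = 5`, `s_within = 0.5`,
#' `s_between = 0.8`) is calmer, with parameters of the kind seen in large
#' tumour-vs-normal comparisons. Any field may be overridden.
#'
#' @param preset `"sim1"` or `"sim2"`.
#' @param n_gene Number of genes.
#' @param n_rep Samples per group (two equal groups).
#' @param n_runs Monte Carlo repetitions of the whole experiment.
#' @param seed Integer seed making the experiment reproducible.
#' @param d_within,s_within Prior df and scale of the gene variances.
#' @param lfc_dist `"scaled_t"` or `"laplace"`.
#' @param d_between t df of the LFC law (scaled_t only).
#' @param s_between Scale of the LFC law.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(preset = c("sim1", "sim2"), n_gene = 2000,
                       n_rep = 8, n_runs = 20, seed = 1,
                       d_within = NULL, s_within = NULL, lfc_dist = NULL,
                       d_between = NULL, s_between = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "sim1") {
    list(d_within = 2, s_within = 0.75, lfc_dist = "scaled_t",
         d_between = 3, s_between = 0.5)
  } else {
    list(d_within = 5, s_within = 0.5, lfc_dist = "laplace",
         d_between = NA_real_, s_between = 0.8)
  }
  cfg <- list(
    preset = preset, n_gene = n_gene, n_rep = n_rep, n_runs = n_runs,
    seed = seed,
    d_within = if (is.null(d_within)) def$d_within else d_within,
    s_within = if (is.null(s_within)) def$s_within else s_within,
    lfc_dist = if (is.null(lfc_dist)) def$lfc_dist else
      match.arg(lfc_dist, c("scaled_t", "laplace")),
    d_between = if (is.null(d_between)) def$d_between else d_between,
    s_between = if (is.null(s_between)) def$s_between else s_between
  )
  stopifnot(cfg$n_gene >= 1, cfg$n_rep >= 2, cfg$n_runs >= 1,
            cfg$d_within > 0, cfg$s_within > 0, cfg$s_between >= 0)
  if (cfg$lfc_dist == "scaled_t" && !(is.finite(cfg$d_between) &&
                                      cfg$d_between > 0))
    stop("'d_between' must be positive for scaled_t LFCs")
  class(cfg) <- "sim_config"
  cfg
}

#' Draw the true state of one simulated experiment
#'
#' Samples per-gene true variances and true log2 fold changes from the laws
#' described in [sim_config()]. Uses the current RNG state; seed control
#' belongs to the caller (see [run_benchmark()]).
#'
#' @param config A [sim_config()].
#' @return A list with `beta` (true LFC per gene) and `sigma2` (true
#'   within-group variance per gene, positive).
#' @export
draw_truth <- function(config) {
  n <- config$n_gene
  sigma2 <- config$d_within * config$s_within^2 /
    stats::rchisq(n, df = config$d_within)
  beta <- if (config$s_between == 0) {
    rep(0, n)
  } else if (config$lfc_dist == "scaled_t") {
    config$s_between * stats::rt(n, df = config$d_between)
  } else {
    # difference of two unit exponentials is standard Laplace
    config$s_between * (stats::rexp(n) - stats::rexp(n))
  }
  list(beta = beta, sigma2 = sigma2)
}

#' Draw an expression matrix given the true state
#'
#' Observations are gene-wise independent normals: group A samples have
#' mean 0, group B samples mean `beta[i]`, both with variance `sigma2[i]` —
#' the minimal observation model consistent with the per-gene linear-model
#' framework the statistics are fitted under.
#'
#' @param truth Output of [draw_truth()].
#' @param config The matching [sim_config()].
#' @return A list with `x` (matrix, `n_gene` by `2 * n_rep`, row names
#'   `gene1...`) and `group` (factor, levels A then B).
#' @export
draw_dataset <- function(truth, config) {
  n <- config$n_gene
  r <- config$n_rep
  sd_i <- sqrt(truth$sigma2)
  x <- matrix(stats::rnorm(n * 2 * r, mean = 0, sd = sd_i), nrow = n)
  x[, (r + 1):(2 * r)] <- x[, (r + 1):(2 * r)] + truth$beta
  rownames(x) <- paste0("gene", seq_len(n))
  colnames(x) <- c(paste0("A", seq_len(r)), paste0("B", seq_len(r)))
  list(x = x, group = factor(rep(c("A", "B"), each = r)))
}

#' Proportion of the true top-k genes recovered by a ranking
#'
#' Scores a ranking against the known truth as the overlap between the
#' method's first k genes and the k genes with largest true |LFC|, divided
#' by k (set overlap; position within the top k is not scored). For
#' rankings with a fallback rule, also reports what fraction of the
#' correctly recovered genes were placed by the fallback rather than the
#' method proper.
#'
#' @param ranking A [rank_genes()] result, or an integer order vector.
#' @param beta True per-gene LFCs.
#' @param k Size of the top list.
#' @return A list with `correct` (proportion in \[0, 1\]) and
#'   `fallback_share` (proportion of the correct genes that were
#'   fallback-ranked; 0 when the method has no fallback).
#' @export
topk_correct <- function(ranking, beta, k) {
  ord <- if (inherits(ranking, "gene_ranking")) ranking$order else ranking
  if (k > length(beta)) stop("'k' exceeds the number of genes")
  true_top <- order(-abs(beta))[seq_len(k)]
  got <- ord[seq_len(k)]
  hit <- got %in% true_top
  fb <- if (inherits(ranking, "gene_ranking") && any(ranking$fallback)) {
    if (any(hit)) mean(ranking$fallback[got[hit]]) else 0
  } else 0
  list(correct = sum(hit) / k, fallback_share = fb)
}

#' Achieved FDR and FCR of signed effect-size bounds
#'
#' Evaluates per-gene signed bounds (confects, or inner CI ends) against
#' known true LFCs, at each selection threshold e: the discoveries are the
#' genes with `|bound| >= e`; a discovery is false when `|beta| <= e`; a
#' false coverage statement is a discovery whose bound has the wrong sign
#' or whose magnitude exceeds `|beta|`. Rates are proportions among the
#' discoveries of this one realisation; with no discoveries the rate is 0
#' (the standard convention, so that averaging realisations estimates the
#' controlled expectation).
#'
#' @param bound Signed bound per gene; `NA` = no bound (never selected).
#' @param beta True LFC per gene.
#' @param thresholds Non-negative selection thresholds.
#' @param sign_of Signs used for the coverage check; defaults to
#'   `sign(bound)`, but pass the estimated effect's signs when a bound of
#'   exactly zero should still carry its direction claim.
#' @return A data.frame with one row per threshold: `threshold`, `n_true`
#'   (genes with `|beta|` exceeding it), `n_discoveries`, `n_false_disc`,
#'   `n_false_cov`, `fdp`, `fcp`.
#' @export
bound_error_rates <- function(bound, beta, thresholds = c(0, 0.5, 1, 1.5, 2),
                              sign_of = NULL) {
  if (any(thresholds < 0)) stop("'thresholds' must be non-negative")
  sgn <- if (is.null(sign_of)) sign(bound) else sign(sign_of)
  ab <- abs(bound)
  false_cov_gene <- !is.na(bound) & (sgn != sign(beta) | ab > abs(beta))
  rows <- lapply(thresholds, function(e) {
    disc <- !is.na(bound) & ab >= e - 1e-9
    nd <- sum(disc)
    fd <- sum(disc & abs(beta) <= e)
    fc <- sum(disc & false_cov_gene)
    data.frame(threshold = e, n_true = sum(abs(beta) > e),
               n_discoveries = nd, n_false_disc = fd, n_false_cov = fc,
               fdp = fd / max(1, nd), fcp = fc / max(1, nd))
  })
  do.call(rbind, rows)
}

#' Run the ranking benchmark on simulated data
#'
#' Repeats, `n_runs` times: draw a true state and dataset from `config`,
#' fit moderated two-group statistics, rank genes by each requested method,
#' and score top-k recovery; for the bound-producing methods (`confect`,
#' `ci_inner`, `fwer_ci_inner`) also score achieved FDR and FCR at each
#' threshold. Everything is driven by `config$seed`, so the full report is
#' reproducible bit for bit.
#'
#' @param config A [sim_config()].
#' @param methods Subset of [ranking_methods()] to benchmark.
#' @param ks Top-list sizes to score.
#' @param thresholds Selection thresholds for the FDR/FCR assessment.
#' @param fdr Target FDR for the confect method.
#'
#' @return An object of class `sim_benchmark`: a list with
#'   `topk` (per method and k: mean proportion correct, its Monte Carlo
#'   standard error, and mean fallback share), `rates` (per bound method
#'   and threshold: mean achieved FDR and FCR with standard errors, mean
#'   true-gene and discovery counts), the per-run tables `topk_runs` and
#'   `rates_runs`, and `config`.
#' @export
run_benchmark <- function(config, methods = ranking_methods(),
                          ks = c(20, 100, 500),
                          thresholds = c(0, 0.5, 1, 1.5, 2), fdr = 0.05) {
  methods <- match.arg(methods, ranking_methods(), several.ok = TRUE)
  ks <- ks[ks <= config$n_gene]
  bound_methods <- intersect(methods,
                             c("confect", "ci_inner", "fwer_ci_inner"))
  set.seed(config$seed)
  topk_runs <- list()
  rates_runs <- list()
  for (run in seq_len(config$n_runs)) {
    truth <- draw_truth(config)
    dat <- draw_dataset(truth, config)
    stats <- gene_stats(dat$x, dat$group, moderate = TRUE)
    for (m in methods) {
      rk <- rank_genes(stats, method = m, fdr = fdr)
      for (k in ks) {
        tk <- topk_correct(rk, truth$beta, k)
        topk_runs[[length(topk_runs) + 1L]] <- data.frame(
          run = run, method = m, k = k, correct = tk$correct,
          fallback_share = tk$fallback_share)
      }
      if (m %in% bound_methods) {
        er <- bound_error_rates(rk$bound, truth$beta, thresholds,
                                sign_of = stats$effect)
        er$run <- run
        er$method <- m
        rates_runs[[length(rates_runs) + 1L]] <- er
      }
    }
  }
  topk_runs <- do.call(rbind, topk_runs)
  rates_runs <- if (length(rates_runs)) do.call(rbind, rates_runs) else NULL

  mc_se <- function(v) stats::sd(v) / sqrt(length(v))
  topk <- do.call(rbind, lapply(split(
    topk_runs, list(topk_runs$method, topk_runs$k), drop = TRUE),
    function(d) data.frame(method = d$method[1], k = d$k[1],
                           correct = mean(d$correct),
                           se_correct = mc_se(d$correct),
                           fallback_share = mean(d$fallback_share))))
  rates <- NULL
  if (!is.null(rates_runs)) {
    rates <- do.call(rbind, lapply(split(
      rates_runs, list(rates_runs$method, rates_runs$threshold),
      drop = TRUE),
      function(d) data.frame(method = d$method[1], threshold = d$threshold[1],
                             fdr = mean(d$fdp), se_fdr = mc_se(d$fdp),
                             fcr = mean(d$fcp), se_fcr = mc_se(d$fcp),
                             n_true = mean(d$n_true),
                             n_discoveries = mean(d$n_discoveries))))
    rates <- rates[order(rates$method, rates$threshold), ]
    rownames(rates) <- NULL
  }
  topk <- topk[order(topk$method, topk$k), ]
  rownames(topk) <- NULL
  out <- list(topk = topk, rates = rates, topk_runs = topk_runs,
              rates_runs = rates_runs, config = config)
  class(out) <- "sim_benchmark"
  out
}

#' @export
print.sim_benchmark <- function(x, ...) {
  cfg <- x$config
  cat("Simulation benchmark (", cfg$preset, "): ", cfg$n_gene, " genes, ",
      cfg$n_rep, " per group, ", cfg$n_runs, " runs, seed ", cfg$seed,
      "\n\n", sep = "")
  cat("Top-k recovery (mean proportion correct):\n")
  print(x$topk, row.names = FALSE, digits = 3)
  if (!is.null(x$rates)) {
    cat("\nAchieved error rates of bounds:\n")
    print(x$rates, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
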