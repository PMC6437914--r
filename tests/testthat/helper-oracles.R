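# Independent oracles and fixture builders shared across test files.
# These deliberately avoid the package's own code paths.

# Random per-gene statistics table; caller controls the RNG seed.
rand_stats <- function(n, effect_sd = 2) {
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    effect = stats::rnorm(n, 0, effect_sd),
    se = exp(stats::rnorm(n, 0, 0.5)) * 0.5,
    df = sample(3:20, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Brute-force search for the largest set S with S == {i : p_i <= |S| q / n},
# by enumeration of all 2^n subsets. Only sane for n <= 12.
oracle_bh_bruteforce <- function(p, q, n_gene = length(p)) {
  n <- length(p)
  best <- integer(0)
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    thr <- length(S) * q / n_gene
    in_set <- p <= thr
    if (setequal(which(in_set), S) && length(S) > length(best)) best <- S
  }
  best
}

# Per-threshold confect oracle: run an independent BH selection
# (stats::p.adjust) at every grid value separately and give each gene the
# largest threshold at which it is selected. No use of set nesting.
oracle_confects <- function(pfun, n, q, step, max_steps = 2000) {
  abs_c <- rep(NA_real_, n)
  for (i in 0:max_steps) {
    e <- i * step
    sel <- which(stats::p.adjust(pfun(e), method = "BH") <= q)
    if (length(sel) == 0) break
    abs_c[sel] <- e
  }
  abs_c
}

# Nine-gene fixture realising nested selections of sizes 7, 6, 3, 1, 0 at
# thresholds 0, 0.5, 1, 1.5, 2 (grid step 0.5). Gene i stays selected for
# all e strictly below its dropout threshold t_i; its p-value function
# steps from a tiny value to a large one at t_i, hence is non-decreasing.
# The expected confect magnitudes are 1.5, 1, 1, 0.5, 0.5, 0.5, 0 with no
# value for the final two genes. The exact gene membership pattern is a
# synthetic realisation consistent with those set sizes.
nested_sets_fixture <- function() {
  t_drop <- c(2, 1.5, 1.5, 1, 1, 1, 0.5, 0, 0)
  n <- length(t_drop)
  pfun <- function(e) {
    ifelse(e < t_drop, 1e-4 * seq_len(n),
           ifelse(seq_len(n) <= 7, 0.5 + 0.01 * seq_len(n),
                  c(rep(NA, 7), 0.90, 0.95)[seq_len(n)]))
  }
  list(
    pfun = pfun,
    effect = c(5, -4, 4, 3, -3, 2, 1, 0.5, -0.4),
    expected_abs = c(1.5, 1, 1, 0.5, 0.5, 0.5, 0, NA, NA),
    expected_order = 1:9,
    step = 0.5
  )
}
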