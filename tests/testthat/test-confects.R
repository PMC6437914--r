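test_that("BH selection is the largest self-referential set", {
  expect_identical(bh_select(rep(1, 5), 0.05), integer(0))
  expect_identical(bh_select(0.01, 0.05), 1L)
  # k = 3 fails (0.04 > 3 * 0.0125), k = 2 passes (0.02 <= 0.025)
  expect_identical(bh_select(c(0.001, 0.02, 0.04, 0.9), 0.05), c(1L, 2L))
  expect_error(bh_select(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_select(c(0.5, NA), 0.05), "\\[0, 1\\]")

  # equivalence with brute-force subset enumeration, all sizes up to 12
  set.seed(31)
  for (n in c(1:12)) {
    for (q in c(0.05, 0.2, 0.5)) {
      p <- runif(n)^2
      expect_identical(bh_select(p, q), oracle_bh_bruteforce(p, q),
                       info = paste("n =", n, "q =", q))
    }
  }
  # step-up universe correction with n_gene larger than length(p)
  set.seed(32)
  p <- runif(8)^3
  expect_identical(bh_select(p, 0.1, n_gene = 20),
                   oracle_bh_bruteforce(p, 0.1, n_gene = 20))
})

test_that("nested-set fixture yields the expected confects and ordering", {
  fx <- nested_sets_fixture()
  sc <- confect_scan(fx$pfun, fx$effect, fdr = 0.05, step = fx$step)
  expect_equal(sc$abs_confect, fx$expected_abs)
  expect_equal(sc$order, fx$expected_order)
  expect_false(sc$capped)
})

test_that("confect scan agrees with the per-threshold BH oracle", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(5:50, 1)
    stats <- rand_stats(n)
    pfun <- function(e) treat_pvalue(stats$effect, stats$se, stats$df, e)
    sc <- confect_scan(pfun, stats$effect, fdr = 0.05, step = 0.1)
    expect_equal(sc$abs_confect,
                 oracle_confects(pfun, n, q = 0.05, step = 0.1),
                 tolerance = 1e-12)
  }
})

test_that("confects table is ordered, signed and bounded by the estimate", {
  set.seed(34)
  stats <- rand_stats(200)
  fit <- confects(stats, fdr = 0.05, step = 0.05)
  tab <- fit$table
  has <- !is.na(tab$confect)
  # genes with a confect first, |confect| non-increasing
  expect_true(all(which(has) <= sum(has)))
  expect_true(all(diff(abs(tab$confect[has])) <= 0))
  # sign and magnitude contracts
  expect_true(all(sign(tab$confect[has]) == sign(tab$effect[has]) |
                    tab$confect[has] == 0))
  expect_true(all(abs(tab$confect[has]) <= abs(tab$effect[has])))
  # genes without a confect in ascending p(0)
  expect_true(all(diff(tab$p_zero[!has]) >= 0))
  expect_equal(fit$n_with_confect, sum(has))
  expect_equal(sort(tab$index), 1:200)  # a permutation: strict total order
})

test_that("selection at a threshold equals a direct TREAT + BH run", {
  set.seed(35)
  stats <- rand_stats(120)
  fit <- confects(stats, fdr = 0.05, step = 0.1)
  # grid origin: plain BH discovery set on p(0)
  p0 <- treat_pvalue(stats$effect, stats$se, stats$df, 0)
  expect_setequal(selected_at(fit, 0),
                  stats$gene_id[bh_select(p0, 0.05)])
  for (e in c(0.3, 0.5, 1, 2)) {
    pe <- treat_pvalue(stats$effect, stats$se, stats$df, e)
    expect_setequal(selected_at(fit, e),
                    stats$gene_id[which(p.adjust(pe, "BH") <= 0.05)])
  }
  # off-grid thresholds round up to the next grid point (conservative)
  expect_setequal(selected_at(fit, 0.41), selected_at(fit, 0.5))
  # beyond the largest confect nothing is selected
  expect_length(selected_at(fit, max(abs(fit$table$confect),
                                     na.rm = TRUE) + 1), 0)
})

test_that("scanned sets nest and are stable under grid refinement", {
  set.seed(36)
  stats <- rand_stats(150)
  fit <- confects(stats, fdr = 0.05, step = 0.2)
  es <- seq(0, 3, 0.2)
  sets <- lapply(es, function(e) selected_at(fit, e))
  for (i in seq_along(es)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # halving the step never changes membership at shared grid values
  fit2 <- confects(stats, fdr = 0.05, step = 0.1)
  for (e in es) expect_setequal(selected_at(fit2, e),
                                selected_at(fit, e))
})

test_that("every fit satisfies the FCR coverage inequality", {
  set.seed(37)
  for (q in c(0.01, 0.05, 0.2)) {
    stats <- rand_stats(200)
    fit <- confects(stats, fdr = q, step = 0.05)
    chk <- check_fcr(fit)
    expect_true(chk$ok)
    expect_lte(chk$max_slack, 0)
    expect_equal(nrow(chk$violations), 0)
  }
  # single gene: its confect b must satisfy p(b) <= q
  one <- data.frame(gene_id = "g1", effect = 4, se = 0.5, df = 10)
  f1 <- confects(one, fdr = 0.05)
  b <- abs(f1$table$confect[1])
  expect_lte(treat_pvalue(4, 0.5, 10, b), 0.05)
})

test_that("degenerate inputs are handled explicitly", {
  # all p(0) above q: nobody gets a confect, ranking is ascending p(0)
  weak <- data.frame(gene_id = paste0("g", 1:6),
                     effect = rnorm(6, 0, 0.05), se = rep(1, 6),
                     df = rep(8, 6))
  fit <- confects(weak, fdr = 0.05)
  expect_equal(fit$n_with_confect, 0)
  expect_true(all(is.na(fit$table$confect)))
  expect_true(all(diff(fit$table$p_zero) >= 0))

  # empty input
  expect_error(confects(weak[0, ]), "at least one gene")
  # scan cap triggers a warning and flags the fit
  strong <- data.frame(gene_id = "g1", effect = 50, se = 0.1, df = 50)
  expect_warning(fcap <- confects(strong, step = 0.5, max_e = 2), "max_e")
  expect_true(fcap$capped)
  expect_equal(abs(fcap$table$confect[1]), 2)
})

test_that("ranking is deterministic and stable under gene relabeling", {
  set.seed(38)
  stats <- rand_stats(80)
  f1 <- confects(stats, fdr = 0.05, step = 0.05)
  f2 <- confects(stats, fdr = 0.05, step = 0.05)
  expect_identical(f1$table, f2$table)
  # renaming genes uniformly permutes ids but not the statistics order
  stats2 <- stats
  stats2$gene_id <- sprintf("x%03d", seq_len(nrow(stats)))
  f3 <- confects(stats2, fdr = 0.05, step = 0.05)
  expect_equal(f3$table$index, f1$table$index)
  expect_equal(f3$table$confect, f1$table$confect)
})
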