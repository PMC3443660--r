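test_that("diff_probability is the differential fraction of the background", {
  expect_equal(diff_probability(simulation_profile()), 0.1)
  bg <- paste0("g", 1:10)
  expect_equal(diff_probability(differential_profile(character(0), bg)), 0)
  expect_equal(diff_probability(differential_profile(bg, bg)), 1)
})

test_that("empirical p-value is the inclusive exceedance proportion", {
  expect_equal(empirical_pvalue(c(1, 2, 3, 4, 5), 3), 0.6)
  expect_equal(empirical_pvalue(c(1, 2, 3), 10), 0)
  expect_equal(empirical_pvalue(c(1, 2, 3), 0), 1)
})

test_that("null simulation is deterministic given a seed and degenerate at p_diff = 0", {
  pw <- er_network(30, seed = 2)
  w <- equal_weight(pw)
  a <- simulate_null_scores(pw, w, 0.2, reps = 200, seed = 99)
  b <- simulate_null_scores(pw, w, 0.2, reps = 200, seed = 99)
  expect_identical(a$scores, b$scores)
  z <- simulate_null_scores(pw, w, 0, reps = 50, seed = 1)
  expect_true(all(z$scores == 0))
  # observed score attached -> p-value filled per the inclusive rule
  d <- simulate_null_scores(pw, w, 0.2, reps = 200, seed = 99, observed = 0)
  expect_equal(d$p_value, 1)
})

test_that("equal-weight null over single-gene nodes follows binomial moments", {
  pw <- er_network(200, seed = 4)
  w <- adjust_weights(weight_vector("equal.weight",
                                    stats::setNames(rep(1, 200), pw$nodes),
                                    pw$pathway_id),
                      alpha = 1e-12)
  nd <- simulate_null_scores(pw, w, 0.1, reps = 20000, seed = 7)
  # Binomial(200, 0.1): mean 20, variance 18
  expect_lt(abs(mean(nd$scores) - 20), 3 * sqrt(18 / 20000))
  expect_lt(abs(stats::var(nd$scores) - 18), 1.5)
})

test_that("null draws are per gene, preserving correlation between shared-gene nodes", {
  # two nodes sharing their only gene must flip together in every draw
  pw <- pathway_graph("share", c("A", "B"), members = list(A = "g1", B = "g1"))
  w <- adjust_weights(weight_vector("equal.weight", c(A = 1, B = 1), "share"))
  nd <- simulate_null_scores(pw, w, 0.5, reps = 500, seed = 3)
  expect_true(all(nd$scores %in% c(0, 2 * 1.01)))
})

test_that("exact tail enumerates the score distribution", {
  tt <- theoretical_tail(c(1, 1), 0.5)
  expect_equal(tt$tail(1), 0.75)   # 1 - P(no differential gene)
  expect_equal(tt$tail(0), 1)
  expect_equal(tt$tail(1 + 1e-9), 0.25)   # only the both-genes outcome remains
  expect_equal(tt$tail(3), 0)

  tt2 <- theoretical_tail(c(1, 2), 0.5)
  expect_equal(tt2$tail(2), 0.5)   # outcomes score {0,1,2,3}; two are >= 2

  # equal weights reduce to the binomial upper tail
  p <- 0.3
  tt3 <- theoretical_tail(rep(1, 12), p)
  for (s in 0:12) {
    expect_equal(tt3$tail(s), stats::pbinom(s - 1, 12, p, lower.tail = FALSE))
  }
  # tail is non-increasing
  grid <- seq(0, 13, by = 0.5)
  expect_true(all(diff(tt3$tail(grid)) <= 1e-12))
  expect_error(theoretical_tail(rep(1, 26), 0.5), "n <= 25")
  expect_error(theoretical_tail(c(1, -1), 0.5), "weights > 0")
})

test_that("Monte-Carlo null converges to the exact tail on small pathways", {
  set.seed(53)
  pw <- adj_to_pathway(random_adj(10, 0.2), id = "mc10")
  w <- adjust_weights(weight_vector(
    "rand", stats::setNames(sample(1:7, 10, replace = TRUE), pw$nodes), "mc10"))
  tt <- theoretical_tail(unname(w$adjusted), 0.3)
  nd <- simulate_null_scores(pw, w, 0.3, reps = 40000, seed = 17)
  for (q in stats::quantile(nd$scores, c(0.2, 0.5, 0.8))) {
    obs <- q - 1e-9
    p_th <- tt$tail(obs)
    p_mc <- empirical_pvalue(nd$scores, obs)
    expect_lt(abs(p_mc - p_th), 3 * sqrt(p_th * (1 - p_th) / 40000) + 1e-12)
  }
})

test_that("ORA p-value reproduces the hypergeometric upper tail", {
  expect_equal(ora_fisher_pvalue(40, 200, 1000, 10000), 1.36e-5,
               tolerance = 0.005)
  expect_equal(ora_fisher_pvalue(0, 200, 1000, 10000), 1)
  # full-overlap point mass has a closed product form
  k <- 200
  expect_equal(ora_fisher_pvalue(k, 200, 1000, 10000),
               prod((1000 - 0:199) / (10000 - 0:199)))
  # dual route: agrees with fisher.test one-sided on a small table
  tab <- matrix(c(8, 12, 42, 438), 2)  # k, pathway-k, diff-k, rest
  ft <- stats::fisher.test(tab, alternative = "greater")$p.value
  expect_equal(ora_fisher_pvalue(8, 20, 50, 500), ft, tolerance = 1e-10)
  expect_error(ora_fisher_pvalue(30, 20, 50, 500), "infeasible")
  expect_error(ora_fisher_pvalue(-1, 20, 50, 500), "infeasible")
})

test_that("minimum significant k matches a brute-force scan", {
  expect_identical(min_significant_k(200, 1000, 10000, 0.01), 31L)
  expect_identical(min_significant_k(200, 1000, 10000, 1), 0L)
  scan_oracle <- function(n_pathway, n_diff, n_bg, thr) {
    for (k in 0:n_pathway) {
      if (ora_fisher_pvalue(k, n_pathway, n_diff, n_bg) < thr) return(k)
    }
    NA_integer_
  }
  for (thr in c(0.05, 0.01, 0.001)) {
    expect_equal(min_significant_k(200, 1000, 10000, thr),
                 scan_oracle(200, 1000, 10000, thr), info = thr)
    expect_equal(min_significant_k(50, 20, 400, thr),
                 scan_oracle(50, 20, 400, thr), info = thr)
  }
  # unattainable threshold yields the sentinel
  expect_true(is.na(min_significant_k(3, 2, 1000, 1e-12)))
})
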