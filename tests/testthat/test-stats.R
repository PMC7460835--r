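# Rank-based factorial statistics

test_that("SRH matches the rank-ANOVA oracle on random balanced designs", {
  set.seed(101)
  for (i in 1:40) {
    a <- sample(2:3, 1); b <- sample(2:3, 1); n <- sample(3:6, 1)
    d <- expand.grid(A = paste0("a", 1:a), B = paste0("b", 1:b),
                     rep = 1:n)
    d$y <- round(rnorm(nrow(d)), sample(0:2, 1))   # induce ties sometimes
    if (length(unique(d$y)) < 2) next
    got <- scheirer_ray_hare(y ~ A + B, d)
    ora <- srh_oracle_balanced(d$y, factor(d$A), factor(d$B))
    expect_equal(got$ss_ranks, unname(ora$ss), tolerance = 1e-10)
    expect_equal(got$H, unname(ora$H), tolerance = 1e-10)
    expect_equal(got$p_chisq, unname(ora$p), tolerance = 1e-10)
  }
})

test_that("SRH unbalanced designs agree with type-II sums of squares", {
  set.seed(55)
  for (i in 1:5) {
    n <- sample(3:7, 4, replace = TRUE)
    d <- data.frame(
      A = rep(rep(c("a1", "a2"), each = 2), times = c(n[1], n[2], n[3],
                                                      n[4])),
      B = rep(c("b1", "b2", "b1", "b2"), times = c(n[1], n[2], n[3],
                                                   n[4])))
    d$y <- rnorm(nrow(d))
    got <- scheirer_ray_hare(y ~ A + B, d)
    r <- rank(d$y)
    ora <- car::Anova(lm(r ~ A * B, data = d), type = 2)
    expect_equal(got$ss_ranks, ora[["Sum Sq"]][1:3], tolerance = 1e-9)
  }
})

test_that("SRH sums of squares are additive and order-invariant", {
  set.seed(8)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"), rep = 1:4)
  d$y <- rnorm(nrow(d))
  got <- scheirer_ray_hare(y ~ A + B, d)
  r <- rank(d$y)
  ss_total <- sum((r - mean(r))^2)
  ss_within <- ss_total - sum(got$ss_ranks)
  expect_gt(ss_within, 0)
  # reconstructed within-SS matches the full-model residual SS
  expect_equal(sum(got$ss_ranks) + ss_within, ss_total, tolerance = 1e-9)

  shuffled <- d[sample(nrow(d)), ]
  got2 <- scheirer_ray_hare(y ~ A + B, shuffled)
  expect_equal(got2$H, got$H, tolerance = 1e-12)
  expect_equal(got2$F, got$F, tolerance = 1e-12)
})

test_that("SRH handles degenerate and invalid input", {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  d$y <- 1
  expect_warning(res <- scheirer_ray_hare(y ~ A + B, d), "constant")
  expect_equal(res$H, rep(0, 3))
  expect_equal(res$p_chisq, rep(1, 3))

  d2 <- d[d$A != "a1" | d$B != "b1", ]
  d2$y <- rnorm(nrow(d2))
  expect_error(scheirer_ray_hare(y ~ A + B, d2), "non-empty")
  expect_error(scheirer_ray_hare(y ~ A + B,
                                 data.frame(A = "a", B = d$B, y = 1)),
               "two levels")
})

test_that("Wilcoxon rank-sum: exact cases match enumeration", {
  # identical groups: symmetric, p = 1
  res <- wilcoxon_mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p, 1)

  # fully separated, n = 3 vs 3: two-sided exact p = 2/20 = 0.1
  res2 <- wilcoxon_mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res2$p, 0.1)
  expect_true(res2$W %in% c(0, 9))

  # enumeration oracle for assorted no-ties samples
  set.seed(21)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    z <- sample(100, n1 + n2)
    x <- z[seq_len(n1)]; y <- z[-seq_len(n1)]
    got <- wilcoxon_mann_whitney(x, y)
    expect_true(got$exact)
    expect_equal(got$p, enumerate_wilcoxon_p(x, y), tolerance = 1e-12)
  }

  # W for {1,2} vs {3,4} from full enumeration: minimum rank sum, W = 0
  expect_equal(wilcoxon_mann_whitney(c(1, 2), c(3, 4))$W, 0)
  # extreme shift attains the minimal achievable exact p
  n1 <- 5; n2 <- 6
  x <- rnorm(n1); y <- rnorm(n2) + 1000
  expect_equal(wilcoxon_mann_whitney(x, y)$p, 2 / choose(n1 + n2, n1),
               tolerance = 1e-12)
})

test_that("pairwise Wilcoxon applies Bonferroni correctly", {
  set.seed(3)
  g <- rep(c("g1", "g2", "g3", "g4"), each = 5)
  yv <- rnorm(20) + rep(c(0, 0, 0, 3), each = 5)
  res <- pairwise_wilcoxon(yv, g, adjust = "bonferroni")
  expect_equal(nrow(res), 6)
  expect_equal(res$p_adj, pmin(1, 6 * res$p), tolerance = 1e-12)
  expect_equal(min(1, 6 * 0.02), 0.12)   # the adjustment rule itself
  res_none <- pairwise_wilcoxon(yv, g, adjust = "none")
  expect_equal(res_none$p_adj, res_none$p)
  expect_error(pairwise_wilcoxon(yv, factor(g, levels = c(unique(g), "g5"))),
               "at least one")
})

test_that("significance bands have inclusive printed boundaries", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***", "***"))
  expect_equal(significance_stars(0.050001), "ns")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
})

test_that("auxiliary tests cover the standard battery", {
  # Spearman of a strictly increasing pairing is exactly +1
  x <- c(1, 4, 9, 16, 25)
  expect_equal(aux_test("spearman", x, x^2)$statistic, 1)
  # paired t on identical vectors: no effect at all
  res <- aux_test("t_paired", c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # unpaired t and Shapiro and Levene return finite results
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20, 1)
  for (tp in c("t", "shapiro", "levene")) {
    r <- if (tp == "shapiro") aux_test(tp, a) else aux_test(tp, a, b)
    expect_true(is.finite(r$statistic))
    expect_true(r$p >= 0 && r$p <= 1)
  }
  expect_error(aux_test("t", a), "required")
})
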