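test_that("ms matches its closed-form examples", {
  expect_identical(ms(0, 4, 5, 10), 1)           # empty sum
  expect_equal(ms(3, 4, 5, 10), 66 / 252)        # enumerate i = 3, 4
  expect_equal(ms(5, 5, 5, 5), 1)                # single-outcome pmf
  expect_error(ms(3, 2, 5, 10), "t <= min")
  expect_error(ms(1, 11, 5, 10), "T1, T2 <= Q")
})

test_that("ms equals the brute-force hypergeometric tail on a dense grid", {
  # moderate exhaustive sweep here; the full Q <= 25 sweep runs in
  # test-acceptance.R
  for (Q in c(1, 2, 5, 9, 12)) {
    for (T1 in 0:Q) for (T2 in 0:Q) for (t in 0:min(T1, T2)) {
      expect_equal(ms(t, T1, T2, Q), oracle_ms(t, T1, T2, Q),
                   tolerance = 1e-12,
                   label = sprintf("ms(%d,%d,%d,%d)", t, T1, T2, Q))
    }
  }
})

test_that("ms is non-increasing in t", {
  for (seed in 1:10) {
    set.seed(seed)
    Q <- sample(5:40, 1)
    T1 <- sample(0:Q, 1)
    T2 <- sample(0:Q, 1)
    vals <- ms(0:min(T1, T2), T1, T2, Q)
    expect_true(all(diff(vals) <= 1e-15))
  }
})

test_that("pcc matches hand examples and the two-pass oracle", {
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(v <- pcc(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(v))
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pcc(x, y), oracle_pcc(x, y), tolerance = 1e-12)
  }
})

test_that("discretize produces the documented binnings", {
  expect_equal(as.integer(discretize(c(1, 2, 3, 4), 2,
                                     "equal_frequency")),
               c(0L, 0L, 1L, 1L))
  expect_equal(as.integer(discretize(c(1, 2, 3, 10), 2, "equal_width")),
               c(0L, 0L, 0L, 1L))
  expect_warning(d <- discretize(rep(2, 5), 2), "constant")
  expect_true(all(d == 0L))
  # ties share a bin under equal frequency
  d2 <- discretize(c(1, 1, 1, 5, 6, 7), 2, "equal_frequency")
  expect_true(length(unique(d2[1:3])) == 1L)
  # equal-frequency bin sizes differ by <= 1 when there are no ties
  set.seed(1)
  x <- runif(17)
  for (k in 2:5) {
    sizes <- table(discretize(x, k, "equal_frequency"))
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("mi matches hand examples and is symmetric, non-negative", {
  expect_equal(mi(c(0, 0, 1, 1), c(0, 0, 1, 1)), log(2))
  expect_equal(mi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mi(c(0, 1, 0, 1), rep(0, 4)), 0)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:50, 1)
    dx <- sample(0:2, n, replace = TRUE)
    dy <- sample(0:2, n, replace = TRUE)
    expect_equal(mi(dx, dy), oracle_mi(dx, dy), tolerance = 1e-12)
    expect_equal(mi(dx, dy), mi(dy, dx))
    expect_gte(mi(dx, dy), -1e-12)
    # mi(x, x) is the empirical entropy of x
    p <- table(dx) / n
    expect_equal(mi(dx, dx), -sum(p * log(p)), tolerance = 1e-12)
  }
})

test_that("cmi matches the triple-sum oracle and reduces to mi", {
  # conditioning on a constant gives plain MI
  set.seed(3)
  dx <- sample(0:1, 12, replace = TRUE)
  dy <- sample(0:1, 12, replace = TRUE)
  expect_equal(cmi(dx, dy, rep(0, 12)), mi(dx, dy), tolerance = 1e-12)
  # mutually independent product joint -> 0 (all cells equally filled)
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  expect_equal(cmi(g$x, g$y, g$z), 0, tolerance = 1e-12)
  # 8-sample hand-built joint, brute-force triple sum
  dx8 <- c(0, 0, 1, 1, 0, 1, 0, 1)
  dy8 <- c(0, 1, 0, 1, 0, 0, 1, 1)
  dz8 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(cmi(dx8, dy8, dz8), oracle_cmi(dx8, dy8, dz8),
               tolerance = 1e-12)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:50, 1)
    dx <- sample(0:2, n, replace = TRUE)
    dy <- sample(0:2, n, replace = TRUE)
    dz <- sample(0:1, n, replace = TRUE)
    expect_equal(cmi(dx, dy, dz), oracle_cmi(dx, dy, dz),
                 tolerance = 1e-12)
    expect_equal(cmi(dx, dy, dz), cmi(dy, dx, dz), tolerance = 1e-12)
    expect_gte(cmi(dx, dy, dz), -1e-12)
  }
})

test_that("vdw_scores gives rank-based normal scores", {
  s <- vdw_scores(c(10, 20, 30))
  expect_equal(s, qnorm(c(0.25, 0.5, 0.75)))
  expect_identical(s[2], 0)
  # rank invariance under monotone transforms
  v <- c(3, 1, 7, 2, 9)
  expect_equal(vdw_scores(v), vdw_scores(exp(v)))
  expect_equal(vdw_scores(v), vdw_scores(rank(v)))
  # 2-way tie shares the average-rank score: oracle by direct computation
  vt <- c(5, 5, 1, 9)
  expected_tied <- qnorm(mean(c(2, 3)) / 5)
  expect_equal(vdw_scores(vt)[1:2], rep(expected_tied, 2))
})

test_that("la matches its direct evaluation and invariances", {
  # constant modulator: all VdW scores are qnorm(1/2) = 0
  expect_equal(la(c(1, 2, 3), c(3, 1, 2), rep(7, 3)), 0)
  # hand example with x = y = (1,2,3): z = (-1, 0, 1), so a monotone
  # modulator gives (1*qnorm(.25) + 0 + 1*qnorm(.75))/3 = 0 exactly
  expect_equal(la(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)), 0,
               tolerance = 1e-12)
  # modulator (2,1,3): VdW scores (0, qnorm(.25), qnorm(.75)) align only
  # with the third term -> LA = qnorm(0.75)/3
  expect_equal(la(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3)),
               qnorm(0.75) / 3, tolerance = 1e-12)
  expect_warning(v <- la(rep(1, 3), c(1, 2, 3), c(1, 2, 3)), "constant")
  expect_true(is.na(v))
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n); m <- rnorm(n)
    expect_equal(la(x, y, m), oracle_la(x, y, m), tolerance = 1e-12)
    expect_equal(la(x, y, m), la(y, x, m))                 # symmetry
    expect_equal(la(2 * x + 3, y, m), la(x, y, m),
                 tolerance = 1e-12)                        # affine in x
    expect_equal(la(x, -1 + 0.5 * y, m), la(x, y, m),
                 tolerance = 1e-12)                        # affine in y
    expect_equal(la(x, y, exp(m)), la(x, y, m),
                 tolerance = 1e-12)                        # monotone in m
  }
})

test_that("all measures are invariant to consistent sample permutation", {
  set.seed(11)
  n <- 24
  x <- rnorm(n); y <- rnorm(n); m <- rnorm(n)
  perm <- sample(n)
  expect_equal(pcc(x, y), pcc(x[perm], y[perm]))
  expect_equal(la(x, y, m), la(x[perm], y[perm], m[perm]))
  dx <- discretize(x, 4); dy <- discretize(y, 4); dz <- discretize(m, 3)
  expect_equal(mi(dx, dy), mi(dx[perm], dy[perm]))
  expect_equal(cmi(dx, dy, dz), cmi(dx[perm], dy[perm], dz[perm]))
})

test_that("pair_context assembles Q, T1, T2, t and the summed modulator", {
  inter <- data.frame(
    mirna = c("m1", "m2", "m2", "m3"),
    target = c("A", "A", "B", "B"))
  universe <- paste0("m", 1:5)
  mexpr <- tiny_expr(paste0("m", 1:3), c("s1", "s2"),
                     values = c(1, 3, 0, 2, 4, 0))
  ctx <- pair_context("A", "B", inter, mexpr, universe)
  expect_equal(ctx[c("Q", "T1", "T2", "t")],
               list(Q = 5L, T1 = 2L, T2 = 2L, t = 1L))
  expect_equal(unname(ctx$summed_mirna_expression),
               unname(mexpr["m2", ]))
  # shared set of 2 miRNAs: summed expression is the per-sample sum
  inter2 <- rbind(inter, data.frame(mirna = "m1", target = "B"))
  ctx2 <- pair_context("A", "B", inter2, mexpr, universe)
  expect_equal(ctx2$t, 2L)
  expect_equal(unname(ctx2$summed_mirna_expression),
               unname(colSums(mexpr[c("m1", "m2"), ])))
  # disjoint targets: t = 0, no modulator
  inter3 <- data.frame(mirna = c("m1", "m2"), target = c("A", "B"))
  ctx3 <- pair_context("A", "B", inter3, mexpr, universe)
  expect_equal(ctx3$t, 0L)
  expect_null(ctx3$summed_mirna_expression)
})
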