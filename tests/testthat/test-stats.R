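test_that("pooled t matches the closed form and the t.test oracle", {
  r <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$statistic), 3 / sqrt(2 / 3))        # 3.674
  expect_equal(abs(r$statistic), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  o <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$statistic, unname(o$statistic), tolerance = 1e-12)
  expect_equal(r$p, o$p.value, tolerance = 1e-12)

  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    mine <- students_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    mw <- students_t(a, b, variant = "welch")
    rw <- t.test(a, b)
    expect_equal(mw$statistic, unname(rw$statistic), tolerance = 1e-10)
    expect_equal(mw$df, unname(rw$parameter), tolerance = 1e-10)
  }
})

test_that("degenerate t inputs are handled per definition", {
  expect_equal(students_t(c(2, 2, 2), c(2, 2, 2))$p, 1)
  d <- students_t(c(2, 2, 2), c(3, 3, 3))
  expect_equal(d$p, 0)
  expect_true(d$degenerate)
  expect_error(students_t(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA matches aov and the F = t^2 identity", {
  set.seed(2)
  for (i in 1:8) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:8, 1), j * 0.3))
    mine <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k), lengths(groups))))
    ref <- summary(aov(y ~ g, df))[[1]]
    expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(mine$ms_within, ref[["Mean Sq"]][2], tolerance = 1e-10)
  }
  # two groups: F = t^2
  a <- c(1.2, 3.1, 2.2, 4.0); b <- c(2.9, 4.4, 3.8)
  expect_equal(one_way_anova(list(a, b))$statistic,
               students_t(a, b)$statistic^2, tolerance = 1e-12)
  # all groups identical -> F = 0, p = 1
  same <- one_way_anova(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(one_way_anova(list(1, c(1, 2))), "n >= 2")
})

test_that("repeated-measures ANOVA matches the aov Error-stratum oracle", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(4:8, 1); k <- sample(3:6, 1)
    x <- matrix(rnorm(n * k), n, k) + outer(rnorm(n), rnorm(k, 0, 0.5), `+`)
    mine <- rm_one_way_anova(x)
    df <- data.frame(y = as.vector(x),
                     cell = factor(rep(seq_len(n), k)),
                     cond = factor(rep(seq_len(k), each = n)))
    ref <- summary(aov(y ~ cond + Error(cell), df))
    tab <- ref[["Error: Within"]][[1]]
    expect_equal(mine$statistic, tab[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p, tab[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(mine$df, c(k - 1, (n - 1) * (k - 1)))
  }
})

test_that("two-way ANOVA matches aov on balanced tables and rejects others", {
  set.seed(4)
  for (i in 1:5) {
    a <- sample(2:3, 1); b <- sample(2:4, 1); r <- sample(2:4, 1)
    fa <- factor(rep(seq_len(a), each = b * r))
    fb <- factor(rep(rep(seq_len(b), each = r), a))
    y <- rnorm(a * b * r) + as.integer(fa) * 0.4 +
      as.integer(fb) * 0.2 + as.integer(fa) * as.integer(fb) * 0.1
    mine <- two_way_anova(y, fa, fb)
    ref <- summary(aov(y ~ fa * fb))[[1]]
    expect_equal(mine$A$statistic, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(mine$B$statistic, ref[["F value"]][2], tolerance = 1e-9)
    expect_equal(mine$interaction$statistic, ref[["F value"]][3],
                 tolerance = 1e-9)
    expect_equal(mine$interaction$p, ref[["Pr(>F)"]][3], tolerance = 1e-9)
  }
  # additive noiseless table: interaction F = 0 (SS exactly 0)
  fa <- factor(rep(1:2, each = 4)); fb <- factor(rep(rep(1:2, each = 2), 2))
  y_add <- as.integer(fa) + 10 * as.integer(fb)
  expect_equal(two_way_anova(y_add, fa, fb)$interaction$statistic, 0)
  # constant table: all F = 0
  cst <- two_way_anova(rep(3, 8), fa, fb)
  expect_equal(c(cst$A$statistic, cst$B$statistic,
                 cst$interaction$statistic), c(0, 0, 0))
  expect_error(two_way_anova(1:5, factor(c(1, 1, 1, 2, 2)),
                             factor(c(1, 2, 2, 1, 2))), "balanced")
})

test_that("Scheffe criterion matches its defining inequality", {
  set.seed(6)
  for (i in 1:8) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(4:7, 1), j * 0.6))
    an <- one_way_anova(groups)
    sch <- scheffe_posthoc(groups, an$ms_within, an$df[2], alpha = 0.05)
    means <- vapply(groups, mean, 0); n <- lengths(groups)
    crit <- qf(0.95, k - 1, an$df[2])
    for (q in seq_len(nrow(sch))) {
      i_ <- sch$i[q]; j_ <- sch$j[q]
      s <- (means[i_] - means[j_])^2 /
        (an$ms_within * (1 / n[i_] + 1 / n[j_]))
      expect_equal(sch$statistic[q], s, tolerance = 1e-10)
      expect_equal(sch$significant[q], s > (k - 1) * crit)
      expect_equal(sch$p[q],
                   pf(s / (k - 1), k - 1, an$df[2], lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("Scheffe with k = 2 reduces to the ANOVA F decision", {
  set.seed(7)
  for (i in 1:10) {
    groups <- list(rnorm(5), rnorm(6, 0.8))
    an <- one_way_anova(groups)
    sch <- scheffe_posthoc(groups, an$ms_within, an$df[2])
    expect_equal(sch$statistic, an$statistic, tolerance = 1e-10)
    expect_equal(sch$significant, an$p < 0.05)
    expect_equal(sch$p, an$p, tolerance = 1e-10)
  }
  # equal means: nothing significant at any alpha
  eq <- scheffe_posthoc(list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1)),
                        alpha = 0.5)
  expect_false(any(eq$significant))
})

test_that("Scheffe is coherent with the omnibus F (defining property)", {
  set.seed(8)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(4, j * 0.3))
    an <- one_way_anova(groups)
    sch <- scheffe_posthoc(groups, an$ms_within, an$df[2])
    if (an$statistic < qf(0.95, an$df[1], an$df[2])) {
      expect_false(any(sch$significant))
    }
  }
})

test_that("p-values are invariant to relabeling and shared affine maps", {
  set.seed(10)
  groups <- lapply(1:4, function(j) rnorm(5, j * 0.4))
  p0 <- one_way_anova(groups)$p
  expect_equal(one_way_anova(rev(groups))$p, p0, tolerance = 1e-12)
  shifted <- lapply(groups, function(g) 3.7 * g - 11)
  expect_equal(one_way_anova(shifted)$p, p0, tolerance = 1e-10)
  t0 <- students_t(groups[[1]], groups[[2]])
  t1 <- students_t(shifted[[1]], shifted[[2]])
  expect_equal(t1$p, t0$p, tolerance = 1e-10)
  expect_equal(students_t(groups[[2]], groups[[1]])$p, t0$p,
               tolerance = 1e-12)
})

test_that("ANOVA type-I rate is calibrated under the null", {
  set.seed(12)
  rej <- vapply(1:2000, function(i) {
    one_way_anova(lapply(1:3, function(j) rnorm(5)))$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})
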