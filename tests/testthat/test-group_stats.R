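test_that("two-way ANOVA matches the brute-force projection oracle", {
  set.seed(101)
  for (rep in 1:25) {
    balanced <- rep %% 2 == 0
    nA <- sample(2:3, 1); nB <- 2
    n_cell <- if (balanced) matrix(sample(3:6, 1), nA, nB)
      else matrix(sample(3:8, nA * nB, replace = TRUE), nA, nB)
    A <- c(); B <- c()
    for (i in 1:nA) for (j in 1:nB) {
      A <- c(A, rep(letters[i], n_cell[i, j]))
      B <- c(B, rep(LETTERS[j], n_cell[i, j]))
    }
    y <- rnorm(length(A), mean = 2 * (A == "a") + 3 * (B == "A"), sd = 1)
    for (type in 1:2) {
      fit <- two_way_anova(y, A, B, ss_type = type)
      orc <- oracle_two_way(y, A, B, type = type)
      expect_equal(fit$table$sum_sq[1:3], orc$ss, tolerance = 1e-8)
      expect_equal(fit$table$F[1:3], orc$F, tolerance = 1e-8)
      expect_equal(fit$table$p[1:3], orc$p, tolerance = 1e-8)
      expect_equal(fit$table$sum_sq[4], orc$rss, tolerance = 1e-8)
      # df decomposition: effects + residual sum to N - 1
      expect_equal(sum(fit$table$df), length(y) - 1)
    }
  }
})

test_that("ANOVA is invariant to adding a constant and degenerates gracefully", {
  set.seed(7)
  A <- rep(c("a", "b"), each = 8)
  B <- rep(c("x", "y"), times = 8)
  y <- rnorm(16)
  f1 <- two_way_anova(y, A, B)
  f2 <- two_way_anova(y + 1000, A, B)
  expect_equal(f1$table$F, f2$table$F, tolerance = 1e-6)

  expect_warning(fd <- two_way_anova(rep(5, 16), A, B), "degenerate")
  expect_true(all(is.na(fd$table$F[1:3])))
  expect_true(all(fd$table$p[1:3] == 1))
  expect_true(all(fd$table$sum_sq < 1e-9))
})

test_that("empty or underfilled cells are rejected", {
  A <- c("a", "a", "b", "b"); B <- c("x", "x", "x", "x")
  expect_error(two_way_anova(rnorm(4), A, c("x", "y", "x", "y")),
               class = "erg_small_cell")
  expect_error(two_way_anova(rnorm(4), A, B), class = "erg_empty_cell")
})

test_that("one-way ANOVA agrees with the oracle and with the pooled t-test", {
  set.seed(11)
  # two groups: F equals the squared pooled-variance t statistic
  a <- rnorm(9, 1); b <- rnorm(7, 2)
  fit <- one_way_anova(c(a, b), rep(c("g1", "g2"), c(9, 7)))
  tt <- unpaired_t(a, b)
  expect_equal(fit$table$F[1], tt$t^2, tolerance = 1e-10)
  expect_equal(fit$table$p[1], tt$p, tolerance = 1e-10)

  for (rep in 1:10) {
    g <- rep(c("u", "v", "w"), times = sample(3:7, 3, replace = TRUE))
    y <- rnorm(length(g), mean = as.integer(factor(g)))
    fit <- one_way_anova(y, g)
    orc <- oracle_one_way(y, g)
    expect_equal(fit$table$sum_sq[1], orc$ss_between, tolerance = 1e-8)
    expect_equal(fit$table$F[1], orc$F, tolerance = 1e-8)
  }

  expect_warning(fd <- one_way_anova(rep(2, 6), rep(c("a", "b"), 3)),
                 "degenerate")
  expect_true(is.na(fd$table$F[1]) && fd$table$p[1] == 1)
})

test_that("Bonferroni adjustment multiplies, caps at one, never shrinks", {
  set.seed(23)
  A <- rep(c("ctl", "dis"), each = 10)
  B <- rep(rep(c("veh", "drug"), each = 5), 2)
  y <- rnorm(20, 10 * (A == "dis") * (B == "veh"))
  fit <- two_way_anova(y, A, B)

  one <- bonferroni_posthoc(fit, comparisons = list(
    list(a = c("ctl", "veh"), b = c("dis", "veh"))))
  expect_equal(one$p_adj, one$p_raw)

  four <- bonferroni_posthoc(fit)
  expect_equal(nrow(four), 4)
  expect_equal(four$p_adj, pmin(1, 4 * four$p_raw))
  expect_true(all(four$p_adj >= four$p_raw))

  expect_error(bonferroni_posthoc(fit, comparisons = list(
    list(a = c("ctl", "veh"), b = c("nothere", "veh")))),
    class = "erg_unknown_cell")

  # raw p 0.03 with m = 4 is not significant after correction
  expect_identical(min(1, 4 * 0.03) < 0.05, FALSE)
})

test_that("posthoc p-values over random instances respect adjustment bounds", {
  set.seed(31)
  for (rep in 1:20) {
    A <- rep(c("a", "b"), each = 8)
    B <- rep(rep(c("x", "y"), each = 4), 2)
    y <- rnorm(16)
    ph <- bonferroni_posthoc(two_way_anova(y, A, B))
    expect_true(all(ph$p_adj >= ph$p_raw - 1e-15))
    expect_true(all(ph$p_adj <= 1))
  }
})

test_that("the unpaired t-test matches its closed form and stats::t.test", {
  a <- c(4.1, 3.7, 5.2, 4.8, 4.4); b <- c(3.1, 2.8, 3.9, 3.3)
  res <- unpaired_t(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  resw <- unpaired_t(a, b, welch = TRUE)
  refw <- t.test(a, b)
  expect_equal(resw$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(resw$df, unname(refw$parameter), tolerance = 1e-10)

  swap <- unpaired_t(b, a)
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  same <- suppressWarnings(unpaired_t(c(1, 1, 1), c(1, 1)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("summary-statistics ANOVA equals raw-data ANOVA, balanced or not", {
  set.seed(47)
  summarize <- function(y, A, B) {
    do.call(rbind, lapply(split(seq_along(y), paste(A, B)), function(i)
      data.frame(factor_a = A[i[1]], factor_b = B[i[1]], mean = mean(y[i]),
                 sem = sd(y[i]) / sqrt(length(i)), n = length(i))))
  }
  for (ns in list(c(6, 6, 6, 6), c(10, 8, 10, 10))) {
    A <- rep(rep(c("nd", "db"), each = 2), times = ns)
    # build per-cell with exact n pattern
    cells <- expand.grid(a = c("nd", "db"), b = c("veh", "feno"),
                         stringsAsFactors = FALSE)
    y <- c(); A <- c(); B <- c()
    for (i in 1:4) {
      y <- c(y, rnorm(ns[i], mean = i * 2, sd = 1 + i / 4))
      A <- c(A, rep(cells$a[i], ns[i]))
      B <- c(B, rep(cells$b[i], ns[i]))
    }
    summ <- summarize(y, A, B)
    for (type in 1:2) {
      raw <- two_way_anova(y, A, B, ss_type = type)
      frm <- summary_stats_anova(summ, ss_type = type)
      expect_equal(frm$table$sum_sq, raw$table$sum_sq, tolerance = 1e-10)
      expect_equal(frm$table$F, raw$table$F, tolerance = 1e-10)
      expect_equal(frm$table$p, raw$table$p, tolerance = 1e-10)
    }
  }
})

test_that("published triglyceride summaries reproduce their raw-equivalent ANOVA", {
  tab <- read_summary(system.file("extdata",
                                  "plasma_triglycerides_summary.csv",
                                  package = "ergkit"),
                      require_crossing = TRUE)
  fit <- summary_stats_anova(tab)
  # oracle: any raw sample realizing the summaries, analysed independently
  y <- c(); A <- c(); B <- c()
  for (i in seq_len(nrow(tab))) {
    y <- c(y, realize_cell(tab$mean[i], tab$sem[i], tab$n[i]))
    A <- c(A, rep(tab$factor_a[i], tab$n[i]))
    B <- c(B, rep(tab$factor_b[i], tab$n[i]))
  }
  orc <- oracle_two_way(y, A, B, type = 2)
  expect_equal(fit$table$sum_sq[1:3], orc$ss, tolerance = 1e-8)
  expect_equal(fit$table$p[1:3], orc$p, tolerance = 1e-8)

  # the diabetic-vs-control contrast under vehicle chow is the table's
  # headline significance
  ph <- bonferroni_posthoc(fit)
  veh <- ph[ph$comparison == "diabetic:vehicle vs non_diabetic:vehicle", ]
  expect_equal(nrow(veh), 1)
  expect_true(veh$significant)
})

test_that("identical summary cells give a zero-F, p = 1 result", {
  cells <- data.frame(factor_a = rep(c("a", "b"), 2),
                      factor_b = rep(c("x", "y"), each = 2),
                      mean = 5, sem = 1, n = 6)
  fit <- summary_stats_anova(cells)
  expect_equal(fit$table$F[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(fit$table$p[1:3], rep(1, 3), tolerance = 1e-12)
})

test_that("realized cells reproduce their summaries exactly", {
  for (n in c(2, 3, 10)) {
    x <- realize_cell(7.3, 1.9, n)
    expect_equal(mean(x), 7.3, tolerance = 1e-12)
    expect_equal(sd(x) / sqrt(n), 1.9, tolerance = 1e-12)
  }
})

test_that("each effect's null rejection rate is near the nominal level", {
  set.seed(613)
  m <- 1000
  rej <- matrix(FALSE, m, 3)
  for (i in 1:m) {
    y <- rnorm(24)
    A <- rep(c("a", "b"), each = 12)
    B <- rep(rep(c("x", "y"), each = 6), 2)
    rej[i, ] <- two_way_anova(y, A, B)$table$p[1:3] < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(abs(rates - 0.05) <= 0.02))
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009, NA)),
               c("", "*", "**", "***", "****", ""))
})
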