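# Group-comparison battery.

test_that("one-way ANOVA matches the textbook sums-of-squares result", {
  r <- oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 13.5)
  expect_equal(r$df1, 1)
  expect_equal(r$df2, 4)
  rid <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(rid$statistic, 0)
  expect_error(
    oneWayAnova(list(c(2, 2, 2), c(2, 2, 2))),
    "undefined"
  )
})

test_that("two-group one-way ANOVA satisfies F = t^2", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(sample(4:12, 1))
    b <- rnorm(sample(4:12, 1), mean = runif(1, -1, 1))
    f <- oneWayAnova(list(a, b))$statistic
    t <- tTest(a, b)$statistic
    expect_equal(f, t^2, tolerance = 1e-12)
  }
})

test_that("two-way ANOVA flags empty cells and sees pure additivity", {
  set.seed(7)
  tab <- expand.grid(group = c("y", "o"), sex = c("M", "F"), rep = 1:5)
  tab$value <- ifelse(tab$group == "y", 20, 0) +
    ifelse(tab$sex == "M", 10, 0) + rnorm(20, sd = 0.1)
  r <- twoWayAnova(tab)
  # additive construction: interaction is noise-level, main effects massive
  expect_lt(r$statistic[r$comparison == "group:sex"], 5)
  expect_gt(r$statistic[r$comparison == "group"], 1e4)
  bad <- tab[!(tab$group == "y" & tab$sex == "M"), ]
  expect_error(twoWayAnova(bad), "non-empty")
})

test_that("mixed ANOVA separates between and within effects", {
  tab <- expand.grid(subject = 1:10, condition = c("a", "b", "c"))
  tab$group <- ifelse(tab$subject <= 5, "young", "older")
  tab$value <- ifelse(tab$group == "young", 10, 0) + rnorm(30, sd = 0.5)
  r <- mixedAnova(tab)
  expect_gt(r$statistic[r$comparison == "group"], 50)
  expect_lt(r$statistic[r$comparison == "condition"], 10)
  # missing condition errors with the subject named
  expect_error(mixedAnova(tab[-1, ]), "1")
})

test_that("Holm-Sidak reproduces the worked step-down example", {
  r <- holmSidak(c(0.01, 0.04, 0.30), alpha = 0.05)
  expect_equal(r$p_adjusted, c(1 - 0.99^3, 1 - 0.96^2, 0.30),
    tolerance = 1e-12
  )
  expect_identical(r$reject, c(TRUE, FALSE, FALSE))
  expect_true(all(holmSidak(rep(0, 4))$reject))
  one <- holmSidak(0.03)
  expect_equal(one$p_adjusted, 0.03) # m = 1: plain comparison
})

test_that("Holm-Sidak adjusted p values are monotone in the sorted order", {
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(2:10, 1))
    r <- holmSidak(p)
    expect_true(all(diff(r$p_adjusted[order(r$p)]) >= -1e-15))
    expect_true(all(r$p_adjusted >= r$p - 1e-15))
    expect_true(all(r$p_adjusted >= 0 & r$p_adjusted <= 1))
  }
})

test_that("t tests match hand calculations and reject degenerate input", {
  r <- tTest(c(2, 4, 6), c(1, 2, 3), paired = TRUE) # diffs 1, 2, 3
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6) # 3.464
  expect_equal(r$df1, 2)
  expect_error(tTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE), "zero variance")
  expect_equal(tTest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

test_that("Brown-Forsythe is a one-way ANOVA on median deviations and
          reduces to t-squared for two groups", {
  set.seed(31)
  a <- rnorm(15)
  b <- rnorm(15, sd = 4)
  r <- brownForsythe(list(a, b))
  t <- tTest(abs(a - median(a)), abs(b - median(b)))
  expect_equal(r$statistic, t$statistic^2, tolerance = 1e-12)
  # equal-spread null: usually insignificant
  r0 <- brownForsythe(list(rnorm(25), rnorm(25)))
  expect_true(r0$p > 0.001)
})

test_that("groupComparison joins subjects and adjusts across scopes", {
  set.seed(41)
  subjects <- data.frame(
    subject = sprintf("S%02d", 1:12),
    group = rep(c("young", "older"), each = 6),
    sex = rep(c("M", "F"), 6)
  )
  results <- do.call(rbind, lapply(subjects$subject, function(s) {
    young <- subjects$group[subjects$subject == s] == "young"
    data.frame(
      subject = s, scope = c("global", "BA"),
      slope = rnorm(2, mean = if (young) 5 else 3, sd = 0.5)
    )
  }))
  out <- groupComparison(results, subjects)
  expect_setequal(out$scope, c("global", "BA"))
  expect_true(all(out$p_adjusted >= out$p))
  expect_true(all(out$reject)) # strong programmed group difference
})
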