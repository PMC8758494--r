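# Group-comparison layer: normality screen, ROUT-style outliers, two-way
# ANOVA, Holm-Sidak, full pipeline.

makeTable <- function(values, genos, ages) {
  cohortTable(values, genos, ages)
}

test_that("the Shapiro-Wilk screen is calibrated and detects non-normality", {
  screenP <- function(x) normalityScreen(makeTable(x, rep("WT", length(x)),
                                                   rep("2", length(x))))$shapiroP
  withr::local_seed(31)
  rej <- mean(vapply(1:2000, function(i) screenP(rnorm(50)) < 0.05, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  pow <- mean(vapply(1:200, function(i) screenP(rexp(50)) < 0.05, logical(1)))
  expect_gte(pow, 0.90)
})

test_that("normalityScreen reports per group and flags degenerate cells", {
  withr::local_seed(32)
  tab <- makeTable(c(rnorm(10), rnorm(10, 5), rep(1, 4), rnorm(2)),
                   rep(c("WT", "KI"), c(20, 6)),
                   rep(c("2", "4", "2", "4"), c(10, 10, 4, 2)))
  ns <- normalityScreen(tab)
  expect_identical(nrow(ns), 4L)
  expect_true(all(is.finite(ns$shapiroP[ns$flag == ""])))
  expect_identical(ns$flag[ns$genotype == "KI" & ns$age == "2"], "degenerate")
  expect_identical(ns$flag[ns$genotype == "KI" & ns$age == "4"], "n < 3")
})

test_that("ROUT-style screen flags gross outliers and spares clean data", {
  expect_identical(routOutliers(c(9.9, 10, 10.1, 10.05, 9.95, 50)),
                   c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(routOutliers(rep(3.2, 8)), rep(FALSE, 8))
  expect_warning(flags <- routOutliers(c(1, 2, 3)), "fewer than 5")
  expect_identical(flags, rep(FALSE, 3))
  # false-positive calibration on clean Gaussian data
  withr::local_seed(33)
  frac <- mean(vapply(1:2000, function(i) mean(routOutliers(rnorm(30))),
                      numeric(1)))
  expect_lte(frac, 0.02)
})

test_that("two-way ANOVA matches a brute-force sums-of-squares oracle", {
  # balanced 2x2 table: SS computed from first principles
  vals <- c(12, 14, 13, 15,   20, 22, 21, 23,
            15, 17, 16, 18,   17, 19, 18, 20)
  tab <- makeTable(vals, rep(c("WT", "KI"), each = 8),
                   rep(rep(c("2", "4"), each = 4), 2))
  a <- twoWayAnova(tab)
  # brute force on the balanced layout
  gm <- mean(vals)
  mG <- tapply(vals, rep(c("WT", "KI"), each = 8), mean)
  mA <- tapply(vals, rep(rep(c("2", "4"), each = 4), 2), mean)
  mGA <- tapply(vals, paste(rep(c("WT", "KI"), each = 8),
                            rep(rep(c("2", "4"), each = 4), 2)), mean)
  ssG <- 8 * sum((mG - gm)^2)
  ssA <- 8 * sum((mA - gm)^2)
  ssCells <- 4 * sum((mGA - gm)^2)
  ssI <- ssCells - ssG - ssA
  ssE <- sum((vals - rep(mGA[paste(rep(c("WT", "KI"), each = 8),
                                   rep(rep(c("2", "4"), each = 4), 2))],
                         1))^2)
  expect_lt(abs(a$sumsq[a$term == "genotype"] - ssG), 1e-10)
  expect_lt(abs(a$sumsq[a$term == "age"] - ssA), 1e-10)
  expect_lt(abs(a$sumsq[a$term == "genotype:age"] - ssI), 1e-10)
  expect_lt(abs(a$sumsq[a$term == "Residuals"] - ssE), 1e-10)
  fG <- (ssG / 1) / (ssE / 12)
  expect_lt(abs(a$F[a$term == "genotype"] - fG), 1e-10)
})

test_that("the genotype test is calibrated under the null and powered under shift", {
  withr::local_seed(34)
  genos <- rep(c("WT", "KI"), each = 40)
  ages <- rep(rep(c("1", "2", "4", "6"), each = 10), 2)
  rej <- mean(vapply(1:2000, function(i) {
    tab <- makeTable(rnorm(80), genos, ages)
    a <- twoWayAnova(tab)
    a$p[a$term == "genotype"] < 0.05
  }, logical(1)))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
  pow <- mean(vapply(1:200, function(i) {
    v <- rnorm(80) + ifelse(genos == "KI", 2, 0)
    a <- twoWayAnova(makeTable(v, genos, ages))
    a$p[a$term == "genotype"] < 0.001
  }, logical(1)))
  expect_gte(pow, 0.95)
})

test_that("ANOVA preconditions give informative errors", {
  tab <- makeTable(rnorm(12), rep(c("WT", "KI"), each = 6),
                   rep(c("2", "2", "2", "4", "4", "4"), 2))
  tab2 <- tab[!(tab$genotype == "KI" & tab$age == "4"), ]
  expect_error(twoWayAnova(tab2), "empty design cell: KI x 4")
  tab3 <- makeTable(rnorm(7), rep(c("WT", "WT", "KI", "KI"), c(2, 2, 2, 1)),
                    c("2", "2", "4", "4", "2", "2", "4"))
  expect_error(twoWayAnova(tab3), "fewer than 2")
  tab4 <- makeTable(rnorm(8), rep("WT", 8), rep(c("2", "4"), each = 4))
  expect_error(twoWayAnova(tab4), "2 levels")
})

test_that("Holm-Sidak adjustment matches stepwise hand evaluation", {
  adj <- holmSidak(c(0.01, 0.04, 0.03))
  # sorted: 1-(0.99)^3 = 0.029701; 1-(0.97)^2 = 0.0591; step-down max
  expect_equal(round(adj, 4), c(0.0297, 0.0591, 0.0591))
  expect_identical(holmSidak(0.2), 1 - (1 - 0.2)^1)
  expect_identical(holmSidak(rep(1, 4)), rep(1, 4))
  expect_error(holmSidak(c(0.1, 0)), "0, 1")
  # monotone, never below raw, order-preserved (property over random cases)
  withr::local_seed(35)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    a <- holmSidak(p)
    expect_true(all(a >= p - 1e-12))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
    expect_true(all(a <= 1))
  }
})

test_that("compareGroups runs the full per-age contrast pipeline", {
  withr::local_seed(36)
  genos <- rep(c("WT", "KI"), each = 32)
  ages <- rep(rep(c("1", "2", "4", "6"), each = 8), 2)
  eff <- ifelse(genos == "KI" & ages != "1", -2.5, 0)
  tab <- makeTable(rnorm(64, 10), genos, ages)
  tab$value <- tab$value + eff
  cr <- compareGroups(tab)
  pw <- pairwiseTable(cr)
  expect_identical(nrow(pw), 4L)
  expect_true(all(pw$adjP >= pw$rawP - 1e-12))
  expect_false(pw$significant[pw$age == "1"])
  expect_true(all(pw$significant[pw$age != "1"]))
  # a gross outlier is removed and recorded
  tab$value[1] <- 1e4
  cr2 <- compareGroups(tab)
  expect_true(tab$cellId[1] %in% cr2@outliersRemoved)
  expect_lte(length(cr2@outliersRemoved), 5L)
  # all-equal groups rarely produce adjusted significance
  genos10 <- rep(c("WT", "KI"), each = 40)
  ages10 <- rep(rep(c("1", "2", "4", "6"), each = 10), 2)
  sig <- vapply(1:60, function(i) {
    t0 <- makeTable(rnorm(80, 10), genos10, ages10)
    any(pairwiseTable(compareGroups(t0))$significant)
  }, logical(1))
  expect_lte(mean(sig), 0.10 + 1e-9)
})
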