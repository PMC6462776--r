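test_that("Kruskal-Wallis H matches the hand-computed example and an oracle", {
  res <- kruskalWallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(res$H, 12 / 42 * 16, tolerance = 1e-10)  # = 32/7
  expect_equal(res$df, 2L)
  same <- kruskalWallis(list(c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  set.seed(70)
  for (r in 1:10) {
    groups <- lapply(1:3, function(i) round(rnorm(sample(4:9, 1)), 1))
    expect_equal(kruskalWallis(groups)$H, kruskalOracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("Dunn post-hoc follows pooled midranks and BH adjustment", {
  same <- dunnPosthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # BH step-up on [0.01, 0.02, 0.03] -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # three-group oracle: recompute z from scratch with explicit midranks
  set.seed(71)
  g <- list(a = rnorm(6), b = rnorm(8) + 1, c = rnorm(5))
  res <- dunnPosthoc(g)
  x <- unlist(g)
  rk <- rank(x)
  n <- length(x)
  ties <- table(x)
  varTerm <- n * (n + 1) / 12 - sum(ties^3 - ties) / (12 * (n - 1))
  mr <- c(mean(rk[1:6]), mean(rk[7:14]), mean(rk[15:19]))
  sz <- c(6, 8, 5)
  zo <- c((mr[1] - mr[2]) / sqrt(varTerm * (1 / 6 + 1 / 8)),
          (mr[1] - mr[3]) / sqrt(varTerm * (1 / 6 + 1 / 5)),
          (mr[2] - mr[3]) / sqrt(varTerm * (1 / 8 + 1 / 5)))
  expect_equal(res$z, zo, tolerance = 1e-10)
  expect_true(all(res$p.adj >= res$p - 1e-15))
  expect_true(all(res$p.adj <= 1))
  # BH is order-preserving
  expect_equal(order(res$p.adj), order(res$p))
  expect_error(dunnPosthoc(list(a = numeric(0), b = 1:3)), "nonempty")
})

test_that("permutation MANOVA hits the extreme-statistic bound under separation", {
  set.seed(72)
  n <- 10
  Y <- rbind(matrix(rnorm(n * 2), n, 2),
             matrix(rnorm(n * 2) + 50, n, 2))
  g <- rep(c("a", "b"), each = n)
  res <- nonparametricManova(Y, g, nPerm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
})

test_that("permutation MANOVA is invariant to monotone column scaling", {
  set.seed(73)
  Y <- matrix(rnorm(30 * 3), 30, 3)
  g <- rep(c("a", "b", "c"), each = 10)
  r1 <- nonparametricManova(Y, g, nPerm = 99, seed = 5)
  Y2 <- sweep(Y, 2, c(10, 0.1, 1000), "*")
  r2 <- nonparametricManova(Y2, g, nPerm = 99, seed = 5)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p)
  expect_error(nonparametricManova(cbind(Y, 1), g), "constant")
})

test_that("r-squared effect size follows r = z / sqrt(n)", {
  expect_equal(effectSizeR2(0, 10), 0)
  expect_equal(effectSizeR2(sqrt(16), 16), 1)
  expect_equal(effectSizeR2(2, 16), 0.25)
  expect_error(effectSizeR2(1, 0), "positive")
})

test_that("Spearman correlations match the rank oracle and handle NAs", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearmanClinical(data.frame(m = x),
                                data.frame(c = x^0.5))$rho, 1)
  expect_equal(spearmanClinical(data.frame(m = x),
                                data.frame(c = rev(x)))$rho, -1)
  set.seed(74)
  a <- rnorm(20); b <- rnorm(20)
  res <- spearmanClinical(data.frame(m = a), data.frame(c = b))
  expect_equal(res$rho, spearmanOracle(a, b), tolerance = 1e-12)
  aNA <- a; aNA[1:3] <- NA
  resNA <- spearmanClinical(data.frame(m = aNA), data.frame(c = b))
  expect_equal(resNA$n, 17)
  expect_equal(resNA$rho, spearmanOracle(aNA[-(1:3)], b[-(1:3)]),
               tolerance = 1e-12)
  expect_error(spearmanClinical(data.frame(m = rep(1, 5)),
                                data.frame(c = 1:5)), "zero variance")
})

test_that("Mann-Whitney U and exact p match enumeration", {
  res <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  ident <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$U, 9 / 2)
  # exact p via enumeration of all label assignments (tie-free samples)
  set.seed(75)
  a <- rnorm(5); b <- rnorm(6) + 0.5
  res2 <- mannWhitneyU(a, b)
  x <- c(a, b)
  combos <- combn(11, 5)
  Ufun <- function(idx) {
    sum(rank(x)[idx]) - 5 * 6 / 2
  }
  Us <- apply(combos, 2, Ufun)
  Uobs <- sum(rank(x)[1:5]) - 15
  pExact <- mean(Us <= min(Uobs, 30 - Uobs)) + mean(Us >= max(Uobs, 30 - Uobs))
  expect_lt(abs(res2$p - pExact), 1e-6)
})

test_that("summary-statistic chi-square, t and ANOVA match the stock tests", {
  tab <- matrix(c(22, 9, 20, 9, 19, 12), 2)
  cs <- chiSquareCounts(tab)
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(cs$statistic, unname(ref$statistic))
  expect_equal(cs$p, ref$p.value)
  set.seed(76)
  x <- rnorm(12); y <- rnorm(15) + 0.4
  ts <- tTestSummary(mean(x), sd(x), 12, mean(y), sd(y), 15)
  reft <- t.test(x, y, var.equal = TRUE)
  expect_equal(ts$t, unname(reft$statistic), tolerance = 1e-10)
  expect_equal(ts$p, reft$p.value, tolerance = 1e-10)
  z <- rnorm(10) - 0.3
  av <- anovaSummary(c(mean(x), mean(y), mean(z)),
                     c(sd(x), sd(y), sd(z)), c(12, 15, 10))
  refa <- summary(aov(v ~ g, data.frame(v = c(x, y, z),
                                        g = rep(letters[1:3], c(12, 15, 10)))))
  expect_equal(av$F, refa[[1]]$`F value`[1], tolerance = 1e-10)
  expect_equal(av$p, refa[[1]]$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("demographics table runs the declared tests per variable", {
  co <- tinyCohort(nPerGroup = 12, T = 16)
  dem <- demographicsTable(co$manifest)
  expect_setequal(dem$variable, c("gender", "study", "age"))
  expect_true(all(dem$p >= 0 & dem$p <= 1))
})

test_that("group comparison wires KW, Dunn, FDR and effect sizes together", {
  set.seed(77)
  metrics <- data.frame(subject = paste0("s", 1:60),
                        frequency.1 = c(rnorm(30, 0.5, 0.05),
                                        rnorm(30, 0.3, 0.05)),
                        meanDwell.1 = rnorm(60, 5))
  groups <- rep(c("HC", "DLB"), each = 30)
  res <- compareGroups(metrics, groups,
                       columns = c("frequency.1", "meanDwell.1"))
  expect_equal(nrow(res$omnibus), 2)
  f1 <- res$omnibus[res$omnibus$measure == "frequency.1", ]
  expect_lt(f1$p, 0.001)
  pw <- res$pairwise[res$pairwise$measure == "frequency.1", ]
  expect_true(all(pw$r2 >= 0 & pw$r2 <= 1))
  expect_gt(pw$r2[1], 0.3)  # strong effect
})
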