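test_that("single comparison reduces exactly to the pooled two-sample t-test", {
  withr::with_seed(3, {
    g <- list(ref = rnorm(9), trt = rnorm(9, 0.8))
  })
  res <- dunnettVsReference(g, "ref")
  tt <- t.test(g$trt, g$ref, var.equal = TRUE)
  expect_equal(res$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(res$estimate, unname(diff(vapply(g, mean, 0))),
               tolerance = 1e-12)
})

test_that("many-to-one quadrature agrees with a Monte-Carlo oracle", {
  k <- 3; n <- 5
  df <- (k + 1) * (n - 1)
  lam <- rep(sqrt(n / (n + n)), k)
  withr::with_seed(42, {
    B <- 100000
    z <- matrix(rnorm(B * (k + 1)), B)
    s <- sqrt(rchisq(B, df) / df)
    tmax <- apply(abs(z[, 2:(k + 1)] - z[, 1]) / sqrt(2), 1, max) / s
  })
  for (q in c(2, 2.5, 3)) {
    mc <- mean(tmax <= q)
    expect_equal(pDunnettMax(q, lam, df), mc, tolerance = 0.005)
  }
  # distribution function sanity
  expect_equal(pDunnettMax(0, lam, df), 0)
  expect_lt(pDunnettMax(1, lam, df), pDunnettMax(3, lam, df))
  # critical value inverts the distribution
  q95 <- qDunnettMax(0.95, lam, df)
  expect_equal(pDunnettMax(q95, lam, df), 0.95, tolerance = 1e-5)
})

test_that("adjusted p-values dominate the unadjusted t-test p-values", {
  withr::with_seed(8, {
    groups <- c(list(Mix = rnorm(9, 10)),
                setNames(lapply(1:5, function(i) rnorm(9, 10 + i / 4)),
                         paste0("g", 1:5)))
  })
  res <- dunnettVsReference(groups, "Mix")
  df <- attr(res, "df")
  praw <- 2 * pt(-abs(res$t), df)
  expect_true(all(res$p_adj >= praw - 1e-10))
  expect_true(all(res$p_adj <= 1 & res$p_adj >= 0))
  expect_true(is.finite(attr(res, "omnibus_F")))
})

test_that("an extreme group lands in the strongest significance tier", {
  withr::with_seed(1, {
    groups <- list(Mix = rnorm(9, 0, 1), far = rnorm(9, 10, 1),
                   near = rnorm(9, 0, 1))
  })
  res <- dunnettVsReference(groups, "Mix")
  expect_identical(res$significance_tier[res$group == "far"], "p<0.001")
  expect_identical(res$symbol[res$group == "far"], "#")
  expect_identical(res$significance_tier[res$group == "near"], "ns")
})

test_that("degenerate inputs are refused", {
  expect_error(dunnettVsReference(list(a = 1:3, b = 1:3), "zz"),
               "not found")
  expect_error(dunnettVsReference(list(a = c(1, 1), b = c(2, 2)), "a"),
               "zero within-group variance")
  expect_error(dunnettVsReference(list(a = 1, b = 1:3), "a"),
               ">= 2 replicates")
})

test_that("Sidak adjustment matches its closed form and bounds", {
  expect_equal(sidakAdjust(0.01, 5), 1 - (1 - 0.01)^5, tolerance = 1e-14)
  expect_identical(sidakAdjust(0, 9), 0)
  expect_equal(sidakAdjust(1, 3), 1)
  withr::with_seed(2, {
    p <- runif(100)
    for (m in c(1, 4, 9)) {
      pa <- sidakAdjust(p, m)
      expect_true(all(pa >= p - 1e-12))
      expect_true(all(pa <= pmin(1, m * p) + 1e-12))
    }
  })
  expect_error(sidakAdjust(0.1, 0), "m must be")
})

test_that("composition contrast finds the planted species shifts only", {
  sp <- paste0("s", 1:5)
  withr::with_seed(6, {
    base <- c(0.3, 0.25, 0.2, 0.15, 0.1)
    mkRep <- function(mu) {
      t(replicate(4, { x <- mu * exp(rnorm(5, 0, 0.05)); x / sum(x) }))
    }
    a <- mkRep(base)
    shifted <- c(0.15, 0.25, 0.2, 0.15, 0.25)  # s1 down, s5 up
    b <- mkRep(shifted)
    colnames(a) <- colnames(b) <- sp
  })
  res <- sidakCompositionTest(a, b)
  expect_true(all(res$p_adj[res$species %in% c("s1", "s5")] < 0.05))
  expect_true(all(res$p_adj[res$species %in% c("s2", "s3")] > 0.05))
  expect_lt(res$estimate[res$species == "s1"], 0)
  expect_gt(res$estimate[res$species == "s5"], 0)
})

test_that("identical compositions in both conditions are all non-significant", {
  withr::with_seed(4, {
    a <- t(replicate(3, { x <- exp(rnorm(4, 0, 0.1)); x / sum(x) }))
    b <- t(replicate(3, { x <- exp(rnorm(4, 0, 0.1)); x / sum(x) }))
    colnames(a) <- colnames(b) <- paste0("s", 1:4)
  })
  res <- sidakCompositionTest(a, b)
  expect_true(all(res$significance_tier == "ns"))
  colnames(b)[1] <- "zz"
  expect_error(sidakCompositionTest(a, b), "mismatched species")
})

test_that("robustness classification follows the significance pattern", {
  mk <- function(p) data.frame(group = c("-A", "-B"), p_adj = p)
  res <- classifyRobustness(list(NPB = mk(c(0.5, 0.9)),
                                 NPPC = mk(c(0.001, 0.7))),
                            alpha = 0.05, dropoutIds = c("-A", "-B"))
  expect_identical(res$robust, c(TRUE, FALSE))
  expect_identical(res$offending, c("", "-A"))
  # alpha = 1 makes every comparison "significant": nothing is robust
  resAll <- classifyRobustness(list(NPB = mk(c(0.5, 0.9))), alpha = 1)
  expect_false(resAll$robust)
  expect_error(classifyRobustness(list(NPB = mk(c(0.5, 0.9))),
                                  dropoutIds = c("-A", "-B", "-C")),
               "missing dropout")
})
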