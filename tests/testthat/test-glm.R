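# The quasi-Poisson repression model: fit, methods, classification, FDR.

sim_pair_data <- function(n = 50, beta = c(-12, -0.8, 0.3, 0.2), phi = 1,
                          seed = 42) {
  set.seed(seed)
  M <- round(runif(n, 8e5, 1.2e6))
  x1 <- rnorm(n)
  x2 <- rep(0:1, length.out = n)
  mu <- M * exp(beta[1] + beta[2] * x1 + beta[3] * x2 + beta[4] * x1 * x2)
  y <- if (phi > 1) rnbinom(n, mu = mu, size = mu / (phi - 1)) else
    rpois(n, mu)
  list(y = y, x1 = x1, x2 = x2, M = M)
}

test_that("fit_pair reproduces the reference quasi-Poisson fit", {
  d <- sim_pair_data(phi = 1.5)
  f <- fit_pair(d$y, d$x1, d$x2, d$M)
  ref <- glm(d$y ~ d$x1 * d$x2 + offset(log(d$M)), family = quasipoisson())
  sref <- summary(ref)
  expect_lt(max(abs(unname(coef(f)) - unname(coef(ref)))), 1e-6)
  expect_lt(max(abs(unname(f$se) - unname(sref$coefficients[, 2]))), 1e-5)
  expect_lt(max(abs(unname(f$tvalues) - unname(sref$coefficients[, 3]))),
            1e-4)
  expect_lt(max(abs(unname(f$pvalues) - unname(sref$coefficients[, 4]))),
            1e-5)
  expect_lt(abs(f$dispersion - sref$dispersion), 1e-4)
  expect_equal(f$df.residual, df.residual(ref))
  # with phi fixed near 1 the point fit equals plain Poisson regression
  d1 <- sim_pair_data(phi = 1, seed = 7)
  f1 <- fit_pair(d1$y, d1$x1, d1$x2, d1$M)
  pref <- glm(d1$y ~ d1$x1 * d1$x2 + offset(log(d1$M)), family = poisson())
  expect_lt(max(abs(unname(coef(f1)) - unname(coef(pref)))), 1e-6)
})

test_that("degenerate designs are rejected", {
  d <- sim_pair_data()
  expect_error(fit_pair(d$y, rep(1, 50), d$x2, d$M), "constant")
  expect_error(fit_pair(d$y, d$x1, rep(0, 50), d$M), "conditions")
  expect_error(fit_pair(d$y[1:4], d$x1[1:4], d$x2[1:4], d$M[1:4]),
               "at least 6")
  expect_no_error(fit_pair(d$y, d$x1, rep(c(0, 1), 25), d$M))
  # perfectly collinear design errors out
  expect_error(lincmir:::qp_irls(cbind(1, d$x1, d$x1), d$y, log(d$M)),
               "singular")
})

test_that("scaling the offset shifts only the intercept, exactly", {
  d <- sim_pair_data(seed = 9)
  f <- fit_pair(d$y, d$x1, d$x2, d$M)
  f10 <- fit_pair(d$y, d$x1, d$x2, d$M * 10)
  expect_lt(abs((coef(f10)["b0"] - coef(f)["b0"]) + log(10)), 1e-6)
  expect_lt(max(abs(coef(f10)[-1] - coef(f)[-1])), 1e-8)
  expect_lt(max(abs(f10$se - f$se)), 1e-8)
})

test_that("pair_glm methods are coherent", {
  d <- sim_pair_data(seed = 10, phi = 1.5)
  f <- fit_pair(d$y, d$x1, d$x2, d$M, pair_id = "m:l")
  expect_named(coef(f), c("b0", "b1", "b2", "b3"))
  expect_equal(dim(vcov(f)), c(4L, 4L))
  expect_equal(unname(sqrt(diag(vcov(f)))), unname(f$se))
  expect_equal(predict(f), unname(fitted(f)))
  expect_equal(predict(f, type = "link"), unname(log(fitted(f))))
  nd <- list(x1 = 0, x2 = 0, M = 1e6)
  expect_equal(predict(f, nd, type = "link"),
               unname(coef(f)["b0"] + log(1e6)))
  r <- residuals(f)
  expect_equal(r, (f$y - fitted(f)) / sqrt(fitted(f)))
  expect_equal(sum(residuals(f, "pearson")^2) / f$df.residual, f$dispersion)
  s <- summary(f)
  expect_s3_class(s, "summary.pair_glm")
  expect_equal(unname(s$coefficients[, 1]), unname(coef(f)))
  expect_output(print(f), "Quasi-Poisson")
  expect_output(print(s), "Dispersion")
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(length(d$y), 3L))
  expect_true(all(sim >= 0))
  pdf(NULL)
  expect_silent(plot(f))
  dev.off()
})

test_that("simulated counts from a fit match its moments", {
  d <- sim_pair_data(seed = 12, phi = 2)
  f <- fit_pair(d$y, d$x1, d$x2, d$M)
  set.seed(5)
  sims <- as.matrix(simulate(f, nsim = 400))
  mu <- fitted(f)
  # unbiased mean (pooled over observations to average out MC noise)
  expect_lt(abs(mean(rowMeans(sims) / mu) - 1), 0.05)
  vr <- apply(sims, 1, var) / mu
  # variance inflation near the estimated dispersion on average
  expect_lt(abs(mean(vr) - f$dispersion), 0.35)
  # a phi ~ 1 fit simulates plain Poisson (no inflation)
  d1 <- sim_pair_data(seed = 3, phi = 1)
  f1 <- fit_pair(d1$y, d1$x1, d1$x2, d1$M)
  set.seed(6)
  s1 <- as.matrix(simulate(f1, nsim = 400))
  expect_lt(mean(apply(s1, 1, var) / fitted(f1)), 1.3)
})

test_that("interaction rule: non-significant b3 triggers a reduced refit", {
  d <- sim_pair_data(seed = 13, beta = c(-12, -0.8, 0.3, 0), phi = 1.5)
  f <- fit_pair(d$y, d$x1, d$x2, d$M)
  cl <- classify_pair(f)
  if (f$pvalues["b3"] >= 0.05) {
    expect_true(cl$reduced_used)
    expect_false(cl$condition_specific)
    expect_true(cl$fit_used$reduced)
    # reduced model re-estimates dispersion on its own residual df
    expect_equal(cl$fit_used$df.residual, length(d$y) - 3L)
  }
  # strong interaction keeps the full model
  d2 <- sim_pair_data(seed = 14, beta = c(-12, -0.2, 0.3, -1.5), phi = 1)
  f2 <- fit_pair(d2$y, d2$x1, d2$x2, d2$M)
  cl2 <- classify_pair(f2)
  expect_true(cl2$condition_specific)
  expect_false(cl2$reduced_used)
})

test_that("bh_fdr equals the textbook step-up on random inputs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(15)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
  # ties keep identical q
  p <- c(0.05, 0.05, 0.7)
  q <- bh_fdr(p)
  expect_equal(q[1], q[2])
})

test_that("call_pairs flags negative-b1 pairs below the FDR cutoff only", {
  set.seed(16)
  n <- 20
  M <- round(runif(n, 4e4, 6e4))
  x1 <- matrix(rnorm(3 * n, 9, 1), nrow = 3,
               dimnames = list(c("mA", "mB", "mC"), sprintf("s%02d", 1:n)))
  cond <- rep(0:1, each = 10)
  counts <- rbind(
    tDown = rnbinom(n, mu = M * exp(-4.5 - 0.8 * (x1["mA", ] - 9)),
                    size = 50),
    tNull = rnbinom(n, mu = M * exp(-4.5), size = 50),
    tUp = rnbinom(n, mu = M * exp(-4.5 + 0.8 * (x1["mC", ] - 9)), size = 50)
  )
  colnames(counts) <- sprintf("s%02d", 1:n)
  pairs <- data.frame(
    pair_id = c("a", "b", "c"),
    target_id = c("tDown", "tNull", "tUp"),
    mirna_id = c("mA", "mB", "mC"), family = "lincrna"
  )
  res <- call_pairs(pairs, counts, x1, cond, M)
  expect_true(all(res$fitted))
  expect_true(res$reverse_correlated[1])
  expect_lt(res$beta1[1], -0.4)
  # the null pair carries no real signal
  expect_lt(abs(res$beta1[2]), 0.4)
  expect_gt(res$p_beta1[2], res$p_beta1[1])
  # positive correlation never calls reverse, regardless of significance
  expect_false(res$reverse_correlated[3])
  expect_true(res$beta1[3] > 0)
  # fdr_cutoff = 0 shuts everything off
  res0 <- call_pairs(pairs, counts, x1, cond, M, fdr_cutoff = 0)
  expect_false(any(res0$reverse_correlated))
})
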