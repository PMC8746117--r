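test_that("OLS recovers known VAR coefficients and is deterministic", {
  tr <- generate_var_truth(
    data.frame(from = c(2, 1), to = c(1, 2), strength = c(0, 0.3)),
    n_channels = 2, self = 0.45)
  tr$A[1, 1, 1] <- 0.5; tr$A[2, 2, 1] <- 0.4   # A1 = [[0.5, 0], [0.3, 0.4]]
  x <- sample_var(tr, 30000, seed = 10)
  m <- fit_mvar(x, 1)
  expect_lt(max(abs(m$A[, , 1] - tr$A[, , 1])), 0.02)
  expect_lt(max(abs(m$Sigma - diag(2))), 0.05)

  # refitting fixed data is bitwise identical
  expect_identical(fit_mvar(x, 1), fit_mvar(x, 1))

  # independent white noise: off-diagonal coefficients within 3 SE of 0
  xw <- matrix(rnorm(2 * 20000), 20000, 2,
               dimnames = list(NULL, c("a", "b")))
  set.seed(77); xw <- matrix(rnorm(2 * 20000), 20000, 2)
  colnames(xw) <- c("a", "b")
  mw <- fit_mvar(xw, 1)
  se <- 1 / sqrt(nrow(xw))
  expect_lt(abs(mw$A[1, 2, 1]), 3 * se)
  expect_lt(abs(mw$A[2, 1, 1]), 3 * se)

  # errors: constant channel, too-short series
  bad <- cbind(x[1:1000, 1], 1)
  colnames(bad) <- c("x1", "flat")
  expect_error(fit_mvar(bad, 2), "flat")
  expect_error(fit_mvar(x[1:20, ], 10), "T > M")
})

test_that("AIC is the penalized log-determinant and behaves under nesting", {
  tr <- generate_var_truth(data.frame(from = 1, to = 2, strength = 0.4,
                                      lag = 2), n_channels = 2, p = 2,
                           self = 0.4)
  x <- sample_var(tr, 8000, seed = 30)
  m <- fit_mvar(x, 3)
  ld <- determinant(m$Sigma, logarithm = TRUE)
  expect_equal(mvar_aic(m),
               as.numeric(ld$modulus) + 2 * 3 * 4 / m$n_eff)

  sel <- select_order(x, p_max = 8)
  tab <- attr(sel, "aic_table")
  # least-squares nesting on the common sample: log det never increases
  expect_true(all(diff(tab$logdet_mle) <= 1e-12))
  expect_equal(sel$p, tab$p[which.min(tab$aic)])

  # white noise prefers the smallest candidate order
  set.seed(8)
  xw <- matrix(rnorm(3 * 5000), 5000, 3)
  selw <- select_order(xw, p_max = 6)
  expect_equal(selw$p, 1L)

  # single candidate and determinism
  expect_equal(select_order(x, p_max = 1)$p, 1L)
  expect_identical(select_order(x, p_max = 5), select_order(x, p_max = 5))
})

test_that("GPDC matches hand evaluation and its algebraic identities", {
  # white-noise model: GPDC is the identity pattern at all frequencies
  wn <- new_mvar <- fit_mvar(local({set.seed(3)
    matrix(rnorm(4000), 2000, 2)}), 1)
  wn$A[] <- 0
  spw <- gpdc(wn, 33)
  for (f in c(1, 17, 33)) {
    expect_equal(diag(spw$values[, , f]), c(x1 = 1, x2 = 1), tolerance = 1e-12)
    expect_equal(spw$values[1, 2, f], 0, tolerance = 1e-12)
    expect_equal(spw$values[2, 1, f], 0, tolerance = 1e-12)
  }

  # hand evaluation at lambda = 0 for A1 = [[0.4, 0], [0.5, 0]], unit noise:
  # Abar(0) column 1 is (1 - 0.4, -0.5); GPDC_21 = 0.5 / sqrt(0.36 + 0.25)
  m <- wn
  m$A[, , 1] <- rbind(c(0.4, 0), c(0.5, 0))
  m$Sigma <- diag(2)
  sp <- gpdc(m, 11)
  expect_equal(sp$values[2, 1, 1], 0.5 / sqrt(0.61), tolerance = 1e-12)
  # generic lambda against a direct transcription of the definition
  lam <- sp$lambda[7]
  abar_col1 <- c(1 - 0.4 * exp(-2i * pi * lam), -0.5 * exp(-2i * pi * lam))
  expect_equal(sp$values[2, 1, 7],
               Mod(abar_col1[2]) / sqrt(sum(Mod(abar_col1)^2)),
               tolerance = 1e-12)

  # column normalization + range on fitted random stable models
  tr <- generate_var_truth(
    data.frame(from = c(1, 2, 3), to = c(2, 3, 1), strength = 0.4),
    n_channels = 3, self = 0.3)
  x <- sample_var(tr, 4000, seed = 12)
  spx <- gpdc(fit_mvar(x, 2), 64)
  expect_lt(max(abs(apply(spx$values^2, c(2, 3), sum) - 1)), 1e-8)
  expect_true(all(spx$values >= 0 & spx$values <= 1))

  # scale invariance: rescaling one channel leaves GPDC untouched
  xs <- x; xs[, 2] <- xs[, 2] * 37
  sps <- gpdc(fit_mvar(xs, 2), 64)
  expect_lt(max(abs(sps$values - spx$values)), 1e-6)

  # degenerate channel is refused
  md <- fit_mvar(x, 2)
  md$Sigma[1, 1] <- 0
  expect_error(gpdc(md), "degenerate")
})

test_that("edge summaries collapse the spectrum as documented", {
  tr <- generate_var_truth("chain3")
  sp <- analytic_gpdc(tr, 101)
  # constant-spectrum arithmetic on a synthetic spectrum object
  const <- sp
  const$values[] <- 0.3
  expect_equal(unname(edge_summary(const, "peak")[2, 1]), 0.3)
  expect_equal(unname(edge_summary(const, "mean")[2, 1]), 0.3)
  expect_equal(unname(edge_summary(const, "auc")[2, 1]), 0.15,
               tolerance = 1e-12)
  # diagonal forced to zero
  expect_equal(unname(diag(edge_summary(sp, "peak"))), rep(0, 3))
  # peak dominates mean edgewise
  pk <- edge_summary(sp, "peak"); mn <- edge_summary(sp, "mean")
  expect_true(all(pk >= mn - 1e-12))
})

test_that("conditioning modes agree where they must and differ where they must", {
  tr <- generate_var_truth("chain3")
  x <- sample_var(tr, 6000, seed = 40)

  full_all <- conditioned_gpdc(x, colnames(x), mode = "full", p_max = 6)
  sub_all <- conditioned_gpdc(x, colnames(x), mode = "subset", p_max = 6)
  expect_equal(full_all, sub_all, tolerance = 1e-12, ignore_attr = TRUE)

  pw <- conditioned_gpdc(x, colnames(x), mode = "pairwise", p_max = 6)
  expect_equal(unname(diag(pw)), rep(0, 3))
  expect_equal(sum(pw != 0), 3 * 2)   # all ordered off-diagonal entries filled

  # mediated chain: bivariate x1 -> x3 looks causal, trivariate does not
  expect_gt(pw["x3", "x1"], full_all["x3", "x1"])

  expect_error(conditioned_gpdc(x, c("x1", "nope")), "not found")
  expect_error(conditioned_gpdc(x, "x1"), "at least 2")
})
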