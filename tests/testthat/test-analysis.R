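test_that("pearson wrapper validates and matches the definitional formula", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(1)
  a <- rnorm(1000); b <- 0.3 * a + rnorm(1000)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

make_edge_table <- function(fln, peaks) {
  # peaks: list of M x M matrices, one per simulation
  spectra <- lapply(peaks, function(p) list(peak = p, mean = p / 2,
                                            auc = p / 4))
  edge_table(fln, spectra)
}

test_that("edge tables index edges correctly and drive correlations", {
  fln <- generate_fln(6, density = 1, seed = 2)
  id <- unclass(fln)                      # make GPDC == FLN edgewise
  tab <- make_edge_table(fln, list(id, id))
  expect_equal(nrow(tab), 6 * 5 * 2)
  expect_false(any(tab$source == tab$target))
  # FLN constant across simulations per edge
  chk <- tab |> dplyr::group_by(source, target) |>
    dplyr::summarise(v = dplyr::n_distinct(fln), .groups = "drop")
  expect_true(all(chk$v == 1))

  expect_equal(fln_gpdc_correlation(tab, "pooled"), 1)
  per <- fln_gpdc_correlation(tab, "per_simulation")
  expect_equal(per$r, c(1, 1))

  # permuting GPDC across edges destroys the correlation
  big <- generate_fln(19, density = 1, seed = 3)
  set.seed(5)
  noise <- matrix(runif(19 * 19), 19, 19)
  perm <- unclass(big)
  off <- which(row(perm) != col(perm))
  perm[off] <- sample(perm[off])
  tabp <- make_edge_table(big, list(perm))
  expect_lt(abs(fln_gpdc_correlation(tabp, "pooled")), 0.1)

  expect_error(fln_gpdc_correlation(tab[0, ]), "empty")
})

test_that("edge bootstrap is consistent, degenerate-exact and reproducible", {
  fln <- generate_fln(19, density = 1, seed = 4)
  id <- unclass(fln)
  tab <- make_edge_table(fln, list(id))
  bs <- bootstrap_edges(tab, n_edges = 80, n_boot = 50, seed = 1)
  expect_equal(bs$mean_r, 1)              # GPDC == FLN -> every sample r = 1

  set.seed(9)
  noisy <- pmax(id * (1 + 0.3 * matrix(rnorm(361), 19, 19)), 0)
  tabn <- make_edge_table(fln, list(noisy))
  full_r <- fln_gpdc_correlation(tabn, "pooled")
  bsn <- bootstrap_edges(tabn, n_edges = 80, n_boot = 400, seed = 2)
  sd_bs <- sd(attr(bsn, "samples"))
  expect_lt(abs(bsn$mean_r - full_r), 3 * sd_bs / sqrt(400) + 0.02)
  expect_true(bsn$ci_lo <= bsn$mean_r && bsn$mean_r <= bsn$ci_hi)

  expect_identical(bootstrap_edges(tabn, n_boot = 50, seed = 3),
                   bootstrap_edges(tabn, n_boot = 50, seed = 3))
  expect_error(bootstrap_edges(tab[1:10, ], n_edges = 80), "fewer edges")
})

test_that("edgewise CV matches a two-pass oracle and aggregates per area", {
  fln <- generate_fln(8, density = 1, seed = 6)
  set.seed(7)
  peaks <- lapply(1:5, function(i) {
    p <- unclass(fln) * matrix(exp(rnorm(64, sd = 0.3)), 8, 8)
    diag(p) <- 0
    p
  })
  tab <- make_edge_table(fln, peaks)
  cvr <- cv_analysis(tab, centrality_table(fln))

  # independent two-pass SD/mean oracle for one edge
  e <- tab[tab$source == "A2" & tab$target == "A1", ]
  mu <- sum(e$gpdc_peak) / 5
  sdv <- sqrt(sum((e$gpdc_peak - mu)^2) / 4)
  got <- cvr$edges[cvr$edges$source == "A2" & cvr$edges$target == "A1", ]
  expect_equal(got$cv, sdv / mu, tolerance = 1e-12)

  # per-area sums over the area's outgoing and incoming edges
  src_sum <- sum(cvr$edges$cv[cvr$edges$source == "A3"])
  expect_equal(cvr$areas$cv_source_sum[cvr$areas$area == "A3"], src_sum)
  expect_named(cvr$correlations, c("measure", "role", "r"))
  expect_equal(nrow(cvr$correlations), 4)
  expect_true(all(abs(cvr$correlations$r) <= 1))

  # identical GPDC across simulations -> all CV zero
  same <- make_edge_table(fln, rep(list(peaks[[1]]), 3))
  cv0 <- cv_analysis(same)
  expect_true(all(cv0$edges$cv == 0, na.rm = TRUE))

  # zero-mean edges are flagged and excluded
  z <- peaks
  for (i in 1:5) z[[i]][1, 2] <- 0
  cvz <- cv_analysis(make_edge_table(fln, z))
  expect_true(cvz$edges$flagged[cvz$edges$target == "A1" &
                                  cvz$edges$source == "A2"])
  expect_error(cv_analysis(make_edge_table(fln, peaks[1:2])), ">= 3")
})

test_that("activity-flow estimates obey their algebraic identities", {
  fln <- generate_fln(10, density = 1, seed = 8)
  labels <- rownames(fln)

  # single-source arithmetic
  one <- matrix(0, 2, 2); one[1, 2] <- 1
  f2 <- fln_matrix(one + t(one) * 0.3)
  act1 <- estimated_activity(f2, rates = c(A1 = 2, A2 = 5))
  expect_equal(act1$p_fln[1], 1 * 5)

  # uniform rates factorize through in-strength, exactly
  rates <- stats::setNames(rep(4, 10), labels)
  act <- estimated_activity(fln, rates = rates)
  expect_equal(act$p_fln, 4 * unname(in_strength(fln)), tolerance = 1e-14)

  # replacing GPDC by FLN reproduces p_fln exactly
  set.seed(3)
  rr <- stats::setNames(runif(10, 2, 6), labels)
  act2 <- estimated_activity(fln, unclass(fln), rr)
  expect_equal(act2$p_gpdc, act2$p_fln, tolerance = 1e-14)
  cors <- attr(act2, "correlations")
  expect_equal(cors$r[cors$pathway == "gpdc"], cors$r[cors$pathway == "fln"])
})

test_that("Welch t + Holm matches direct formulas and dominates Bonferroni", {
  # identical groups: p = 1, no rejection
  same <- list(c(1, 2, 3))
  wh <- welch_holm(same, same)
  expect_equal(wh$p, 1)
  expect_false(wh$reject)

  # Welch statistic/p against the definitional computation
  set.seed(11)
  a <- rnorm(14, 0, 1); b <- rnorm(9, 0.8, 2)
  res <- welch_holm(list(a), list(b))
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_direct <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_direct <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_direct <- 2 * stats::pt(-abs(t_direct), df_direct)
  expect_equal(res$t, t_direct, tolerance = 1e-10)
  expect_equal(res$df, df_direct, tolerance = 1e-10)
  expect_equal(res$p, p_direct, tolerance = 1e-10)

  # Holm step-down arithmetic: (0.01, 0.02, 0.03) all rejected at 0.05
  ps <- c(0.01, 0.02, 0.03)
  expect_equal(stats::p.adjust(ps, "holm"), c(0.03, 0.04, 0.04))
  expect_true(all(stats::p.adjust(ps, "holm") < 0.05))

  # Holm rejects whatever Bonferroni rejects (uniformly more powerful)
  for (i in 1:20) {
    p <- runif(8)^2
    holm <- stats::p.adjust(p, "holm") < 0.05
    bonf <- stats::p.adjust(p, "bonferroni") < 0.05
    expect_true(all(holm[bonf]))
  }
})

test_that("cluster experiment bookkeeping on a VAR stand-in network", {
  # 6-channel VAR system whose coupling strengths play the role of FLN
  set.seed(20)
  m6 <- matrix(runif(36, 0.02, 0.12), 6, 6); diag(m6) <- 0
  m6 <- m6 / (1.6 * max(rowSums(m6)))
  fln <- fln_matrix(m6, paste0("A", 1:6))
  topo <- tidy(fln) |> dplyr::transmute(
    from = match(source, rownames(fln)), to = match(target, rownames(fln)),
    strength = fln)
  tr <- generate_var_truth(topo, n_channels = 6, self = 0.4)
  x <- sample_var(tr, 4000, seed = 21)
  colnames(x) <- rownames(fln)

  res <- cluster_experiment(x, fln, sizes = c(3, 6), n_clusters = 4,
                            modes = c("full", "subset"), p_max = 4, seed = 22)
  expect_s3_class(res, "cluster_experiment")
  expect_equal(nrow(res), 2 * 4 * 1 * 2)
  expect_true(all(res$r >= -1 & res$r <= 1))

  # at size = N all modes see the same channels: full == subset, t = 0
  at6 <- res[res$size == 6, ]
  rf <- at6$r[at6$mode == "full"]; rs <- at6$r[at6$mode == "subset"]
  expect_equal(rf, rs, tolerance = 1e-10)

  ct <- cluster_tests(res)
  expect_named(ct$summary, c("size", "mode", "mean_r", "sd_r", "n"))
  # subset-conditioned correlation improves with cluster size (within 1 SD)
  sub_sm <- ct$summary[ct$summary$mode == "subset", ]
  sub_sm <- sub_sm[order(sub_sm$size), ]
  expect_true(all(diff(sub_sm$mean_r) >= -sub_sm$sd_r[-nrow(sub_sm)]))
  t6 <- ct$tests[ct$tests$size == 6 & ct$tests$mode == "subset", ]
  expect_equal(t6$t, 0, tolerance = 1e-8)
  expect_false(t6$reject)

  # determinism of the cluster draws
  res2 <- cluster_experiment(x, fln, sizes = c(3, 6), n_clusters = 4,
                             modes = c("full", "subset"), p_max = 4,
                             seed = 22)
  expect_equal(res$r, res2$r)

  expect_error(cluster_experiment(x, fln, sizes = 2), "below 3")
  expect_error(cluster_experiment(x, fln, sizes = 7), "exceeds")
})
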