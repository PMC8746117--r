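#' Pearson product-moment correlation
#'
#' Thin validated wrapper around the sample correlation used by all
#' structure-function analyses: errors (instead of returning `NA`) on
#' length mismatch, fewer than 3 points, or zero variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Per-edge table of structural and functional connectivity
#'
#' One row per directed edge per simulation, carrying the structural weight
#' (FLN) and the GPDC summaries estimated from that simulation's LFP. This
#' is the tidy backbone of the correlation, variability and cluster
#' analyses. Self-edges are excluded.
#'
#' @param fln an [fln_matrix()].
#' @param spectra a list of [gpdc()] results (one per simulation), or a
#'   list of per-simulation named lists `list(peak =, mean =, auc =)` of
#'   M x M matrices.
#' @param fln_threshold keep edges with `FLN > fln_threshold`; the default 0
#'   keeps every structurally present edge (with a near-complete connectome
#'   this drops almost nothing).
#' @return a tibble with columns `source`, `target`, `sim`, `fln`,
#'   `gpdc_peak`, `gpdc_mean`, `gpdc_auc`.
#' @export
edge_table <- function(fln, spectra, fln_threshold = 0) {
  stopifnot(inherits(fln, "fln_matrix"), length(spectra) >= 1)
  labels <- rownames(fln)
  n <- nrow(fln)
  off <- which(row(fln) != col(fln))
  per_sim <- purrr::imap(spectra, function(sp, sim_id) {
    if (inherits(sp, "gpdc_spectrum")) {
      sp <- list(peak = edge_summary(sp, "peak"),
                 mean = edge_summary(sp, "mean"),
                 auc = edge_summary(sp, "auc"))
    }
    stopifnot(all(dim(sp$peak) == c(n, n)))
    tibble::tibble(
      target = labels[row(fln)[off]],
      source = labels[col(fln)[off]],
      sim = sim_id,
      fln = unclass(fln)[off],
      gpdc_peak = sp$peak[off],
      gpdc_mean = sp$mean[off],
      gpdc_auc = sp$auc[off]
    )
  })
  out <- dplyr::bind_rows(per_sim)
  dplyr::filter(out, .data$fln > fln_threshold)
}

#' Correlation between structural and directed functional connectivity
#'
#' Pearson correlation between FLN and a GPDC edge summary, either pooling
#' all (edge, simulation) points into one coefficient or computing one
#' coefficient per simulation over edges.
#'
#' @param table an [edge_table()].
#' @param scope `"per_simulation"` (one r per simulation) or `"pooled"`.
#' @param measure which GPDC summary column to correlate with FLN.
#' @return pooled scope: a single number. Per-simulation scope: a tibble
#'   with columns `sim`, `r`.
#' @export
fln_gpdc_correlation <- function(table,
                                 scope = c("per_simulation", "pooled"),
                                 measure = "gpdc_peak") {
  scope <- match.arg(scope)
  if (nrow(table) == 0) stop("empty edge table")
  if (scope == "pooled") {
    return(pearson(table$fln, table[[measure]]))
  }
  table |>
    dplyr::group_by(.data$sim) |>
    dplyr::summarise(r = pearson(.data$fln, .data[[measure]]),
                     .groups = "drop")
}

#' Bootstrap the structure-function correlation over edges
#'
#' Repeatedly samples `n_edges` edges with replacement from the (pooled)
#' edge table, computes the FLN-GPDC Pearson correlation per sample, and
#' returns the bootstrap mean and percentile interval.
#'
#' @param table an [edge_table()].
#' @param n_edges edges per bootstrap sample (default 80).
#' @param n_boot number of bootstrap samples (default 1000).
#' @param conf percentile-interval coverage.
#' @param measure GPDC summary column.
#' @param seed optional integer for a reproducible resampling.
#' @return a tibble with columns `mean_r`, `ci_lo`, `ci_hi`, `n_boot`,
#'   `n_edges`; the per-sample correlations in attribute `"samples"`.
#' @export
bootstrap_edges <- function(table, n_edges = 80, n_boot = 1000,
                            conf = 0.95, measure = "gpdc_peak",
                            seed = NULL) {
  if (nrow(table) < n_edges) {
    stop("fewer edges (", nrow(table), ") than requested (", n_edges, ")")
  }
  draw <- function() {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(table), n_edges, replace = TRUE)
      pearson(table$fln[idx], table[[measure]][idx])
    }, numeric(1))
  }
  rs <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  alpha <- (1 - conf) / 2
  out <- tibble::tibble(
    mean_r = mean(rs),
    ci_lo = unname(stats::quantile(rs, alpha)),
    ci_hi = unname(stats::quantile(rs, 1 - alpha)),
    n_boot = n_boot, n_edges = n_edges
  )
  attr(out, "samples") <- rs
  out
}

#' Variability of functional-connectivity estimates vs. centrality
#'
#' Per-edge coefficient of variation (SD / mean) of the GPDC peak across
#' repeated simulations; per-area sums of the CVs over outgoing (the area
#' as source) and incoming (the area as target) edges; and Pearson
#' correlations of those sums against nodal in-strength (and eigenvector
#' centrality when supplied). Raw SD sums are reported alongside. Edges
#' whose mean GPDC is 0 have an undefined CV: they are flagged and excluded
#' from the sums.
#'
#' @param table an [edge_table()] with >= 3 simulations.
#' @param centrality optional [centrality_table()]; computed measures are
#'   matched by area label.
#' @return a list of class `cv_analysis` with elements
#'   * `edges` — tibble `source`, `target`, `mean_gpdc`, `sd_gpdc`, `cv`,
#'     `flagged`;
#'   * `areas` — tibble `area`, `cv_source_sum`, `cv_target_sum`,
#'     `sd_source_sum`, `sd_target_sum` (+ centrality columns when given);
#'   * `correlations` — tibble `measure`, `role`, `r` (when centrality
#'     given).
#' @export
cv_analysis <- function(table, centrality = NULL) {
  n_sims <- length(unique(table$sim))
  if (n_sims < 3) stop("need >= 3 simulations for a CV analysis")
  edges <- table |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(mean_gpdc = mean(.data$gpdc_peak),
                     sd_gpdc = stats::sd(.data$gpdc_peak),
                     .groups = "drop") |>
    dplyr::mutate(flagged = .data$mean_gpdc == 0,
                  cv = dplyr::if_else(.data$flagged, NA_real_,
                                      .data$sd_gpdc / .data$mean_gpdc))
  ok <- dplyr::filter(edges, !.data$flagged)
  src <- ok |>
    dplyr::group_by(area = .data$source) |>
    dplyr::summarise(cv_source_sum = sum(.data$cv),
                     sd_source_sum = sum(.data$sd_gpdc), .groups = "drop")
  tgt <- ok |>
    dplyr::group_by(area = .data$target) |>
    dplyr::summarise(cv_target_sum = sum(.data$cv),
                     sd_target_sum = sum(.data$sd_gpdc), .groups = "drop")
  areas <- dplyr::full_join(src, tgt, by = "area")
  correlations <- NULL
  if (!is.null(centrality)) {
    areas <- dplyr::inner_join(areas, centrality, by = "area")
    cors <- list(
      c("in_strength", "source", "cv_source_sum"),
      c("in_strength", "target", "cv_target_sum"),
      c("eigenvector", "source", "cv_source_sum"),
      c("eigenvector", "target", "cv_target_sum")
    )
    correlations <- purrr::map_dfr(cors, function(cc) {
      if (!cc[1] %in% names(areas)) return(NULL)
      tibble::tibble(measure = cc[1], role = cc[2],
                     r = pearson(areas[[cc[1]]], areas[[cc[3]]]))
    })
  }
  structure(list(edges = edges, areas = areas, correlations = correlations),
            class = "cv_analysis")
}

#' Activity flow estimated through structural or functional pathways
#'
#' Estimated input activity of each target area as the connectivity-weighted
#' sum of the source areas' firing rates:
#' `P_i^FLN = sum_{j != i} FLN[i, j] * r_j` and analogously with the GPDC
#' peak matrix. When both estimates are correlated with the target areas'
#' own rates, the structural pathway should track the rates more tightly
#' than the functional estimate.
#'
#' @param fln an [fln_matrix()].
#' @param gpdc_matrix M x M GPDC peak matrix (rows = targets), e.g. from
#'   [edge_summary()]; may be `NULL` to compute only `p_fln`.
#' @param rates named vector of per-area firing rates (Hz), or a
#'   [mean_rates()] tibble (its excitatory rows are used).
#' @return a tibble with columns `area`, `rate_hz`, `p_fln` (and `p_gpdc`),
#'   with the rate correlations in attribute `"correlations"` (tibble
#'   `pathway`, `r`).
#' @export
estimated_activity <- function(fln, gpdc_matrix = NULL, rates) {
  if (is.data.frame(rates)) {
    rr <- dplyr::filter(rates, .data$type == "exc")
    rates <- stats::setNames(rr$rate_hz, rr$area)
  }
  labels <- rownames(fln)
  stopifnot(all(labels %in% names(rates)))
  r <- rates[labels]
  m <- unclass(fln)          # zero diagonal: the j != i restriction is built in
  out <- tibble::tibble(area = labels, rate_hz = unname(r),
                        p_fln = unname(drop(m %*% r)))
  # correlation undefined for < 3 areas or constant rates: report NA
  safe_r <- function(x, y) {
    tryCatch(pearson(x, y), error = function(e) NA_real_)
  }
  cors <- tibble::tibble(pathway = "fln",
                         r = safe_r(out$p_fln, out$rate_hz))
  if (!is.null(gpdc_matrix)) {
    g <- as.matrix(gpdc_matrix)
    stopifnot(all(dim(g) == dim(m)))
    diag(g) <- 0
    out$p_gpdc <- unname(drop(g %*% r))
    cors <- dplyr::bind_rows(
      cors, tibble::tibble(pathway = "gpdc",
                           r = safe_r(out$p_gpdc, out$rate_hz)))
  }
  attr(out, "correlations") <- cors
  out
}

#' Welch t-tests with Holm-Bonferroni correction
#'
#' Unequal-variance (Welch) two-sample t-tests of condition-matched groups,
#' with the step-down Holm adjustment controlling the family-wise error
#' over conditions.
#'
#' @param groups_a,groups_b lists of numeric vectors (same length and
#'   condition order; each vector n >= 2).
#' @param conditions optional condition labels.
#' @param alpha family-wise error level for the decisions.
#' @return a tibble with columns `condition`, `t`, `df`, `p`, `p_holm`,
#'   `reject`.
#' @export
welch_holm <- function(groups_a, groups_b, conditions = NULL, alpha = 0.05) {
  stopifnot(length(groups_a) == length(groups_b))
  if (is.null(conditions)) conditions <- seq_along(groups_a)
  res <- purrr::map2_dfr(groups_a, groups_b, function(a, b) {
    if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
    stderr <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (stderr < 10 * .Machine$double.eps * max(abs(mean(a)), abs(mean(b)))) {
      # numerically constant groups (the degenerate case t.test refuses)
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        return(tibble::tibble(t = 0, df = NA_real_, p = 1))
      }
      stop("zero variance in both groups with unequal means")
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value)
  })
  res <- dplyr::mutate(res,
                       condition = conditions,
                       p_holm = stats::p.adjust(.data$p, method = "holm"),
                       reject = .data$p_holm < alpha,
                       .before = 1)
  res
}

#' Partial-observation cluster experiment
#'
#' Emulates recording only a subset ("cluster") of areas: for each cluster
#' size, draws random area subsets (uniform, without replacement within a
#' subset; subsets may repeat across draws), and for each subset,
#' simulation and conditioning mode computes the Pearson correlation
#' between the subset's FLN edges and its GPDC edge summaries under
#' [conditioned_gpdc()]'s `full` / `subset` / `pairwise` regimes.
#'
#' The full-connectome fit is computed once per simulation and reused
#' across subsets, since its model does not depend on the subset.
#'
#' @param lfp_set a single preprocessed `lfp_record` (see [compute_lfp()]) (or signal matrix) or a
#'   list of them, one per simulation.
#' @param fln an [fln_matrix()] whose labels match the LFP channels.
#' @param sizes cluster sizes to test (each >= 3; correlations over fewer
#'   than 6 directed edges are too unstable and are rejected).
#' @param n_clusters random clusters per size (default 150).
#' @param modes conditioning regimes to evaluate.
#' @param p_max,n_freq passed to the MVAR/GPDC fits.
#' @param seed optional integer making the cluster draws reproducible.
#' @return an object of class `cluster_experiment`: tibble with columns
#'   `size`, `cluster`, `sim`, `mode`, `r`.
#' @export
cluster_experiment <- function(lfp_set, fln, sizes = 3:15, n_clusters = 150,
                               modes = c("full", "subset", "pairwise"),
                               p_max = 50, n_freq = 512, seed = NULL) {
  if (!is.list(lfp_set) || inherits(lfp_set, "lfp_record")) {
    lfp_set <- list(lfp_set)
  }
  sigs <- lapply(lfp_set, as_signal_matrix)
  labels <- rownames(fln)
  stopifnot(all(vapply(sigs, function(s) all(labels %in% colnames(s)),
                       logical(1))))
  if (any(sizes < 3)) stop("cluster sizes below 3 are rejected")
  if (any(sizes > length(labels))) stop("cluster size exceeds area count")
  modes <- match.arg(modes, c("full", "subset", "pairwise"),
                     several.ok = TRUE)
  run <- function() {
    full_peak <- NULL
    if ("full" %in% modes) {
      full_peak <- lapply(sigs, function(s) {
        model <- select_order(s[, labels, drop = FALSE], p_max)
        edge_summary(gpdc(model, n_freq), "peak")
      })
    }
    out <- list()
    for (size in sizes) {
      for (cl in seq_len(n_clusters)) {
        subset <- sample(labels, size)
        sub_fln <- unclass(fln)[subset, subset]
        off <- which(row(sub_fln) != col(sub_fln))
        for (s in seq_along(sigs)) {
          for (mode in modes) {
            peak <- if (mode == "full") {
              full_peak[[s]][subset, subset]
            } else {
              conditioned_gpdc(sigs[[s]], subset, mode = mode,
                               p_max = p_max, n_freq = n_freq)
            }
            out[[length(out) + 1]] <- tibble::tibble(
              size = size, cluster = cl, sim = s, mode = mode,
              r = pearson(sub_fln[off], peak[off]))
          }
        }
      }
    }
    dplyr::bind_rows(out)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(res) <- c("cluster_experiment", class(res))
  res
}

#' Summarize and test a cluster experiment
#'
#' Mean and SD of the FLN-GPDC correlation per size and mode, and Welch
#' t-tests of each partial-conditioning mode against the full-connectome
#' mode per size, Holm-Bonferroni corrected across sizes within a mode.
#'
#' @param experiment a [cluster_experiment()] result (must include the
#'   `"full"` mode for the tests).
#' @param alpha family-wise error level.
#' @return a list with `summary` (tibble `size`, `mode`, `mean_r`, `sd_r`,
#'   `n`) and `tests` (tibble `mode`, `size`, `t`, `df`, `p`, `p_holm`,
#'   `reject`, comparing the mode against `"full"`).
#' @export
cluster_tests <- function(experiment, alpha = 0.05) {
  summary <- experiment |>
    dplyr::group_by(.data$size, .data$mode) |>
    dplyr::summarise(mean_r = mean(.data$r), sd_r = stats::sd(.data$r),
                     n = dplyr::n(), .groups = "drop")
  tests <- NULL
  if ("full" %in% experiment$mode) {
    other <- setdiff(unique(experiment$mode), "full")
    tests <- purrr::map_dfr(other, function(md) {
      sizes <- sort(unique(experiment$size))
      ga <- gb <- list()
      keep <- logical(0)
      for (sz in sizes) {
        a <- experiment$r[experiment$size == sz & experiment$mode == md]
        b <- experiment$r[experiment$size == sz & experiment$mode == "full"]
        keep <- c(keep, length(a) >= 2 && length(b) >= 2)
        ga <- c(ga, list(a)); gb <- c(gb, list(b))
      }
      wh <- welch_holm(ga[keep], gb[keep], conditions = sizes[keep],
                       alpha = alpha)
      dplyr::mutate(wh, mode = md, .before = 1) |>
        dplyr::rename(size = "condition")
    })
  }
  list(summary = summary, tests = tests)
}

#' @export
autoplot.cluster_experiment <- function(object, ...) {
  sm <- cluster_tests(object)$summary
  ggplot2::ggplot(sm, ggplot2::aes(.data$size, .data$mean_r,
                                   colour = .data$mode)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                                          ymax = .data$mean_r + .data$sd_r),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = "cluster size (areas)",
                  y = "Pearson r (FLN vs GPDC peak)", colour = "conditioning")
}

#' Scatter of structural vs. functional edge weights
#'
#' @param table an [edge_table()].
#' @param measure GPDC summary column on the y axis.
#' @return a ggplot object with a linear fit overlaid.
#' @export
plot_fln_gpdc <- function(table, measure = "gpdc_peak") {
  ggplot2::ggplot(table, ggplot2::aes(.data$fln, .data[[measure]])) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::labs(x = "FLN", y = "GPDC peak")
}
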