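#' Weighted directed connectome (fraction of labeled neurons)
#'
#' An `fln_matrix` stores the structural connectome as an N x N matrix of
#' fractions of labeled neurons (FLN). Entry `[i, j]` is the FLN of the
#' projection from source area `j` to target area `i`, i.e. **rows are
#' targets, columns are sources**. All file I/O and downstream analyses use
#' this orientation.
#'
#' Invariants enforced by the constructor:
#' * square, N >= 2, finite, nonnegative entries;
#' * exactly zero diagonal (an area does not project to itself in an FLN
#'   table: intrinsic neurons are excluded from the denominator);
#' * every row sum in (0, 1]. Row sums need not equal 1 because the
#'   denominator of the fractions includes source areas outside the modeled
#'   set.
#'
#' @param values numeric N x N matrix, rows = targets, columns = sources.
#' @param area_labels character vector of N area names; defaults to the
#'   dimnames of `values` or `A1..AN`.
#' @return an object of class `fln_matrix` (a matrix with labels).
#' @export
fln_matrix <- function(values, area_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("FLN matrix must be square, got ", nrow(values), " x ", ncol(values))
  }
  n <- nrow(values)
  if (n < 2) stop("FLN matrix needs at least 2 areas")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("FLN matrix must be finite numeric")
  }
  if (any(values < 0)) stop("negative FLN entry")
  if (any(diag(values) != 0)) stop("nonzero diagonal in FLN matrix")
  if (is.null(area_labels)) {
    area_labels <- rownames(values)
    if (is.null(area_labels)) area_labels <- paste0("A", seq_len(n))
  }
  if (length(area_labels) != n) stop("area_labels length must match matrix size")
  rs <- rowSums(values)
  if (any(rs <= 0)) {
    stop("row sum of 0 for target area(s): ",
         paste(area_labels[rs <= 0], collapse = ", "))
  }
  if (any(rs > 1 + 1e-9)) {
    stop("FLN row sum > 1 for target area(s): ",
         paste(area_labels[rs > 1 + 1e-9], collapse = ", "))
  }
  dimnames(values) <- list(area_labels, area_labels)
  structure(values, class = c("fln_matrix", "matrix", "array"))
}

#' @export
print.fln_matrix <- function(x, ...) {
  cat("<fln_matrix> ", nrow(x), " areas, density ",
      format(graph_density(x), digits = 3),
      ", row sums in [", format(min(rowSums(x)), digits = 3), ", ",
      format(max(rowSums(x)), digits = 3), "]\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Inter-areal distance matrix
#'
#' Symmetric matrix of anatomical distances between area centroids, in
#' millimeters; zero diagonal. Used to derive long-range conduction delays
#' (distance / conduction speed).
#'
#' @param values numeric N x N symmetric matrix (mm).
#' @param area_labels optional character vector of area names.
#' @return an object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, area_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("distances must be finite and nonnegative")
  }
  if (max(abs(values - t(values))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be zero")
  n <- nrow(values)
  if (is.null(area_labels)) {
    area_labels <- rownames(values)
    if (is.null(area_labels)) area_labels <- paste0("A", seq_len(n))
  }
  dimnames(values) <- list(area_labels, area_labels)
  structure(values, class = c("distance_matrix", "matrix", "array"))
}

#' Read / write connectome matrices as CSV
#'
#' CSV layout: a header row of area labels, and one row per **target** area
#' whose first field is the target's label. Entry `[i, j]` is the weight from
#' source `j` (column) to target `i` (row). Scientific notation is accepted.
#'
#' @param path file path.
#' @return `read_fln()` returns a validated [fln_matrix()];
#'   `read_distances()` a [distance_matrix()].
#' @export
read_fln <- function(path) {
  m <- read_square_csv(path)
  fln_matrix(m, rownames(m))
}

#' @rdname read_fln
#' @export
read_distances <- function(path) {
  m <- read_square_csv(path)
  distance_matrix(m, rownames(m))
}

#' @rdname read_fln
#' @param x an `fln_matrix` or `distance_matrix`.
#' @export
write_fln <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname read_fln
#' @export
write_distances <- write_fln

read_square_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m), ")")
  }
  rownames(m) <- rownames(df)
  colnames(m) <- colnames(df)
  m
}

#' Nodal in-strength
#'
#' The in-strength of area i is the sum of inbound structural weights,
#' `s_i = sum_j FLN[i, j]` over sources j != i (the diagonal is zero by
#' construction). High in-strength means the area is a strongly targeted hub.
#'
#' @param fln an [fln_matrix()].
#' @return named numeric vector of in-strengths, one per area.
#' @export
in_strength <- function(fln) {
  stopifnot(inherits(fln, "fln_matrix"))
  rowSums(unclass(fln))
}

#' Eigenvector centrality of the connectome
#'
#' Dominant eigenvector of the FLN matrix, computed by power iteration and
#' oriented so all entries are nonnegative, scaled to unit L2 norm. With
#' `direction = "in"` (default) the in-edge matrix is used (row i collects
#' inputs to area i), so high centrality marks strongly targeted areas;
#' `direction = "out"` uses the transpose.
#'
#' @param fln an [fln_matrix()].
#' @param direction `"in"` or `"out"`.
#' @param tol convergence tolerance on the iterate (L2 change).
#' @param max_iter maximum power-iteration steps.
#' @return named numeric unit vector of centralities.
#' @export
eigenvector_centrality <- function(fln, direction = c("in", "out"),
                                   tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(fln, "fln_matrix"))
  direction <- match.arg(direction)
  m <- unclass(fln)
  if (direction == "out") m <- t(m)
  v <- rep(1 / sqrt(nrow(m)), nrow(m))
  for (it in seq_len(max_iter)) {
    w <- drop(m %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("power iteration collapsed to the zero vector")
    w <- w / nw
    if (sqrt(sum((w - v)^2)) < tol) {
      if (sum(w) < 0) w <- -w
      names(w) <- rownames(fln)
      return(w)
    }
    v <- w
  }
  stop("power iteration did not converge in ", max_iter, " steps")
}

#' Graph density of the connectome
#'
#' Fraction of ordered off-diagonal area pairs whose FLN exceeds `threshold`.
#' The default threshold 0 counts any positive projection as an edge, which
#' is how tracer connectome densities (~97% for the mouse cortex) are
#' reported.
#'
#' @param fln an [fln_matrix()].
#' @param threshold edges are entries strictly greater than this.
#' @return a fraction in \[0, 1\].
#' @export
graph_density <- function(fln, threshold = 0) {
  stopifnot(inherits(fln, "fln_matrix"))
  n <- nrow(fln)
  off <- unclass(fln)[row(fln) != col(fln)]
  mean(off > threshold)
}

#' Area centrality table
#'
#' Tidy summary of the connectome's centrality measures: in-strength and
#' eigenvector centrality (in-edge convention) per area.
#'
#' @param fln an [fln_matrix()].
#' @return a tibble with columns `area`, `in_strength`, `eigenvector`.
#' @export
centrality_table <- function(fln) {
  tibble::tibble(
    area = rownames(fln),
    in_strength = unname(in_strength(fln)),
    eigenvector = unname(eigenvector_centrality(fln))
  )
}

#' @export
tidy.fln_matrix <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(
    target = rep(rownames(x), times = n),
    source = rep(colnames(x), each = n),
    fln = as.vector(unclass(x))
  )[rep(seq_len(n), times = n) != rep(seq_len(n), each = n), ]
}
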