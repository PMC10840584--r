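#' Structural connectome container
#'
#' A connectome couples a nonnegative, symmetric matrix of inter-regional
#' connection weights (arbitrary streamline-count units) with a matrix of
#' inter-regional fiber distances in millimetres and a vector of region
#' labels. Both matrices are N x N with zero diagonal.
#'
#' @param weights Square numeric matrix of nonnegative connection weights.
#' @param distances Square numeric matrix of nonnegative distances (mm),
#'   same dimension as `weights`.
#' @param labels Optional character vector of unique region identifiers;
#'   defaults to `"roi_1" ... "roi_N"`.
#' @param sym_tol Relative asymmetry below which a matrix is accepted as
#'   symmetric without comment; larger asymmetries are averaged with a
#'   warning (mirroring the convention of averaging directed streamline
#'   counts into undirected edges).
#'
#' @return An object of class `sgm_connectome`: a list with elements
#'   `weights`, `distances`, `labels`, `n_regions`, and an attribute
#'   `provenance` recording any cleaning applied.
#' @export
connectome <- function(weights, distances, labels = NULL, sym_tol = 1e-8) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  if (nrow(weights) != ncol(weights))
    stop("weights matrix is not square: ", nrow(weights), " x ", ncol(weights))
  if (nrow(distances) != ncol(distances))
    stop("distances matrix is not square: ", nrow(distances), " x ", ncol(distances))
  if (nrow(weights) != nrow(distances))
    stop("size mismatch: weights is ", nrow(weights), " x ", ncol(weights),
         " but distances is ", nrow(distances), " x ", ncol(distances))
  storage.mode(weights) <- "double"
  storage.mode(distances) <- "double"
  .check_nonnegative(weights, "weights")
  .check_nonnegative(distances, "distances")

  n <- nrow(weights)
  if (n < 2L) stop("a connectome needs at least 2 regions")
  provenance <- character(0)

  w <- .clean_symmetric(weights, "weights", sym_tol)
  d <- .clean_symmetric(distances, "distances", sym_tol)
  provenance <- c(attr(w, "log"), attr(d, "log"))
  attr(w, "log") <- NULL
  attr(d, "log") <- NULL

  if (is.null(labels)) labels <- paste0("roi_", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels has length ", length(labels), " but there are ", n, " regions")
  if (anyDuplicated(labels))
    stop("labels are not unique: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  dimnames(w) <- dimnames(d) <- list(labels, labels)

  structure(
    list(weights = w, distances = d, labels = labels, n_regions = n),
    provenance = provenance,
    class = "sgm_connectome"
  )
}

.check_nonnegative <- function(m, what) {
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    shown <- utils::head(neg, 5)
    stop(what, " has negative entries at indices: ",
         paste(sprintf("(%d,%d)", shown[, 1], shown[, 2]), collapse = " "))
  }
  invisible(TRUE)
}

# Symmetrize with provenance; asymmetry beyond tol (relative to scale) warns.
.clean_symmetric <- function(m, what, sym_tol) {
  log <- character(0)
  scale <- max(abs(m), 1e-300)
  asym <- max(abs(m - t(m))) / scale
  if (asym > sym_tol) {
    warning(what, " asymmetric (relative asymmetry ", signif(asym, 3),
            "); averaging with its transpose")
    log <- c(log, sprintf("%s symmetrized (relative asymmetry %.3g)", what, asym))
    m <- (m + t(m)) / 2
  } else if (asym > 0) {
    m <- (m + t(m)) / 2
  }
  if (any(diag(m) != 0)) {
    log <- c(log, sprintf("%s diagonal zeroed", what))
    diag(m) <- 0
  }
  attr(m, "log") <- log
  m
}

#' @export
print.sgm_connectome <- function(x, ...) {
  cat("Structural connectome:", x$n_regions, "regions\n")
  offdiag <- x$weights[upper.tri(x$weights)]
  cat(sprintf("  weight range  [%.4g, %.4g], density %.2f\n",
              min(offdiag), max(offdiag), mean(offdiag > 0)))
  cat(sprintf("  distance range [%.4g, %.4g] mm\n",
              min(x$distances[upper.tri(x$distances)]),
              max(x$distances[upper.tri(x$distances)])))
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  cleaning:", paste(prov, collapse = "; "), "\n")
  invisible(x)
}

#' Load a connectome from CSV files
#'
#' Reads the weight and distance matrices from CSV (plain numeric, or with a
#' header row / first column of region labels as written by
#' [write_connectome()]), validates them, and returns a cleaned
#' [connectome()].
#'
#' @param weights_path Path to the weights CSV.
#' @param distances_path Path to the distances CSV.
#' @param labels Optional region labels (override any found in the files).
#' @return An `sgm_connectome`.
#' @export
load_connectome <- function(weights_path, distances_path, labels = NULL) {
  w <- .read_matrix_csv(weights_path)
  d <- .read_matrix_csv(distances_path)
  if (is.null(labels)) labels <- attr(w, "labels")
  attr(w, "labels") <- NULL
  attr(d, "labels") <- NULL
  connectome(w, d, labels = labels)
}

.read_matrix_csv <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks[toks != ""])))
  df <- utils::read.csv(path, header = has_header, check.names = FALSE)
  labels <- NULL
  if (ncol(df) >= 2 && !is.numeric(df[[1]])) {
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else if (has_header) {
    labels <- colnames(df)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  dimnames(m) <- NULL
  attr(m, "labels") <- labels
  m
}

#' Write a connectome to CSV files
#'
#' @param conn An `sgm_connectome`.
#' @param weights_path,distances_path Output CSV paths. Labels are written
#'   as the header row.
#' @return Invisibly, the connectome.
#' @export
write_connectome <- function(conn, weights_path, distances_path) {
  stopifnot(inherits(conn, "sgm_connectome"))
  w <- conn$weights; d <- conn$distances
  utils::write.table(w, weights_path, sep = ",", row.names = FALSE,
                     col.names = conn$labels, qmethod = "double")
  utils::write.table(d, distances_path, sep = ",", row.names = FALSE,
                     col.names = conn$labels, qmethod = "double")
  invisible(conn)
}

#' Average a matrix with its transpose
#'
#' Directed connection strengths are averaged between the two directions to
#' form undirected edge weights; the diagonal is forced to zero.
#'
#' @param weights Square nonnegative numeric matrix.
#' @return The symmetrized matrix `(A + t(A)) / 2` with zero diagonal.
#' @export
symmetrize <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("matrix is not square")
  .check_nonnegative(weights, "weights")
  s <- (weights + t(weights)) / 2
  diag(s) <- 0
  s
}

#' Degree-normalize a connectivity matrix
#'
#' @param weights Square nonnegative numeric matrix.
#' @param scheme `"row"` divides each row by its sum (rows summing to zero
#'   are left untouched: isolated regions are legal); `"symmetric"` divides
#'   entry (i,j) by `sqrt(deg_i * deg_j)` with degrees the row sums.
#' @return The normalized matrix, with the scheme recorded in attribute
#'   `"scheme"`.
#' @export
degree_normalize <- function(weights, scheme = c("row", "symmetric")) {
  scheme <- match.arg(scheme)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("matrix is not square")
  .check_nonnegative(weights, "weights")
  deg <- rowSums(weights)
  if (all(deg == 0)) stop("degenerate graph: all entries are zero")
  out <- if (scheme == "row") {
    sweep(weights, 1, ifelse(deg > 0, deg, 1), "/")
  } else {
    cdeg <- colSums(weights)
    s <- sqrt(pmax(deg, 0)) %o% sqrt(pmax(cdeg, 0))
    ifelse(s > 0, weights / s, 0)
  }
  attr(out, "scheme") <- scheme
  out
}

#' Generate a synthetic structural connectome
#'
#' Places `n_regions` points uniformly in a 140 mm cube (roughly head
#' scale), takes pairwise Euclidean distances, and sets weights to an
#' exponentially distance-decaying kernel times multiplicative lognormal
#' noise, symmetrized with zero diagonal. Weight decays with distance, so
#' synthetic graphs reproduce the negative weight-distance association of
#' tractography connectomes.
#'
#' @param n_regions Number of regions (>= 2).
#' @param seed Integer seed; the construction is reproducible given a seed.
#' @param length_scale Exponential decay length in mm (default 40).
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   lognormal edge noise (default 0.5).
#' @return An `sgm_connectome`.
#' @export
synth_connectome <- function(n_regions, seed = 1L, length_scale = 40,
                             noise_sd = 0.5) {
  if (n_regions < 2) stop("n_regions must be at least 2")
  stopifnot(length_scale > 0, noise_sd >= 0)
  rs <- .local_rng(seed)
  on.exit(rs$restore(), add = TRUE)
  pts <- matrix(stats::runif(n_regions * 3, 0, 140), ncol = 3)
  d <- as.matrix(stats::dist(pts))
  noise <- matrix(stats::rlnorm(n_regions^2, 0, noise_sd), n_regions)
  noise <- (noise + t(noise)) / 2
  w <- exp(-d / length_scale) * noise
  w <- symmetrize(w)
  diag(d) <- 0
  connectome(w, d, labels = sprintf("syn_%03d", seq_len(n_regions)))
}

# Seed-scoped RNG: set a seed without clobbering the caller's stream.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
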