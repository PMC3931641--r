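#' Validate a signed weight matrix
#'
#' Checks that a square numeric matrix is a valid signed weighted network:
#' symmetric (within tolerance), all entries in `[-1, 1]`, zero diagonal.
#' A nonzero diagonal (e.g. the unit diagonal of a correlation matrix) is
#' silently zeroed, following the convention for correlation networks.
#' Asymmetries within tolerance are symmetrized by averaging `w_ij` and
#' `w_ji`; larger asymmetries are an error.
#'
#' @param w square numeric matrix (or object coercible to one) with entries
#'   in `[-1, 1]`, e.g. a correlation matrix.
#' @param labels optional character vector of node names; defaults to
#'   existing dimnames or `V1..Vn`.
#' @param tol symmetry tolerance (default `1e-10`).
#' @return a numeric matrix of class `"signed_matrix"` with zero diagonal
#'   and dimnames set to the node labels.
#' @examples
#' w <- matrix(c(0, .5, -.5, .5, 0, .5, -.5, .5, 0), 3, 3)
#' signed_matrix(w)
#' @export
signed_matrix <- function(w, labels = NULL, tol = 1e-10) {
  w <- as.matrix(w)
  if (!is.numeric(w)) stop("weight matrix must be numeric")
  if (nrow(w) != ncol(w)) {
    stop(sprintf("weight matrix must be square, got %d x %d",
                 nrow(w), ncol(w)))
  }
  n <- nrow(w)
  asym <- abs(w - t(w))
  if (any(asym > tol)) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "matrix is not symmetric: |w[%d,%d] - w[%d,%d]| = %g exceeds tol %g",
      bad[1], bad[2], bad[2], bad[1], max(asym), tol))
  }
  w <- (w + t(w)) / 2  # absorb floating-point asymmetry
  if (any(abs(w) > 1 + tol)) {
    bad <- which(abs(w) > 1 + tol, arr.ind = TRUE)[1, ]
    stop(sprintf("|w[%d,%d]| = %g exceeds 1", bad[1], bad[2],
                 w[bad[1], bad[2]]))
  }
  w[w > 1] <- 1
  w[w < -1] <- -1
  if (any(diag(w) != 0)) {
    message("nonzero diagonal entries set to zero")
    diag(w) <- 0
  }
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(w))) rownames(w) else paste0("V", seq_len(n))
  }
  if (length(labels) != n) stop("labels length must equal node count")
  dimnames(w) <- list(labels, labels)
  class(w) <- c("signed_matrix", class(matrix()))
  w
}

#' @export
print.signed_matrix <- function(x, ...) {
  cat(sprintf("Signed weight matrix: %d nodes, %d nonzero edges (%d negative)\n",
              nrow(x), sum(x[upper.tri(x)] != 0), sum(x[upper.tri(x)] < 0)))
  invisible(x)
}

#' Threshold a signed weight matrix into a signed adjacency
#'
#' An edge is retained when its weight strictly exceeds `tau` in absolute
#' value (`|w_ij| > tau`); weights exactly equal to the threshold are
#' dropped.  With `tau = 0` every nonzero edge is kept.
#'
#' @param w a [signed_matrix()] (validated if not already).
#' @param tau nonnegative threshold; default `0` retains all nonzero edges.
#' @return an object of class `"signed_adjacency"`: a list with elements
#'   `signed` (matrix in `{-1, 0, +1}`), `unsigned` (matrix in `{0, 1}`)
#'   and `tau`.
#' @examples
#' w <- signed_matrix(matrix(c(0, .2, -.05, .2, 0, .3, -.05, .3, 0), 3, 3))
#' a <- binarize(w, tau = 0.1)
#' a$signed
#' @export
binarize <- function(w, tau = 0) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0)
  keep <- abs(w) > tau
  a_signed <- sign(unclass(w)) * keep
  a_unsigned <- abs(a_signed)
  structure(list(signed = a_signed, unsigned = a_unsigned, tau = tau),
            class = "signed_adjacency")
}

#' @export
print.signed_adjacency <- function(x, ...) {
  cat(sprintf("Signed adjacency (tau = %g): %d nodes, %d edges (%d negative)\n",
              x$tau, nrow(x$unsigned), sum(x$unsigned[upper.tri(x$unsigned)]),
              sum(x$signed[upper.tri(x$signed)] < 0)))
  invisible(x)
}

#' Unsigned node degree
#'
#' Number of neighbors of each node in the unsigned adjacency; edge signs
#' are ignored.
#'
#' @param a a [binarize()] result, or a signed/weight matrix (thresholded
#'   at 0).
#' @return integer vector of degrees, named by node label.
#' @export
node_degree <- function(a) {
  if (!inherits(a, "signed_adjacency")) a <- binarize(a)
  k <- as.integer(rowSums(a$unsigned))
  names(k) <- rownames(a$unsigned)
  k
}

#' Enumerate all triangles of a signed weighted network
#'
#' Lists every unordered triple of nodes whose three pairwise edges all
#' exceed `tau` in absolute value.  The sign of a triangle is the product
#' of the signs of its three edge weights (balance-theoretic convention),
#' and its weight is the product of the three edge weights in absolute
#' value.
#'
#' Triangle signs are invariant under reflection of a node (negating all
#' weights incident to it): a reflection flips exactly two of a triangle's
#' edges.
#'
#' @param w a [signed_matrix()].
#' @param tau edge-retention threshold, strict (`|w| > tau`); default 0.
#' @return data frame with columns `node_i`, `node_j`, `node_q` (labels,
#'   `i < j < q` in node order), `sign` (`-1`/`+1`) and `abs_weight`.
#' @examples
#' w <- signed_matrix(matrix(c(0, .5, -.8, .5, 0, .5, -.8, .5, 0), 3, 3))
#' enumerate_triangles(w)
#' @export
enumerate_triangles <- function(w, tau = 0) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  n <- nrow(w)
  labels <- rownames(w)
  adj <- abs(unclass(w)) > tau
  empty <- data.frame(node_i = character(), node_j = character(),
                      node_q = character(), sign = integer(),
                      abs_weight = numeric(), stringsAsFactors = FALSE)
  if (n < 3) return(empty)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) == 0) return(empty)
  out_i <- vector("list", nrow(edges))
  out_q <- vector("list", nrow(edges))
  # each triangle i<j<q is found exactly once: from its edge (i,j) plus a
  # common neighbor q > j
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    common <- which(adj[, i] & adj[, j])
    common <- common[common > j]
    if (length(common)) {
      out_i[[e]] <- rep.int(e, length(common))
      out_q[[e]] <- common
    }
  }
  e_idx <- unlist(out_i)
  if (is.null(e_idx)) return(empty)
  q <- unlist(out_q)
  i <- edges[e_idx, 1]; j <- edges[e_idx, 2]
  wij <- w[cbind(i, j)]; wjq <- w[cbind(j, q)]; wqi <- w[cbind(q, i)]
  prod_w <- wij * wjq * wqi
  ord <- order(i, j, q)  # lexicographic by node index
  data.frame(node_i = labels[i][ord], node_j = labels[j][ord],
             node_q = labels[q][ord],
             sign = as.integer(sign(prod_w))[ord],
             abs_weight = abs(prod_w)[ord],
             stringsAsFactors = FALSE)
}

#' Write a triangle enumeration as TSV
#'
#' @param triangles data frame from [enumerate_triangles()].
#' @param path output path.
#' @export
write_triangles <- function(triangles, path) {
  utils::write.table(triangles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
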