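# diag(M %*% M %*% M) for a symmetric matrix, without forming the cube
diag_cube <- function(m) rowSums((m %*% m) * m)

as_adjacency <- function(a) {
  if (inherits(a, "signed_adjacency")) a else binarize(a)
}

#' Watts-Strogatz local clustering coefficient (unsigned)
#'
#' Fraction of a node's neighbor pairs that are directly connected,
#' computed on the unsigned adjacency: `C(i) = 2 t_i / (k_i (k_i - 1))`
#' where `t_i` is the number of triangles through `i` and `k_i` its degree.
#'
#' @param a a [binarize()] result (or matrix, thresholded at 0).
#' @param undefined_value value reported for nodes with degree < 2, where
#'   the coefficient is undefined; default `NA`.
#' @return named numeric vector, one value per node, in `[0, 1]`.
#' @export
clustering_ws <- function(a, undefined_value = NA_real_) {
  a <- as_adjacency(a)
  k <- rowSums(a$unsigned)
  num <- diag_cube(a$unsigned)
  finish_adjacency_index(num, k, a, undefined_value)
}

#' Signed Watts-Strogatz clustering coefficient
#'
#' As [clustering_ws()] but the numerator sums the products of the three
#' signed adjacency values around each closed triple, so triangles with a
#' negative edge-sign product (1 or 3 negative edges) count -1 and positive
#' triangles count +1.  The degree in the denominator is unsigned.  Values
#' lie in `[-1, 1]`: 0 indicates balanced positive/negative triangles or
#' disconnected neighbors.
#'
#' @inheritParams clustering_ws
#' @return named numeric vector in `[-1, 1]`.
#' @export
clustering_ws_signed <- function(a, undefined_value = NA_real_) {
  a <- as_adjacency(a)
  k <- rowSums(a$unsigned)
  num <- diag_cube(a$signed)
  finish_adjacency_index(num, k, a, undefined_value)
}

finish_adjacency_index <- function(num, k, a, undefined_value) {
  den <- k * (k - 1)
  out <- ifelse(k < 2, undefined_value, num / pmax(den, 1))
  names(out) <- rownames(a$unsigned)
  out
}

#' Onnela local clustering coefficient (unsigned)
#'
#' Sum over neighbor pairs of the triangle intensity — the geometric mean
#' of the three absolute edge weights — divided by `k_i (k_i - 1)`.  The
#' adjacency `a` determines which triples contribute and supplies the
#' unweighted degree for the denominator; for correlation networks the
#' usual choice is to treat every nonzero correlation as present
#' (`binarize(w, 0)`), which makes the denominator depend only on network
#' size.
#'
#' @param w a [signed_matrix()].
#' @param a adjacency from [binarize()]; defaults to all nonzero edges.
#' @param normalize if `TRUE`, weights are scaled by the maximum absolute
#'   weight (`w / max|w|`) before taking geometric means.  Off by default:
#'   correlations are already bounded by 1, and the scaling multiplies the
#'   index by a constant so node-wise correlations between indices are
#'   unaffected either way.
#' @param undefined_value reported when degree < 2.
#' @return named numeric vector in `[0, 1]` (when `normalize = TRUE` or
#'   all `|w| <= 1`).
#' @export
clustering_onnela <- function(w, a = binarize(w, 0), normalize = FALSE,
                              undefined_value = NA_real_) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  a <- as_adjacency(a)
  b <- onnela_weights(w, a, normalize)
  k <- rowSums(a$unsigned)
  finish_adjacency_index(diag_cube(abs(b)), k, a, undefined_value)
}

#' Signed Onnela clustering coefficient
#'
#' As [clustering_onnela()], but the intensity of each triangle enters the
#' sum with the sign of the triangle (product of its edge signs): negative
#' triangles are subtracted.  Values lie in `[-1, 1]`.
#'
#' @inheritParams clustering_onnela
#' @export
clustering_onnela_signed <- function(w, a = binarize(w, 0), normalize = FALSE,
                                     undefined_value = NA_real_) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  a <- as_adjacency(a)
  b <- onnela_weights(w, a, normalize)
  k <- rowSums(a$unsigned)
  # signed cube roots: the product of three of them is
  # sign(w1 w2 w3) * |w1 w2 w3|^(1/3)
  finish_adjacency_index(diag_cube(b), k, a, undefined_value)
}

onnela_weights <- function(w, a, normalize) {
  w <- unclass(w) * a$unsigned
  if (normalize) {
    mx <- max(abs(w))
    if (mx > 0) w <- w / mx
  }
  sign(w) * abs(w)^(1 / 3)
}

#' Zhang-Horvath local clustering coefficient (unsigned)
#'
#' Weighted generalization in which the numerator sums the products of the
#' three absolute edge weights over all neighbor pairs and the denominator
#' is its maximum attainable value,
#' `(sum_j |w_ij|)^2 - sum_j w_ij^2`.  All nonzero edges enter both
#' numerator and denominator: no thresholding.  Insensitive to the weights
#' of the edges incident to the focal node; reduces to [clustering_ws()]
#' for binary weights.
#'
#' @param w a [signed_matrix()].
#' @param undefined_value reported when a node has fewer than two incident
#'   edges (zero denominator).
#' @return named numeric vector in `[0, 1]`.
#' @export
clustering_zhang <- function(w, undefined_value = NA_real_) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  aw <- abs(unclass(w))
  finish_zhang(diag_cube(aw), aw, undefined_value, rownames(w))
}

#' Signed Zhang-Horvath clustering coefficient
#'
#' As [clustering_zhang()] but the numerator keeps the signed weights while
#' the denominator keeps absolute values, so the index responds to triangle
#' signs but not to the (arbitrary) orientation of the variables: reversing
#' a variable leaves every node's value unchanged.  Values lie in
#' `[-1, 1]`.
#'
#' @inheritParams clustering_zhang
#' @export
clustering_zhang_signed <- function(w, undefined_value = NA_real_) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  wm <- unclass(w)
  finish_zhang(diag_cube(wm), abs(wm), undefined_value, rownames(w))
}

zhang_denominator <- function(aw) rowSums(aw)^2 - rowSums(aw^2)

finish_zhang <- function(num, aw, undefined_value, labels) {
  den <- zhang_denominator(aw)
  out <- ifelse(den == 0, undefined_value, num / ifelse(den == 0, 1, den))
  names(out) <- labels
  out
}

#' Global signed clustering coefficient
#'
#' Network-level signed clustering ratio: the sum over nodes of the signed
#' Zhang numerators, divided by the sum of the Zhang denominators plus the
#' sum of all squared weights.  Lies in `[-1, 1]`; zero for a network
#' without triangles, positive when positive triangle mass dominates.
#'
#' @param w a [signed_matrix()].
#' @param undefined_value returned for an empty network.
#' @return scalar.
#' @examples
#' w3 <- signed_matrix(matrix(1, 3, 3) - diag(3))
#' global_signed(w3)  # 0.5 for a single unit-weight triangle
#' @export
global_signed <- function(w, undefined_value = NA_real_) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  wm <- unclass(w)
  if (all(wm == 0)) return(undefined_value)
  num <- sum(diag_cube(wm))
  den <- sum(zhang_denominator(abs(wm))) + sum(wm^2)
  num / den
}

#' All six clustering indices plus the global coefficient
#'
#' Convenience wrapper computing, for each node, the unsigned and signed
#' Watts-Strogatz, Onnela and Zhang-Horvath coefficients, plus the global
#' signed coefficient of the network.  The unweighted indices use the
#' adjacency thresholded at `tau`; the Onnela denominators use the
#' adjacency thresholded at `onnela_tau` (default 0: all nonzero edges
#' count toward the degree); the Zhang indices always use all edges.
#'
#' @param w a [signed_matrix()].
#' @param tau threshold for the unweighted (adjacency-based) indices;
#'   default 0.1, a common choice for correlation networks.
#' @param onnela_tau threshold for the adjacency underlying the Onnela
#'   indices; default 0.
#' @param normalize passed to the Onnela indices.
#' @param undefined_value reported where an index is undefined.
#' @return data frame of class `"clustering_result"` with columns `node`,
#'   `c_ws`, `c_on`, `c_zh`, `c_ws_s`, `c_on_s`, `c_zh_s`; the global
#'   coefficient and the parameters are attached as attributes
#'   `global_signed`, `tau`, `onnela_tau`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 50, 6)
#' w <- correlation_network(x)
#' clustering_table(w)
#' @export
clustering_table <- function(w, tau = 0.1, onnela_tau = 0, normalize = FALSE,
                             undefined_value = NA_real_) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  a_thr <- binarize(w, tau)
  a_on <- if (onnela_tau == tau) a_thr else binarize(w, onnela_tau)
  res <- data.frame(
    node = rownames(w),
    c_ws = clustering_ws(a_thr, undefined_value),
    c_on = clustering_onnela(w, a_on, normalize, undefined_value),
    c_zh = clustering_zhang(w, undefined_value),
    c_ws_s = clustering_ws_signed(a_thr, undefined_value),
    c_on_s = clustering_onnela_signed(w, a_on, normalize, undefined_value),
    c_zh_s = clustering_zhang_signed(w, undefined_value),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("clustering_result", "data.frame"),
            global_signed = global_signed(w, undefined_value),
            tau = tau, onnela_tau = onnela_tau)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Clustering coefficients for %d nodes (tau = %g, onnela_tau = %g)\n",
              nrow(x), attr(x, "tau"), attr(x, "onnela_tau")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4, ...)
  if (nrow(x) > 10) cat(sprintf("... %d more nodes\n", nrow(x) - 10))
  cat(sprintf("Global signed clustering coefficient: %.4f\n",
              attr(x, "global_signed")))
  invisible(x)
}
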