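#' Item-response table
#'
#' An observations-by-items score table on a bounded Likert-type scale,
#' carrying the scale bounds and the set of reverse-keyed items.
#'
#' @param scores data frame or matrix of numeric scores.
#' @param scale_min,scale_max scale bounds (default 1 and 5).
#' @param reverse_keyed character vector of reverse-keyed item names (or
#'   integer indices).
#' @return data frame of class `"item_table"` with attributes `scale_min`,
#'   `scale_max`, `reverse_keyed`.
#' @export
item_table <- function(scores, scale_min = 1, scale_max = 5,
                       reverse_keyed = character()) {
  scores <- as.data.frame(scores)
  if (is.null(names(scores)) || any(names(scores) == "")) {
    names(scores) <- paste0("item", seq_along(scores))
  }
  stopifnot(scale_min < scale_max)
  vals <- as.matrix(scores)
  if (any(!is.finite(vals))) stop("non-finite item scores")
  if (any(vals < scale_min | vals > scale_max)) {
    bad <- which(vals < scale_min | vals > scale_max, arr.ind = TRUE)[1, ]
    stop(sprintf("score out of range [%g, %g] at row %d, item %s",
                 scale_min, scale_max, bad[1], names(scores)[bad[2]]))
  }
  if (is.numeric(reverse_keyed)) reverse_keyed <- names(scores)[reverse_keyed]
  missing_items <- setdiff(reverse_keyed, names(scores))
  if (length(missing_items)) {
    stop("reverse-keyed items not in table: ",
         paste(missing_items, collapse = ", "))
  }
  structure(scores, class = c("item_table", "data.frame"),
            scale_min = scale_min, scale_max = scale_max,
            reverse_keyed = reverse_keyed)
}

#' Reverse-score the reverse-keyed items
#'
#' Replaces each reverse-keyed item's score `x` by
#' `(scale_min + scale_max) - x` (e.g. subtraction from 6 on a 1-5 scale),
#' so that every item indexes the positive pole of its trait.  Applying
#' the function twice restores the original table.
#'
#' @param table an [item_table()].
#' @return the transformed [item_table()] (same reverse-keyed set).
#' @export
reverse_score <- function(table) {
  stopifnot(inherits(table, "item_table"))
  rev_items <- attr(table, "reverse_keyed")
  tot <- attr(table, "scale_min") + attr(table, "scale_max")
  for (it in rev_items) table[[it]] <- tot - table[[it]]
  table
}

#' Edge and triangle census of a signed network
#'
#' Counts positive and negative edges and triangles, summarizes the
#' triangle weights (product of the three edge weights, in absolute value)
#' by triangle sign, and compares the two weight distributions with a
#' pooled-variance (Student) two-sample t-test, whose degrees of freedom
#' are `n_pos_triangles + n_neg_triangles - 2`.
#'
#' @param w a [signed_matrix()].
#' @param tau edge-retention threshold (strict `|w| > tau`); default 0,
#'   i.e. the full correlation matrix.
#' @return list of class `"census_summary"` with elements `n_pos_edges`,
#'   `n_neg_edges`, `n_pos_triangles`, `n_neg_triangles`,
#'   `mean_weight_pos`, `sd_weight_pos`, `mean_weight_neg`,
#'   `sd_weight_neg`, `t_statistic`, `df`, `p_value` and the `triangles`
#'   data frame.
#' @export
census <- function(w, tau = 0) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  ut <- w[upper.tri(w)]
  present <- abs(ut) > tau
  tri <- enumerate_triangles(w, tau)
  wp <- tri$abs_weight[tri$sign > 0]
  wn <- tri$abs_weight[tri$sign < 0]
  res <- list(
    n_pos_edges = sum(ut > tau), n_neg_edges = sum(ut < -tau),
    n_pos_triangles = length(wp), n_neg_triangles = length(wn),
    mean_weight_pos = if (length(wp)) mean(wp) else NA_real_,
    sd_weight_pos = if (length(wp) > 1) stats::sd(wp) else NA_real_,
    mean_weight_neg = if (length(wn)) mean(wn) else NA_real_,
    sd_weight_neg = if (length(wn) > 1) stats::sd(wn) else NA_real_,
    t_statistic = NA_real_, df = length(wp) + length(wn) - 2L,
    p_value = NA_real_, tau = tau, triangles = tri)
  if (length(wp) >= 2 && length(wn) >= 2) {
    tt <- stats::t.test(wp, wn, var.equal = TRUE)
    res$t_statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p_value <- tt$p.value
  } else {
    message("fewer than 2 triangles in a sign class; t-test skipped")
  }
  structure(res, class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf("Edges: %d positive, %d negative (tau = %g)\n",
              x$n_pos_edges, x$n_neg_edges, x$tau))
  cat(sprintf("Triangles: %d positive (mean |w| = %.4g), %d negative (mean |w| = %.4g)\n",
              x$n_pos_triangles, x$mean_weight_pos,
              x$n_neg_triangles, x$mean_weight_neg))
  if (!is.na(x$t_statistic)) {
    cat(sprintf("Pooled t-test, positive vs negative weight: t(%d) = %.2f, p = %.3g\n",
                x$df, x$t_statistic, x$p_value))
  }
  invisible(x)
}

#' Agreement between the four weighted clustering indices
#'
#' Correlations across nodes between the unsigned and signed Onnela and
#' Zhang index vectors: Pearson correlations below the diagonal,
#' Spearman rank correlations (average ranks for ties) above, ones on the
#' diagonal.  Nodes with undefined values are excluded pairwise.
#'
#' @param w a [signed_matrix()].
#' @param onnela_tau threshold for the Onnela adjacency (default 0: all
#'   nonzero edges).
#' @param normalize passed to the Onnela indices.
#' @return 4x4 matrix with dimnames `c_on`, `c_zh`, `c_on_s`, `c_zh_s`.
#' @export
index_agreement <- function(w, onnela_tau = 0, normalize = FALSE) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  if (nrow(w) < 3) stop("need at least 3 nodes")
  a_on <- binarize(w, onnela_tau)
  vec <- cbind(c_on = clustering_onnela(w, a_on, normalize),
               c_zh = clustering_zhang(w),
               c_on_s = clustering_onnela_signed(w, a_on, normalize),
               c_zh_s = clustering_zhang_signed(w))
  pear <- suppressWarnings(
    stats::cor(vec, use = "pairwise.complete.obs", method = "pearson"))
  spear <- suppressWarnings(
    stats::cor(vec, use = "pairwise.complete.obs", method = "spearman"))
  out <- pear
  out[upper.tri(out)] <- spear[upper.tri(spear)]
  diag(out) <- 1
  if (any(is.na(out))) message("zero-variance index vector: NA entries")
  out
}

#' Threshold sweep of unweighted-index agreement
#'
#' For each dichotomization threshold on the grid, computes the unweighted
#' clustering coefficients (unsigned and signed) on the binarized network
#' and correlates each, across nodes (Pearson), with the four weighted
#' index vectors.  Thresholds that leave any node with fewer than two
#' neighbors — where the unweighted coefficient is undefined — are skipped
#' and reported.
#'
#' @param w a [signed_matrix()].
#' @param tau_min,tau_max,step sweep grid (defaults 0.01 to 0.17 by 0.01).
#' @param onnela_tau,normalize Onnela conventions, as [index_agreement()].
#' @return data frame with one row per admissible threshold: column `tau`
#'   plus eight correlation columns named
#'   `<unweighted>_vs_<weighted>`; skipped thresholds are in
#'   `attr(, "skipped_taus")`.
#' @export
threshold_sweep <- function(w, tau_min = 0.01, tau_max = 0.17, step = 0.01,
                            onnela_tau = 0, normalize = FALSE) {
  if (!inherits(w, "signed_matrix")) w <- signed_matrix(w)
  stopifnot(tau_min >= 0, tau_max >= tau_min, step > 0)
  taus <- seq(tau_min, tau_max, by = step)
  a_on <- binarize(w, onnela_tau)
  weighted <- cbind(c_on = clustering_onnela(w, a_on, normalize),
                    c_zh = clustering_zhang(w),
                    c_on_s = clustering_onnela_signed(w, a_on, normalize),
                    c_zh_s = clustering_zhang_signed(w))
  rows <- list()
  skipped <- numeric()
  for (tau in taus) {
    a <- binarize(w, tau)
    if (any(rowSums(a$unsigned) < 2)) {
      skipped <- c(skipped, tau)
      next
    }
    unweighted <- cbind(c_ws = clustering_ws(a),
                        c_ws_s = clustering_ws_signed(a))
    cm <- suppressWarnings(
      stats::cor(unweighted, weighted, use = "pairwise.complete.obs"))
    row <- as.data.frame(as.list(c(tau = tau, t(cm))))
    names(row)[-1] <- paste(rep(rownames(cm), each = ncol(cm)),
                            rep(colnames(cm), nrow(cm)), sep = "_vs_")
    rows[[length(rows) + 1]] <- row
  }
  if (length(skipped)) {
    message("skipped thresholds leaving a node with degree < 2: ",
            paste(format(skipped), collapse = ", "))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tau = numeric())
  attr(out, "skipped_taus") <- skipped
  out
}

#' Factor-model specification for synthetic questionnaire data
#'
#' Describes a simple-structure linear factor model emulating a
#' multi-factor personality questionnaire: each item loads strongly on its
#' own factor, weakly (at random) on the others, and a fraction of items
#' are negatively keyed.  Defaults emulate a 60-item, 6-factor inventory
#' answered by 355 respondents on a 1-5 scale with 29 reverse-keyed items.
#'
#' @param n_factors number of factors (default 6).
#' @param items_per_factor items per factor (default 10).
#' @param primary_loading loading of each item on its own factor
#'   (default 0.6).
#' @param secondary_loading_sd SD of the random loadings on the other
#'   factors (default 0.05).
#' @param proportion_reversed fraction of items negatively keyed
#'   (default 29/60).
#' @param n_obs respondents (default 355).
#' @param scale_min,scale_max response scale (default 1-5).
#' @return list of class `"factor_model_spec"`.
#' @export
factor_model_spec <- function(n_factors = 6, items_per_factor = 10,
                              primary_loading = 0.6,
                              secondary_loading_sd = 0.05,
                              proportion_reversed = 29 / 60,
                              n_obs = 355, scale_min = 1, scale_max = 5) {
  stopifnot(n_factors >= 1, items_per_factor >= 2,
            abs(primary_loading) < 1, secondary_loading_sd >= 0,
            proportion_reversed >= 0, proportion_reversed <= 1, n_obs >= 10)
  structure(list(n_factors = n_factors, items_per_factor = items_per_factor,
                 primary_loading = primary_loading,
                 secondary_loading_sd = secondary_loading_sd,
                 proportion_reversed = proportion_reversed,
                 n_obs = n_obs, scale_min = scale_min,
                 scale_max = scale_max),
            class = "factor_model_spec")
}

#' Generate synthetic questionnaire responses from a factor model
#'
#' Draws standard-normal factor scores, builds each item as its loading
#' combination plus a unique error scaled so the latent item variance is
#' one, negates the latent scores of reverse-keyed items, and discretizes
#' to the response scale through equal-probability thresholds on the
#' latent normal scale.  Items are labeled `F<f>I<i>`; reverse-keyed items
#' are spread evenly across factors.
#'
#' @param spec a [factor_model_spec()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return an [item_table()] with the reverse-keyed set attached.
#' @export
generate_factor_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "factor_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_items <- spec$n_factors * spec$items_per_factor
  lambda <- matrix(stats::rnorm(n_items * spec$n_factors,
                                sd = spec$secondary_loading_sd),
                   n_items, spec$n_factors)
  own <- rep(seq_len(spec$n_factors), each = spec$items_per_factor)
  lambda[cbind(seq_len(n_items), own)] <- spec$primary_loading
  uniq_var <- 1 - rowSums(lambda^2)
  if (any(uniq_var <= 0)) {
    stop("implied item variance exceeds 1; loadings too large (non-PSD)")
  }
  n_rev <- round(spec$proportion_reversed * n_items)
  # spread reverse-keyed items across factors: every other item, wrapping
  rev_idx <- (seq_len(n_rev) * 2 - 1) %% n_items + 1
  rev_idx <- unique(rev_idx)
  extra <- setdiff(seq_len(n_items), rev_idx)
  rev_idx <- sort(c(rev_idx, extra[seq_len(n_rev - length(rev_idx))]))
  keying <- rep(1, n_items)
  keying[rev_idx] <- -1
  f <- matrix(stats::rnorm(spec$n_obs * spec$n_factors),
              spec$n_obs, spec$n_factors)
  e <- matrix(stats::rnorm(spec$n_obs * n_items), spec$n_obs, n_items)
  latent <- sweep(f %*% t(lambda) + sweep(e, 2, sqrt(uniq_var), "*"),
                  2, keying, "*")
  n_levels <- spec$scale_max - spec$scale_min + 1
  breaks <- c(-Inf, stats::qnorm(seq_len(n_levels - 1) / n_levels), Inf)
  scores <- matrix(findInterval(latent, breaks), spec$n_obs, n_items) +
    spec$scale_min - 1
  colnames(scores) <- paste0("F", own, "I",
                             stats::ave(own, own, FUN = seq_along))
  item_table(scores, spec$scale_min, spec$scale_max,
             reverse_keyed = colnames(scores)[rev_idx])
}
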