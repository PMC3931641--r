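# Brute-force oracles: explicit loops over ordered neighbor pairs (j, q),
# written independently of the package's matrix-algebra implementation.

rand_signed <- function(n, density = 0.7, allow_zero_rows = TRUE) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < density) {
        w[i, j] <- w[j, i] <- stats::runif(1, -1, 1)
      }
    }
  }
  if (allow_zero_rows && n > 3 && stats::runif(1) < 0.3) {
    z <- sample(n, 1)
    w[z, ] <- w[, z] <- 0
  }
  signed_matrix(w)
}

oracle_ws <- function(a_unsigned, a_signed = a_unsigned) {
  n <- nrow(a_unsigned)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a_unsigned[i, ])
    if (k < 2) { out[i] <- NA_real_; next }
    s <- 0
    for (j in seq_len(n)) for (q in seq_len(n)) {
      if (j != q && j != i && q != i) {
        s <- s + a_signed[i, j] * a_signed[j, q] * a_signed[q, i]
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_onnela <- function(w, a_unsigned, signed) {
  n <- nrow(w)
  out <- numeric(n)
  wm <- unclass(w) * a_unsigned
  for (i in seq_len(n)) {
    k <- sum(a_unsigned[i, ])
    if (k < 2) { out[i] <- NA_real_; next }
    s <- 0
    for (j in seq_len(n)) for (q in seq_len(n)) {
      if (j != q && j != i && q != i) {
        prod3 <- wm[i, j] * wm[j, q] * wm[q, i]
        term <- abs(prod3)^(1 / 3)
        if (signed) term <- term * sign(prod3)
        s <- s + term
      }
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

oracle_zhang <- function(w, signed) {
  n <- nrow(w)
  out <- numeric(n)
  wm <- unclass(w)
  for (i in seq_len(n)) {
    den <- sum(abs(wm[i, ]))^2 - sum(wm[i, ]^2)
    if (den == 0) { out[i] <- NA_real_; next }
    s <- 0
    for (j in seq_len(n)) for (q in seq_len(n)) {
      if (j != q && j != i && q != i) {
        s <- s + if (signed) wm[i, j] * wm[j, q] * wm[q, i] else
          abs(wm[i, j]) * abs(wm[j, q]) * abs(wm[q, i])
      }
    }
    out[i] <- s / den
  }
  out
}

oracle_global <- function(w) {
  n <- nrow(w)
  wm <- unclass(w)
  num <- den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) for (q in seq_len(n)) {
      if (j != q && j != i && q != i) num <- num + wm[i, j] * wm[j, q] * wm[q, i]
    }
    den <- den + sum(abs(wm[i, ]))^2 - sum(wm[i, ]^2)
  }
  num / (den + sum(wm^2))
}

oracle_triangles <- function(w, tau = 0) {
  n <- nrow(w)
  out <- NULL
  if (n >= 3) {
    for (trip in utils::combn(n, 3, simplify = FALSE)) {
      i <- trip[1]; j <- trip[2]; q <- trip[3]
      if (abs(w[i, j]) > tau && abs(w[j, q]) > tau && abs(w[q, i]) > tau) {
        pw <- w[i, j] * w[j, q] * w[q, i]
        out <- rbind(out, data.frame(i = i, j = j, q = q,
                                     sign = sign(pw), abs_weight = abs(pw)))
      }
    }
  }
  out
}

# negate all weights incident to the nodes in s (one endpoint in s)
reflect_nodes <- function(w, s) {
  m <- unclass(w)
  for (i in s) {
    m[i, ] <- -m[i, ]
    m[, i] <- -m[, i]
  }
  signed_matrix(m)
}

all_indices <- function(w, tau = 0.1, onnela_tau = 0) {
  a_thr <- binarize(w, tau)
  a_on <- binarize(w, onnela_tau)
  list(c_ws = clustering_ws(a_thr),
       c_on = clustering_onnela(w, a_on),
       c_zh = clustering_zhang(w),
       c_ws_s = clustering_ws_signed(a_thr),
       c_on_s = clustering_onnela_signed(w, a_on),
       c_zh_s = clustering_zhang_signed(w))
}
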