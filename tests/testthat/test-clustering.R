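test_that("unweighted indices reproduce hand-computed configurations", {
  tri <- signed_matrix(matrix(1, 3, 3) - diag(3))
  expect_equal(clustering_ws(binarize(tri)), rep(1, 3), ignore_attr = TRUE)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- .5
  a <- binarize(signed_matrix(star))
  expect_equal(clustering_ws(a)[1], 0, ignore_attr = TRUE)
  expect_true(all(is.na(clustering_ws(a)[2:4])))  # leaves: degree 1
  expect_equal(unname(clustering_ws(a, undefined_value = 0)[2]), 0)

  # focal node with 3 neighbors, 2 of the 3 neighbor pairs connected: 2/3
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- w[2:4, 1] <- .5
  w[2, 3] <- w[3, 2] <- .5
  w[3, 4] <- w[4, 3] <- .5
  expect_equal(unname(clustering_ws(binarize(signed_matrix(w)))[1]), 2 / 3)

  # one negative edge: the triangle is negative for every node
  ntri <- signed_matrix(matrix(c(0, 1, -1, 1, 0, 1, -1, 1, 0), 3, 3))
  expect_equal(clustering_ws_signed(binarize(ntri)), rep(-1, 3),
               ignore_attr = TRUE)
  expect_equal(clustering_ws(binarize(ntri)), rep(1, 3), ignore_attr = TRUE)

  # one positive and one negative triangle, third neighbor pair absent: 0
  wb <- matrix(0, 4, 4)
  wb[1, 2:4] <- wb[2:4, 1] <- .5
  wb[2, 3] <- wb[3, 2] <- .5    # positive triangle (1,2,3)
  wb[3, 4] <- wb[4, 3] <- -.5   # negative triangle (1,3,4)
  expect_equal(unname(clustering_ws_signed(binarize(signed_matrix(wb)))[1]), 0)
})

test_that("Onnela indices equal the geometric-mean formula", {
  w <- signed_matrix(matrix(c(0, .5, .8, .5, 0, .5, .8, .5, 0), 3, 3))
  expect_equal(unname(clustering_onnela(w)[2]), (0.5 * 0.5 * 0.8)^(1 / 3))
  wn <- signed_matrix(matrix(c(0, .5, -.8, .5, 0, .5, -.8, .5, 0), 3, 3))
  expect_equal(unname(clustering_onnela_signed(wn)[2]), -(0.2)^(1 / 3))
  # all |w| equal to the max and normalization on: geometric mean of ones
  expect_equal(clustering_onnela(signed_matrix(
    0.4 * (matrix(1, 3, 3) - diag(3))), normalize = TRUE), rep(1, 3),
    ignore_attr = TRUE)
  # all-positive network: signed equals unsigned
  expect_equal(clustering_onnela_signed(w), clustering_onnela(w))
})

test_that("Zhang indices match hand evaluation and reduce correctly", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- .5
  w[1, 3] <- w[3, 1] <- .5
  w[2, 3] <- w[3, 2] <- .8
  w <- signed_matrix(w)
  expect_equal(unname(clustering_zhang(w)[1]), 0.4 / 0.5)  # = 0.8
  wn <- w
  wn[2, 3] <- wn[3, 2] <- -.8
  expect_equal(unname(clustering_zhang_signed(wn)[1]), -0.8)
  expect_equal(clustering_zhang_signed(w), clustering_zhang(w))
  # disconnected neighbors: 0; single edge: undefined
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- .5
  path[1, 3] <- path[3, 1] <- .4
  pw <- signed_matrix(path)
  expect_equal(unname(clustering_zhang(pw)[1]), 0)
  expect_true(is.na(clustering_zhang(pw)[2]))
})

test_that("global signed coefficient composes the Zhang terms", {
  tri <- signed_matrix(matrix(1, 3, 3) - diag(3))
  expect_equal(global_signed(tri), 0.5)  # 6 / (6 + 6)
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- .5
  path[2, 3] <- path[3, 2] <- .5
  expect_equal(global_signed(signed_matrix(path)), 0)
  expect_true(is.na(global_signed(signed_matrix(matrix(0, 3, 3)))))
  set.seed(3)
  for (rep in 1:10) {
    w <- rand_signed(6)
    expect_equal(global_signed(w), oracle_global(w), tolerance = 1e-12)
    # reflection of one node leaves the global value unchanged
    expect_equal(global_signed(reflect_nodes(w, sample(6, 1))),
                 global_signed(w), tolerance = 1e-12)
  }
})

test_that("all six indices match the brute-force neighbor-pair oracle", {
  set.seed(100)
  for (rep in 1:60) {
    n <- sample(4:8, 1)
    w <- rand_signed(n, density = stats::runif(1, 0.3, 1))
    a <- binarize(w, 0)
    expect_equal(unname(clustering_ws(a)), oracle_ws(a$unsigned),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_ws_signed(a)),
                 oracle_ws(a$unsigned, a$signed), tolerance = 1e-12)
    expect_equal(unname(clustering_onnela(w, a)),
                 oracle_onnela(w, a$unsigned, signed = FALSE),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_onnela_signed(w, a)),
                 oracle_onnela(w, a$unsigned, signed = TRUE),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_zhang(w)),
                 oracle_zhang(w, signed = FALSE), tolerance = 1e-12)
    expect_equal(unname(clustering_zhang_signed(w)),
                 oracle_zhang(w, signed = TRUE), tolerance = 1e-12)
  }
})

test_that("binary weights collapse the three index families", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    w <- signed_matrix((rand_signed(n, density = 0.6) != 0) * 1)
    idx <- all_indices(w, tau = 0, onnela_tau = 0)
    expect_identical(idx$c_ws, idx$c_on)
    expect_identical(idx$c_ws, idx$c_zh)
    expect_identical(idx$c_ws_s, idx$c_on_s)
    expect_identical(idx$c_ws_s, idx$c_zh_s)
  }
})

test_that("signed equals unsigned on nonnegative networks", {
  set.seed(9)
  for (rep in 1:10) {
    w <- rand_signed(7)
    w <- signed_matrix(abs(unclass(w)))
    idx <- all_indices(w, tau = 0.2, onnela_tau = 0)
    expect_equal(idx$c_ws, idx$c_ws_s)
    expect_equal(idx$c_on, idx$c_on_s)
    expect_equal(idx$c_zh, idx$c_zh_s)
  }
})

test_that("signed indices are invariant under reflection of a node set", {
  set.seed(10)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    w <- rand_signed(n)
    s <- sample(n, sample(1:3, 1))
    wr <- reflect_nodes(w, s)
    i1 <- all_indices(w, tau = 0.2)
    i2 <- all_indices(wr, tau = 0.2)
    for (nm in names(i1)) expect_equal(i1[[nm]], i2[[nm]], tolerance = 1e-12)
  }
})

test_that("index bounds hold on random valid inputs", {
  set.seed(12)
  for (rep in 1:20) {
    idx <- all_indices(rand_signed(sample(4:8, 1)), tau = 0.1)
    for (nm in c("c_ws", "c_on", "c_zh")) {
      v <- idx[[nm]][!is.na(idx[[nm]])]
      expect_true(all(v >= 0 & v <= 1 + 1e-12))
    }
    for (nm in c("c_ws_s", "c_on_s", "c_zh_s")) {
      v <- idx[[nm]][!is.na(idx[[nm]])]
      expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
    }
  }
})

test_that("Zhang is insensitive to weights of edges incident to the focal node", {
  set.seed(13)
  for (rep in 1:10) {
    w <- rand_signed(7, density = 1, allow_zero_rows = FALSE)
    i <- sample(7, 1)
    cscale <- stats::runif(1, 0.1, 1)
    ws <- unclass(w)
    ws[i, ] <- ws[i, ] * cscale
    ws[, i] <- ws[, i] * cscale
    ws <- signed_matrix(ws)
    expect_equal(clustering_zhang(ws)[i], clustering_zhang(w)[i],
                 tolerance = 1e-12)
    expect_equal(clustering_zhang_signed(ws)[i], clustering_zhang_signed(w)[i],
                 tolerance = 1e-12)
  }
})

test_that("Onnela max-weight normalization is a constant rescaling", {
  set.seed(14)
  w <- rand_signed(8, density = 0.8)
  plain <- clustering_onnela_signed(w)
  normed <- clustering_onnela_signed(w, normalize = TRUE)
  ratio <- normed / plain
  ratio <- ratio[is.finite(ratio) & abs(plain) > 1e-9]
  expect_equal(stats::sd(ratio), 0, tolerance = 1e-10)
  expect_equal(stats::cor(plain, normed, use = "complete.obs"), 1,
               tolerance = 1e-10)
})

test_that("clustering_table assembles all indices and the global value", {
  set.seed(15)
  w <- rand_signed(8)
  tab <- clustering_table(w, tau = 0.1)
  expect_named(tab, c("node", "c_ws", "c_on", "c_zh",
                      "c_ws_s", "c_on_s", "c_zh_s"))
  expect_equal(tab$c_zh_s, unname(clustering_zhang_signed(w)))
  expect_equal(attr(tab, "global_signed"), global_signed(w))
  expect_equal(tab$c_ws, unname(clustering_ws(binarize(w, 0.1))))
})
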