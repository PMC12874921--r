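# Relation networks: cosine similarity, top-k sparsification, 2-hop subgraph
# extraction (vs a BFS oracle), and the GATv2 layer semantics.

make_emb <- function(m, ids = sprintf("e%02d", seq_len(nrow(m)))) {
  embedding_matrix(ids, m, "sequence")
}

test_that("cosine similarity network matches a dot-product loop oracle", {
  expect_equal(
    cosine_similarity_network(make_emb(rbind(c(1, 2), c(1, 2))))$edges$weight,
    1.0, tolerance = 1e-12)
  expect_equal(
    cosine_similarity_network(make_emb(rbind(c(1, 0), c(0, 1))))$edges$weight,
    0.0, tolerance = 1e-12)

  set.seed(8)
  X <- matrix(rnorm(8 * 5), 8L, 5L)
  net <- cosine_similarity_network(make_emb(X))
  expect_equal(nrow(net$edges), 28L)
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$i[r]; j <- net$edges$j[r]
    want <- sum(X[i, ] * X[j, ]) /
      (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
    expect_equal(net$edges$weight[r], want, tolerance = 1e-9)
  }
  Xz <- X; Xz[3L, ] <- 0
  expect_error(cosine_similarity_network(make_emb(Xz)), "e03")
})

test_that("top-k sparsification keeps per-node top edges with union semantics", {
  # 3 nodes: w_AB = 0.9, w_AC = 0.5, w_BC = 0.1; k = 1 keeps {AB, AC}
  net <- relational_network(c("A", "B", "C"),
                            data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                       weight = c(0.9, 0.5, 0.1)),
                            diag(3))
  sp <- topk_sparsify(net, 1L)
  expect_equal(nrow(sp$edges), 2L)
  expect_setequal(paste(sp$edges$i, sp$edges$j), c("1 2", "1 3"))

  # k >= n-1 keeps everything
  full <- cosine_similarity_network(make_emb(matrix(rnorm(20), 5L)))
  expect_equal(topk_sparsify(full, 4L)$edges, full$edges)

  # monotone: edges at k form a subset of edges at k+1
  set.seed(13)
  net2 <- cosine_similarity_network(make_emb(matrix(rnorm(60), 10L)))
  for (k in 1:4) {
    a <- topk_sparsify(net2, k)$edges
    b <- topk_sparsify(net2, k + 1L)$edges
    expect_true(all(paste(a$i, a$j) %in% paste(b$i, b$j)))
  }
})

test_that("2-hop subgraphs equal a textbook BFS oracle", {
  # path A-B-C-D-E
  path <- relational_network(LETTERS[1:5],
                             data.frame(i = 1:4, j = 2:5, weight = 1),
                             diag(5))
  expect_equal(extract_2hop_subgraph(path, 3L)$members, 1:5)
  expect_equal(extract_2hop_subgraph(path, 1L)$members, 1:3)

  bfs2 <- function(edges, n, center) {
    adj <- lapply(seq_len(n), function(v) {
      c(edges$j[edges$i == v], edges$i[edges$j == v])
    })
    depth <- rep(Inf, n); depth[center] <- 0
    frontier <- center
    for (d in 1:2) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[depth[nxt] == Inf]
      depth[nxt] <- d
      frontier <- nxt
    }
    sort(which(is.finite(depth)))
  }

  set.seed(17)
  for (trial in 1:30) {
    n <- sample(5:12, 1L)
    emb <- make_emb(matrix(rnorm(n * 6L), n))
    net <- topk_sparsify(cosine_similarity_network(emb), 2L)
    center <- sample(n, 1L)
    sg <- extract_2hop_subgraph(net, center, cap = 1000L)
    expect_equal(sg$members, bfs2(net$edges, n, center))
    # induced edges stay within members and reference local indices
    expect_true(all(sg$induced_edges$i <= length(sg$members)))
    expect_true(all(sg$induced_edges$j <= length(sg$members)))
  }
})

test_that("subgraph cap keeps the center and highest-weight neighbors", {
  # star with weighted spokes; cap 3 keeps center + 2 strongest
  n <- 6L
  net <- relational_network(
    sprintf("n%d", 1:n),
    data.frame(i = rep(1L, 5L), j = 2:6, weight = c(0.9, 0.5, 0.7, 0.3, 0.8)),
    diag(n))
  sg <- extract_2hop_subgraph(net, 1L, cap = 3L)
  expect_true(1L %in% sg$members)
  expect_setequal(sg$members, c(1L, 2L, 6L))  # weights 0.9 and 0.8
})

test_that("GATv2 attention normalizes and matches a dense softmax oracle", {
  set.seed(23)
  d_in <- 5L; d_out <- 4L
  params <- gatv2_params(d_in, d_out)[[1L]]
  n <- 5L
  H <- matrix(rnorm(n * d_in), n, d_in)
  edges <- data.frame(i = c(1, 1, 2, 3, 4), j = c(2, 3, 4, 5, 5))
  res <- gatv2_layer(H, edges, params, return_attention = TRUE)
  att <- res$attention
  sums <- tapply(att$alpha, att$src, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # dense loop oracle
  Hl <- H %*% params$Wl; Hr <- H %*% params$Wr
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  eluf <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  nbrs <- lapply(1:n, function(v) {
    c(edges$j[edges$i == v], edges$i[edges$j == v])
  })
  want <- matrix(0, n, d_out)
  for (i in 1:n) {
    js <- nbrs[[i]]
    if (length(js) == 0L) js <- i
    logits <- vapply(js, function(j) {
      sum(params$a * lrelu(Hl[i, ] + Hr[j, ]))
    }, 1)
    alpha <- exp(logits - max(logits))
    alpha <- alpha / sum(alpha)
    acc <- rep(0, d_out)
    for (q in seq_along(js)) acc <- acc + alpha[q] * Hr[js[q], ]
    want[i, ] <- eluf(acc)
  }
  expect_equal(res$states, want, tolerance = 1e-9)
})

test_that("GATv2 degenerate cases: single neighbor and zero attention vector", {
  set.seed(31)
  params <- gatv2_params(3L, 3L)[[1L]]
  H <- matrix(rnorm(6L), 2L, 3L)
  res <- gatv2_layer(H, data.frame(i = 1L, j = 2L), params,
                     return_attention = TRUE)
  expect_true(all(abs(res$attention$alpha - 1) < 1e-12))
  eluf <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  expect_equal(res$states[1L, ],
               as.numeric(eluf(H[2L, , drop = FALSE] %*% params$Wr)),
               tolerance = 1e-10)

  params0 <- params
  params0$a[] <- 0
  H3 <- matrix(rnorm(9L), 3L, 3L)
  res0 <- gatv2_layer(H3, data.frame(i = c(1L, 1L), j = c(2L, 3L)), params0,
                      return_attention = TRUE)
  a1 <- res0$attention$alpha[res0$attention$src == 1L]
  expect_equal(a1, rep(1 / 2, 2L), tolerance = 1e-12)
})

test_that("relation encoding is order-free and clones embed identically", {
  set.seed(41)
  emb <- make_emb(matrix(rnorm(10 * 6L), 10L))
  net <- topk_sparsify(cosine_similarity_network(emb), 2L)
  params <- gatv2_params(6L, 4L)
  sg <- extract_2hop_subgraph(net, 1L)
  v <- encode_relation(sg, net$node_features, params)
  expect_length(v, 4L)

  # singleton subgraph: self-loop, mean of one transform
  iso <- relational_network(c("a", "b"),
                            data.frame(i = integer(0), j = integer(0),
                                       weight = numeric(0))[0, ],
                            matrix(rnorm(12L), 2L, 6L))
  sg1 <- extract_2hop_subgraph(iso, 1L)
  v1 <- encode_relation(sg1, iso$node_features, params)
  expect_length(v1, 4L)
  expect_all_finite(v1)

  # disconnected clone of the subgraph around a cloned center
  m <- length(sg$members)
  feats <- net$node_features[sg$members, , drop = FALSE]
  both <- rbind(feats, feats)
  e1 <- sg$induced_edges
  e2 <- data.frame(i = e1$i + m, j = e1$j + m, weight = e1$weight)
  netc <- relational_network(sprintf("c%02d", 1:(2 * m)), rbind(e1, e2), both)
  c1 <- extract_2hop_subgraph(netc, sg$center_local)
  c2 <- extract_2hop_subgraph(netc, sg$center_local + m)
  expect_equal(encode_relation(c1, netc$node_features, params),
               encode_relation(c2, netc$node_features, params),
               tolerance = 1e-10)
})

test_that("networks serialize to an edge-list TSV plus ids file and back", {
  set.seed(2)
  emb <- make_emb(matrix(rnorm(6 * 4), 6L))
  net <- topk_sparsify(cosine_similarity_network(emb), 2L)
  ef <- tempfile(fileext = ".tsv"); idf <- tempfile(fileext = ".txt")
  write_network(net, ef, idf)
  back <- read_network(ef, idf, net$node_features)
  expect_equal(back$node_ids, net$node_ids)
  expect_equal(back$edges$i, net$edges$i)
  expect_equal(back$edges$j, net$edges$j)
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-9)
})
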