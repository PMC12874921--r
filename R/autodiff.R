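#' @useDynLib dtifuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Every trainable component of the model (GIN, protein CNN, GATv2,
# projections, fusion, classifier, contrastive loss) is expressed with these
# ops; gradients are obtained by a single reverse sweep over the tape.
#
# Conventions: all values are base R matrices. Constants may be passed as
# plain matrices/vectors and are wrapped on the fly; gradients are only
# accumulated for nodes created with ad_param(). Ops are added sparingly -
# each one states its backward rule next to its forward rule.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

# Nodes are plain lists (never mutated after creation); parents are stored by
# id so the backward sweep walks the tape, not object references.
ad_is_node <- function(x) is.list(x) && !is.null(x[["ad_value"]])

ad_push <- function(tape, value, parents = list(), backward = NULL) {
  id <- tape$n + 1L
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node <- list(ad_value = value,
               parent_ids = vapply(parents, function(p) p$id, 1L),
               backward = backward,
               id = id)
  tape$nodes[[id]] <- node
  tape$n <- id
  node
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Leaf node holding a trainable parameter.
ad_param <- function(tape, value) ad_push(tape, as_mat(value))

# Leaf node holding a constant (gradient computed but discarded).
ad_const <- function(tape, value) ad_push(tape, as_mat(value))

ad_wrap <- function(tape, x) if (ad_is_node(x)) x else ad_const(tape, x)

ad_value <- function(x) if (ad_is_node(x)) x$ad_value else as_mat(x)

# Reverse sweep; returns a list indexed by node id (NULL where no gradient).
ad_backward <- function(tape, loss) {
  stopifnot(ad_is_node(loss), length(loss$ad_value) == 1L)
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(node$backward)) next
    pg <- node$backward(g, node)
    pid <- node$parent_ids
    for (k in seq_along(pid)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- pid[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

ad_grad <- function(grads, node) {
  g <- grads[[node$id]]
  if (is.null(g)) matrix(0, nrow(node$ad_value), ncol(node$ad_value)) else g
}

# ---- arithmetic ------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  a <- ad_wrap(tape, a); b <- ad_wrap(tape, b)
  av <- a$ad_value; bv <- b$ad_value
  ad_push(tape, av %*% bv, list(a, b), function(g, node) {
    list(tcrossprod(g, bv), crossprod(av, g))
  })
}

ad_t <- function(tape, a) {
  a <- ad_wrap(tape, a)
  ad_push(tape, t(a$ad_value), list(a), function(g, node) list(t(g)))
}

ad_add <- function(tape, a, b) {
  a <- ad_wrap(tape, a); b <- ad_wrap(tape, b)
  ad_push(tape, a$ad_value + b$ad_value, list(a, b),
          function(g, node) list(g, g))
}

ad_sub <- function(tape, a, b) {
  a <- ad_wrap(tape, a); b <- ad_wrap(tape, b)
  ad_push(tape, a$ad_value - b$ad_value, list(a, b),
          function(g, node) list(g, -g))
}

# x (n x k) plus a 1 x k bias row broadcast over rows
ad_add_bias <- function(tape, x, b) {
  x <- ad_wrap(tape, x); b <- ad_wrap(tape, b)
  v <- sweep(x$ad_value, 2L, -as.numeric(b$ad_value))
  ad_push(tape, v, list(x, b), function(g, node) {
    list(g, matrix(colSums(g), 1L))
  })
}

# elementwise product of two nodes (same shape)
ad_mul <- function(tape, a, b) {
  a <- ad_wrap(tape, a); b <- ad_wrap(tape, b)
  ad_push(tape, a$ad_value * b$ad_value, list(a, b), function(g, node) {
    list(g * b$ad_value, g * a$ad_value)
  })
}

# elementwise product with a constant matrix/scalar
ad_mulc <- function(tape, x, c) {
  x <- ad_wrap(tape, x)
  ad_push(tape, x$ad_value * c, list(x), function(g, node) list(g * c))
}

ad_addc <- function(tape, x, c) {
  x <- ad_wrap(tape, x)
  ad_push(tape, x$ad_value + c, list(x), function(g, node) list(g))
}

# scale a matrix node by a 1x1 scalar node
ad_scale_by <- function(tape, x, s) {
  x <- ad_wrap(tape, x); s <- ad_wrap(tape, s)
  sv <- as.numeric(s$ad_value)
  ad_push(tape, x$ad_value * sv, list(x, s), function(g, node) {
    list(g * sv, matrix(sum(g * x$ad_value), 1L, 1L))
  })
}

# multiply each row of x by the matching entry of a (n x 1) node
ad_rowscale <- function(tape, x, s) {
  x <- ad_wrap(tape, x); s <- ad_wrap(tape, s)
  sv <- as.numeric(s$ad_value)
  ad_push(tape, x$ad_value * sv, list(x, s), function(g, node) {
    list(g * sv, matrix(rowSums(g * x$ad_value), ncol = 1L))
  })
}

# ---- nonlinearities --------------------------------------------------------

ad_relu <- function(tape, x) {
  x <- ad_wrap(tape, x)
  ad_push(tape, pmax(x$ad_value, 0), list(x), function(g, node) {
    list(g * (x$ad_value > 0))
  })
}

ad_leaky_relu <- function(tape, x, alpha = 0.2) {
  x <- ad_wrap(tape, x)
  slope <- alpha + (1 - alpha) * (x$ad_value > 0)
  ad_push(tape, x$ad_value * slope, list(x), function(g, node) {
    list(g * slope)
  })
}

ad_elu <- function(tape, x) {
  x <- ad_wrap(tape, x)
  xv <- x$ad_value
  pos <- xv > 0
  ex <- exp(xv * !pos)         # 1 on the positive side
  v <- xv * pos + (ex - 1) * !pos
  deriv <- pos + ex * !pos
  ad_push(tape, v, list(x), function(g, node) list(g * deriv))
}

ad_gelu <- function(tape, x) {
  x <- ad_wrap(tape, x)
  xv <- x$ad_value
  Phi <- stats::pnorm(xv)
  ad_push(tape, xv * Phi, list(x), function(g, node) {
    list(g * (Phi + xv * stats::dnorm(xv)))
  })
}

ad_tanh <- function(tape, x) {
  x <- ad_wrap(tape, x)
  v <- tanh(x$ad_value)
  ad_push(tape, v, list(x), function(g, node) list(g * (1 - v^2)))
}

ad_exp <- function(tape, x) {
  x <- ad_wrap(tape, x)
  v <- exp(x$ad_value)
  ad_push(tape, v, list(x), function(g, node) list(g * v))
}

ad_log <- function(tape, x) {
  x <- ad_wrap(tape, x)
  ad_push(tape, log(x$ad_value), list(x), function(g, node) {
    list(g / x$ad_value)
  })
}

ad_sqrt <- function(tape, x) {
  x <- ad_wrap(tape, x)
  v <- sqrt(x$ad_value)
  ad_push(tape, v, list(x), function(g, node) list(g * 0.5 / v))
}

ad_recip <- function(tape, x) {
  x <- ad_wrap(tape, x)
  v <- 1 / x$ad_value
  ad_push(tape, v, list(x), function(g, node) list(-g * v^2))
}

# ---- structure ops ---------------------------------------------------------

# gather rows by index; backward scatter-adds
ad_rows <- function(tape, x, idx) {
  x <- ad_wrap(tape, x)
  idx <- as.integer(idx)
  nx <- nrow(x$ad_value)
  ad_push(tape, dti_gather(x$ad_value, idx), list(x), function(g, node) {
    list(dti_scatter_add(g, idx, nx))
  })
}

# segment sum: rows of x grouped by `group` (values 1..ngroups)
ad_rowsum_by <- function(tape, x, group, ngroups) {
  x <- ad_wrap(tape, x)
  group <- as.integer(group)
  ad_push(tape, dti_scatter_add(x$ad_value, group, ngroups), list(x),
          function(g, node) {
    list(dti_gather(g, group))
  })
}

# segment max (global max pooling per group); gradient routes to argmax rows
ad_rowmax_by <- function(tape, x, group, ngroups) {
  x <- ad_wrap(tape, x)
  group <- as.integer(group)
  xv <- x$ad_value
  k <- ncol(xv)
  sm <- dti_segment_max(xv, group, ngroups)
  amax <- sm$argmax
  ad_push(tape, sm$values, list(x), function(g, node) {
    dX <- matrix(0, nrow(xv), k)
    pos <- cbind(as.vector(amax), rep(seq_len(k), each = ngroups))
    ok <- pos[, 1L] > 0L
    dX[pos[ok, , drop = FALSE]] <- g[cbind(as.vector(row(amax)),
                                           as.vector(col(amax)))][ok]
    list(dX)
  })
}

ad_cbind <- function(tape, xs) {
  xs <- lapply(xs, ad_wrap, tape = tape)
  widths <- vapply(xs, function(x) ncol(x$ad_value), 1L)
  v <- do.call(cbind, lapply(xs, ad_value))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_push(tape, v, xs, function(g, node) {
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rbind <- function(tape, xs) {
  xs <- lapply(xs, ad_wrap, tape = tape)
  heights <- vapply(xs, function(x) nrow(x$ad_value), 1L)
  v <- do.call(rbind, lapply(xs, ad_value))
  ends <- cumsum(heights)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ad_push(tape, v, xs, function(g, node) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_col <- function(tape, x, j) {
  x <- ad_wrap(tape, x)
  ad_push(tape, x$ad_value[, j, drop = FALSE], list(x), function(g, node) {
    dX <- matrix(0, nrow(x$ad_value), ncol(x$ad_value))
    dX[, j] <- g
    list(dX)
  })
}

ad_rowsums <- function(tape, x) {
  x <- ad_wrap(tape, x)
  k <- ncol(x$ad_value)
  ad_push(tape, matrix(rowSums(x$ad_value), ncol = 1L), list(x),
          function(g, node) list(g[, rep(1L, k), drop = FALSE]))
}

ad_sum <- function(tape, x) {
  x <- ad_wrap(tape, x)
  dims <- dim(x$ad_value)
  ad_push(tape, matrix(sum(x$ad_value), 1L, 1L), list(x), function(g, node) {
    list(matrix(as.numeric(g), dims[1L], dims[2L]))
  })
}

ad_mean <- function(tape, x) {
  n <- length(ad_value(x))
  ad_mulc(tape, ad_sum(tape, x), 1 / n)
}

# subtract a per-row constant (n-vector), e.g. a stop-gradient row max
ad_sub_rowconst <- function(tape, x, m) {
  x <- ad_wrap(tape, x)
  ad_push(tape, x$ad_value - m, list(x), function(g, node) list(g))
}

# row-wise softmax
ad_softmax_rows <- function(tape, x) {
  x <- ad_wrap(tape, x)
  xv <- x$ad_value
  e <- exp(xv - apply(xv, 1L, max))
  v <- e / rowSums(e)
  ad_push(tape, v, list(x), function(g, node) {
    list(v * (g - rowSums(g * v)))
  })
}

# mean binary cross-entropy computed from logits (numerically stable)
ad_bce_logits <- function(tape, z, y) {
  z <- ad_wrap(tape, z)
  zv <- as.numeric(z$ad_value)
  y <- as.numeric(y)
  n <- length(zv)
  stopifnot(length(y) == n)
  softplus <- pmax(zv, 0) + log1p(exp(-abs(zv)))
  v <- matrix(mean(softplus - y * zv), 1L, 1L)
  ad_push(tape, v, list(z), function(g, node) {
    list(matrix(as.numeric(g) * (stats::plogis(zv) - y) / n, ncol = 1L))
  })
}

# L2 row normalization with an epsilon guard (cosine-similarity plumbing)
ad_rownorm <- function(tape, x, eps = 1e-8) {
  sq <- ad_rowsums(tape, ad_mul(tape, x, x))
  nrm <- ad_addc(tape, ad_sqrt(tape, ad_addc(tape, sq, 1e-20)), eps)
  ad_rowscale(tape, x, ad_recip(tape, nrm))
}

# fused dense layer: activation(x %*% W + b) in one tape node
ad_dense <- function(tape, x, W, b, act = c("identity", "relu", "gelu", "tanh")) {
  act <- match.arg(act)
  x <- ad_wrap(tape, x); W <- ad_wrap(tape, W); b <- ad_wrap(tape, b)
  xv <- x$ad_value; Wv <- W$ad_value
  pre <- xv %*% Wv
  pre <- pre + rep(as.numeric(b$ad_value), each = nrow(pre))
  if (act == "identity") {
    v <- pre; dact <- NULL
  } else if (act == "relu") {
    v <- pre * (dact <- (pre > 0))
  } else if (act == "gelu") {
    Phi <- stats::pnorm(pre)
    v <- pre * Phi
    dact <- Phi + pre * stats::dnorm(pre)
  } else {
    v <- tanh(pre)
    dact <- 1 - v^2
  }
  ad_push(tape, v, list(x, W, b), function(g, node) {
    dpre <- if (is.null(dact)) g else g * dact
    list(tcrossprod(dpre, Wv),
         crossprod(xv, dpre),
         matrix(colSums(dpre), 1L))
  })
}

# ---- fused graph / sequence ops (hot path) ----------------------------------

# neighbor sum over a directed edge list: out[i] = sum_{e: src=i} h[dst[e]]
ad_neighbor_sum <- function(tape, h, src, dst, n) {
  h <- ad_wrap(tape, h)
  hv <- h$ad_value
  src <- as.integer(src); dst <- as.integer(dst)
  ad_push(tape, dti_scatter_add(dti_gather(hv, dst), src, n), list(h),
          function(g, node) {
    list(dti_scatter_add(dti_gather(g, src), dst, nrow(hv)))
  })
}

# per-group mean of rows (readout pooling)
ad_group_mean <- function(tape, h, group, ngroups) {
  h <- ad_wrap(tape, h)
  group <- as.integer(group)
  sizes <- tabulate(group, nbins = ngroups)
  sizes[sizes == 0L] <- 1L
  v <- dti_scatter_add(h$ad_value, group, ngroups) / sizes
  ad_push(tape, v, list(h), function(g, node) {
    list(dti_gather(g / sizes, group))
  })
}

# im2col gather for 1-d convolution: idx is (positions x k) with 0 denoting a
# zero pad; output column blocks are the k shifted copies of h
ad_im2col <- function(tape, h, idx) {
  h <- ad_wrap(tape, h)
  hv <- h$ad_value
  storage.mode(idx) <- "integer"
  ad_push(tape, dti_im2col(hv, idx), list(h), function(g, node) {
    list(dti_im2col_grad(g, idx, nrow(hv)))
  })
}

# attention-weighted neighbor aggregation:
# out[i] = sum_{e: src=i} alpha[e] * h[dst[e]]
ad_edge_aggregate <- function(tape, h, alpha, src, dst, n) {
  h <- ad_wrap(tape, h); alpha <- ad_wrap(tape, alpha)
  hv <- h$ad_value
  src <- as.integer(src); dst <- as.integer(dst)
  av <- as.numeric(alpha$ad_value)
  hd <- dti_gather(hv, dst)
  ad_push(tape, dti_scatter_add(hd * av, src, n), list(h, alpha),
          function(g, node) {
    T_ <- dti_gather(g, src)
    list(dti_scatter_add(T_ * av, dst, nrow(hv)),
         matrix(rowSums(hd * T_), ncol = 1L))
  })
}
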