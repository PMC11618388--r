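# Elementwise, reduction and shape operations on the tape.
# All tensors are plain numeric arrays; feature maps use dim c(H, W, C, N).

ag_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ag_op(av + bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) sum(g) else g
    list(ga, gb)
  })
}

ag_sub <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ag_op(av - bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ag_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ag_op(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(av) == 1L) ga <- sum(ga)
    if (length(bv) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_div <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ag_op(av / bv, list(a, b), function(g) {
    ga <- g / bv; gb <- -g * av / (bv * bv)
    if (length(av) == 1L) ga <- sum(ga)
    if (length(bv) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_neg  <- function(a) ag_op(-vof(a), list(a), function(g) list(-g))
ag_sq   <- function(a) { v <- vof(a); ag_op(v * v, list(a), function(g) list(2 * g * v)) }
ag_sqrt <- function(a) { v <- sqrt(vof(a)); ag_op(v, list(a), function(g) list(g / (2 * pmax(v, 1e-12)))) }
ag_exp  <- function(a) { v <- exp(vof(a)); ag_op(v, list(a), function(g) list(g * v)) }
ag_log  <- function(a) { v <- vof(a); ag_op(log(v), list(a), function(g) list(g / v)) }
ag_atan <- function(a) { v <- vof(a); ag_op(atan(v), list(a), function(g) list(g / (1 + v * v))) }

ag_sigmoid <- function(a) {
  s <- cpp_sigmoid(vof(a))
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_silu <- function(a) {
  v <- vof(a)
  ag_op(cpp_silu(v), list(a), function(g) list(cpp_silu_bw(v, g)))
}

# tanh-approximation GELU (transformer MLP convention)
ag_gelu <- function(a) {
  v <- vof(a)
  k <- sqrt(2 / pi)
  inner <- k * (v + 0.044715 * v^3)
  t <- tanh(inner)
  y <- 0.5 * v * (1 + t)
  ag_op(y, list(a), function(g) {
    dt <- (1 - t^2) * k * (1 + 3 * 0.044715 * v^2)
    list(g * (0.5 * (1 + t) + 0.5 * v * dt))
  })
}

# hard swish / hard sigmoid (coordinate-attention convention: relu6(x+3)/6)
ag_hsigmoid <- function(a) {
  v <- vof(a)
  y <- pmin(pmax(v + 3, 0), 6) / 6
  ag_op(y, list(a), function(g) list(g * ((v > -3) & (v < 3)) / 6))
}

ag_hswish <- function(a) {
  v <- vof(a)
  h <- pmin(pmax(v + 3, 0), 6) / 6
  ag_op(v * h, list(a), function(g) list(g * (h + v * ((v > -3) & (v < 3)) / 6)))
}

ag_pmax <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  m <- pmax(av, bv)
  ag_op(m, list(a, b), function(g) {
    ga <- g * (av >= bv); gb <- g * (av < bv)
    if (length(av) == 1L) ga <- sum(ga)
    if (length(bv) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_pmin <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  m <- pmin(av, bv)
  ag_op(m, list(a, b), function(g) {
    ga <- g * (av <= bv); gb <- g * (av > bv)
    if (length(av) == 1L) ga <- sum(ga)
    if (length(bv) == 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ag_clamp <- function(a, lo, hi) {
  v <- vof(a)
  ag_op(pmin(pmax(v, lo), hi), list(a), function(g) list(g * (v >= lo & v <= hi)))
}

ag_sum  <- function(a) ag_op(sum(vof(a)), list(a), function(g) list(array(as.numeric(g), dim = dim(vof(a)) %||% length(vof(a)))))
ag_mean <- function(a) {
  n <- length(vof(a))
  ag_op(sum(vof(a)) / n, list(a), function(g) list(array(as.numeric(g) / n, dim = dim(vof(a)) %||% n)))
}

ag_reshape <- function(a, dims) {
  v <- vof(a); od <- dim(v) %||% length(v)
  y <- v; dim(y) <- dims
  ag_op(y, list(a), function(g) { dim(g) <- od; list(g) })
}

ag_aperm <- function(a, perm) {
  v <- vof(a)
  ag_op(aperm(v, perm), list(a), function(g) list(aperm(g, order(perm))))
}

# concatenate along array dimension `dm`
ag_concat <- function(xs, dm) {
  vals <- lapply(xs, vof)
  dims <- lapply(vals, dim)
  fast <- dm == 3L && all(vapply(dims, length, integer(1)) == 4L)
  y <- if (fast) cpp_concat_c(vals, dims) else do.call(abind4, c(vals, list(dm = dm)))
  sizes <- vapply(dims, function(d) d[dm], numeric(1))
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  ag_op(y, xs, function(g) {
    if (fast)
      lapply(seq_along(xs), function(k)
        cpp_slice_c(g, dim(g), starts[k] - 1L, sizes[k]))
    else
      lapply(seq_along(xs), function(k) slice_dim(g, dm, starts[k]:ends[k]))
  })
}

# slice along dimension `dm` (keeps dims)
ag_slice <- function(a, dm, idx) {
  v <- vof(a); od <- dim(v)
  contiguous <- length(idx) > 0L && all(diff(idx) == 1L)
  fast <- dm == 3L && length(od) == 4L && contiguous
  y <- if (fast) cpp_slice_c(v, od, idx[1] - 1L, length(idx)) else slice_dim(v, dm, idx)
  ag_op(y, list(a), function(g) {
    if (fast) return(list(cpp_slice_c_bw(g, od, idx[1] - 1L, length(idx))))
    gx <- array(0, dim = od)
    list(assign_dim(gx, dm, idx, g))
  })
}

# gather a flat-index subset as a vector
ag_gather <- function(a, idx) {
  v <- vof(a)
  ag_op(as.numeric(v[idx]), list(a), function(g) {
    gx <- array(0, dim = dim(v) %||% length(v))
    # idx may repeat: accumulate
    agg <- rowsum(as.numeric(g), group = idx)
    gx[as.numeric(rownames(agg))] <- agg[, 1]
    list(gx)
  })
}

# multiply with broadcasting: dims of `b` are 1 wherever they differ from `a`
ag_mul_bc <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  da <- dim(av); db <- dim(bv)
  ag_op(cpp_bc_mul(av, da, bv, db), list(a, b), function(g) {
    list(cpp_bc_mul(g, da, bv, db), cpp_bc_sum(g * av, da, db))
  })
}

# ---- small array helpers (plain values, not ops) --------------------------

abind4 <- function(..., dm) {
  xs <- list(...)
  d0 <- dim(xs[[1]])
  nd <- length(d0)
  total <- sum(vapply(xs, function(x) dim(x)[dm], numeric(1)))
  dn <- d0; dn[dm] <- total
  out <- array(0, dim = dn)
  at <- 1L
  for (x in xs) {
    k <- dim(x)[dm]
    out <- assign_dim(out, dm, at:(at + k - 1L), x)
    at <- at + k
  }
  out
}

slice_dim <- function(x, dm, idx) {
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[dm]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

assign_dim <- function(x, dm, idx, value) {
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[dm]] <- idx
  do.call(`[<-`, c(list(x), args, list(value = value)))
}

bc_expand <- function(b, target_dim) {
  db <- dim(b)
  if (identical(db, target_dim)) return(b)
  for (k in seq_along(target_dim)) {
    if (db[k] == 1L && target_dim[k] > 1L) {
      perm <- c(k, seq_along(db)[-k])
      bp <- aperm(b, perm)
      bp <- array(rep(as.numeric(bp), each = target_dim[k]),
                  dim = c(target_dim[k], dim(b)[-k]))
      b <- aperm(bp, order(perm))
      db <- dim(b)
    }
  }
  b
}

dim_sum <- function(x, k) {
  d <- dim(x)
  perm <- c(k, seq_along(d)[-k])
  xp <- aperm(x, perm)
  dim(xp) <- c(d[k], prod(d[-k]))
  s <- colSums(xp)
  out <- array(s, dim = c(1L, d[-k]))
  aperm(out, order(perm))
}
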