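# Low-level neural-network primitives.
#
# Feature maps are stored as (H*W) x C matrices using R's column-major
# convention for an H x W image plane: row index = y + (x - 1) * H.
# All convolutions are 3x3, stride 1, zero-padded ("same"); pooling is
# 2x2 max with stride 2. Gather/scatter index tables are precomputed once
# per layer, so the forward and reverse passes reduce to single vector
# gathers plus BLAS matrix products.

.conv_geom <- function(H, W, Cin) {
  Hp <- H + 2L
  Wp <- W + 2L
  np <- Hp * Wp
  ys <- rep(seq_len(H), times = W)
  xs <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  o <- 0L
  for (dx in -1L:1L) {
    for (dy in -1L:1L) {
      o <- o + 1L
      # padded-plane linear index of input pixel (y+dy, x+dx)
      idx[, o] <- (ys + dy + 1L) + (xs + dx) * Hp
    }
  }
  chan_off <- (seq_len(Cin) - 1L) * np
  gidx <- matrix(0L, H * W, 9L * Cin)
  for (o in 1:9) {
    gidx[, ((o - 1L) * Cin + 1L):(o * Cin)] <-
      outer(idx[, o], chan_off, `+`)
  }
  interior <- outer((ys + 1L) + xs * Hp, chan_off, `+`)
  list(gidx = gidx, interior = interior, np = np, Cin = Cin, H = H, W = W)
}

.pool_geom <- function(H, W, C) {
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), times = Wo)
  xo <- rep(seq_len(Wo), each = Ho)
  y1 <- 2L * yo - 1L
  x1 <- 2L * xo - 1L
  base <- cbind(y1 + (x1 - 1L) * H,
                y1 + 1L + (x1 - 1L) * H,
                y1 + x1 * H,
                y1 + 1L + x1 * H)
  chan_off <- (seq_len(C) - 1L) * (H * W)
  # kept as plain vectors: indexing a matrix with a 2-column integer matrix
  # would otherwise be read as (row, col) coordinate pairs
  pvidx <- lapply(1:4, function(j) as.vector(outer(base[, j], chan_off, `+`)))
  list(pvidx = pvidx, Ho = Ho, Wo = Wo, H = H, W = W, C = C)
}

# x: (H*W) x Cin; Wm: (9*Cin) x Cout with rows grouped by kernel offset
# then input channel (the layout must only be consistent between the
# forward and reverse passes).
.conv_forward <- function(x, Wm, b, g) {
  Pv <- numeric(g$np * g$Cin)
  Pv[g$interior] <- x
  cols <- matrix(Pv[g$gidx], nrow(x), 9L * g$Cin)
  out <- cols %*% Wm
  out <- out + rep(b, each = nrow(out))
  list(out = out, cols = cols)
}

.conv_backward <- function(dout, cols, Wm, g) {
  dW <- crossprod(cols, dout)
  db <- colSums(dout)
  dcols <- tcrossprod(dout, Wm)
  dPv <- numeric(g$np * g$Cin)
  Cin <- g$Cin
  for (o in 1:9) {
    blk <- ((o - 1L) * Cin + 1L):(o * Cin)
    sub <- g$gidx[, blk]
    # indices are unique within one kernel offset, so gather-add-scatter
    # accumulates correctly; overlaps only occur across offsets
    dPv[sub] <- dPv[sub] + dcols[, blk]
  }
  list(dW = dW, db = db,
       dx = matrix(dPv[g$interior], nrow(dout), Cin))
}

.maxpool_forward <- function(x, pg) {
  m <- matrix(x[pg$pvidx[[1]]], pg$Ho * pg$Wo, pg$C)
  arg <- matrix(1L, nrow(m), ncol(m))
  for (j in 2:4) {
    cand <- matrix(x[pg$pvidx[[j]]], nrow(m), ncol(m))
    upd <- cand > m          # ties keep the earliest window position
    m[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(out = m, arg = arg)
}

.maxpool_backward <- function(dout, arg, pg) {
  dx <- matrix(0, pg$H * pg$W, pg$C)
  for (j in 1:4) {
    mask <- arg == j
    if (any(mask)) {
      sub <- pg$pvidx[[j]][mask]
      dx[sub] <- dx[sub] + dout[mask]
    }
  }
  dx
}

.sigmoid <- function(z) stats::plogis(z)

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
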