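# Minimal convolutional network on im2col + GEMM.
#
# Activations are stored column-per-sample with channel-major layout: a
# (C, H, W) feature map flattens to index c + (h-1)C + (w-1)CH, so a
# batch is a (C*H*W) x B matrix and every convolution is one matrix
# product against an im2col view. Max pooling acts along the time (W)
# axis only. All shapes are fixed at build time from the frame geometry.

# im2col gather index for a (C, H, W) input and a (kh, kw) kernel,
# valid padding, optional stride along time; columns ordered time-major
# (h' fastest)
conv_index <- function(C, H, W, kh, kw, stride = 1L) {
  Ho <- H - kh + 1
  Wo <- (W - kw) %/% stride + 1L
  cs <- rep(seq_len(C), times = kh * kw)
  dhs <- rep(rep(0:(kh - 1), each = C), times = kw)
  dws <- rep(0:(kw - 1), each = C * kh)
  is <- rep(seq_len(Ho), times = Wo)
  js <- rep((seq_len(Wo) - 1L) * stride + 1L, each = Ho)
  idx <- cs + (outer(dhs, is, `+`) - 1L) * C + (outer(dws, js, `+`) - 1L) * C * H
  storage.mode(idx) <- "integer"
  list(idx = as.vector(idx), P = C * kh * kw, Ho = Ho, Wo = Wo)
}

# network plan: conv stages then dense stack, from the input geometry;
# with global_pool the conv output is averaged over all positions per
# filter (translation-invariant features) instead of flattened
nn_plan <- function(height, width, conv_filters, kernel_time, pool,
                    dense_widths, global_pool = FALSE, stride = 1L) {
  C <- 1L; H <- as.integer(height); W <- as.integer(width)
  pool <- rep_len(as.integer(pool), length(conv_filters))
  stride <- rep_len(as.integer(stride), length(conv_filters))
  stages <- list()
  for (si in seq_along(conv_filters)) {
    f <- conv_filters[si]
    kh <- min(3L, H)
    kw <- min(as.integer(kernel_time), W)
    ci <- conv_index(C, H, W, kh, kw, stride = stride[si])
    pw <- if (ci$Wo >= pool[si]) pool[si] else 1L
    stages[[length(stages) + 1]] <-
      list(C_in = C, H_in = H, W_in = W, kh = kh, kw = kw, filters = f,
           idx = ci$idx, P = ci$P, Ho = ci$Ho, Wo = ci$Wo,
           pool = pw, Wp = ci$Wo %/% pw)
    C <- as.integer(f); H <- ci$Ho; W <- stages[[length(stages)]]$Wp
  }
  flat <- if (global_pool) C else C * H * W
  widths <- c(flat, dense_widths, 1L)
  list(stages = stages, flat = flat, gp_hw = H * W,
       global_pool = global_pool, dense_widths = widths)
}

nn_init <- function(plan) {
  ws <- list(conv = list(), dense = list())
  for (s in plan$stages) {
    ws$conv[[length(ws$conv) + 1]] <-
      list(W = matrix(rnorm(s$filters * s$P, sd = sqrt(2 / s$P)),
                      s$filters, s$P),
           b = rep(0, s$filters))
  }
  wd <- plan$dense_widths
  for (i in seq_len(length(wd) - 1)) {
    last <- i == length(wd) - 1
    ws$dense[[i]] <- list(W = matrix(rnorm(wd[i + 1] * wd[i],
                                           sd = sqrt((if (last) 1 else 2) / wd[i])),
                                     wd[i + 1], wd[i]),
                          b = rep(0, wd[i + 1]))
  }
  ws
}

# forward pass; keep = TRUE retains the caches needed for backprop
nn_forward <- function(x, plan, ws, keep = FALSE) {
  B <- ncol(x)
  caches <- if (keep) vector("list", length(plan$stages))
  a <- x
  for (si in seq_along(plan$stages)) {
    s <- plan$stages[[si]]
    O <- s$Ho * s$Wo
    xcol <- a[s$idx, , drop = FALSE]
    dim(xcol) <- c(s$P, O * B)
    z <- ws$conv[[si]]$W %*% xcol + ws$conv[[si]]$b
    relu_mask <- z > 0
    z[!relu_mask] <- 0
    dim(z) <- c(s$filters * O, B)
    # max pool along time: view as (GH*pool, Wp*B) row blocks
    GH <- s$filters * s$Ho
    pooled_cols <- s$Wp * s$pool
    if (s$pool > 1L || pooled_cols < s$Wo) {
      zt <- z
      dim(zt) <- c(GH, s$Wo, B)
      zt <- zt[, seq_len(pooled_cols), , drop = FALSE]
      dim(zt) <- c(GH * s$pool, s$Wp * B)
      cur <- zt[seq_len(GH), , drop = FALSE]
      amax <- matrix(1L, GH, s$Wp * B)
      if (s$pool > 1) {
        for (p in 2:s$pool) {
          blk <- zt[((p - 1) * GH + 1):(p * GH), , drop = FALSE]
          upd <- blk > cur
          amax[upd] <- p
          cur[upd] <- blk[upd]
        }
      }
      out <- cur
      dim(out) <- c(GH * s$Wp, B)
    } else {
      amax <- NULL
      out <- z
    }
    if (keep) {
      caches[[si]] <- list(xcol = xcol, relu = relu_mask, amax = amax)
    }
    a <- out
  }
  if (plan$global_pool) {
    C <- plan$flat
    dim(a) <- c(C, plan$gp_hw, B)
    a <- colMeans(aperm(a, c(2, 1, 3)))  # (C, B) mean over positions
    dim(a) <- c(C, B)
  }
  dcache <- if (keep) vector("list", length(ws$dense))
  for (di in seq_along(ws$dense)) {
    if (keep) dcache[[di]] <- list(a_in = a)
    z <- ws$dense[[di]]$W %*% a + ws$dense[[di]]$b
    if (di < length(ws$dense)) {
      mask <- z > 0
      z[!mask] <- 0
      if (keep) dcache[[di]]$relu <- mask
    }
    a <- z
  }
  p <- plogis(drop(a))
  if (keep) list(p = p, conv = caches, dense = dcache) else p
}

# backward pass: returns gradients with the same shapes as ws
nn_backward <- function(x, y, plan, ws, fw, w = 1) {
  B <- ncol(x)
  grads <- list(conv = vector("list", length(ws$conv)),
                dense = vector("list", length(ws$dense)))
  delta <- matrix(w * (fw$p - y) / B, 1, B)  # dL/dz of the sigmoid output
  for (di in rev(seq_along(ws$dense))) {
    cache <- fw$dense[[di]]
    grads$dense[[di]] <- list(W = delta %*% t(cache$a_in),
                              b = rowSums(delta))
    if (di > 1 || length(ws$conv)) {
      delta <- t(ws$dense[[di]]$W) %*% delta
      if (di > 1) delta <- delta * fw$dense[[di - 1]]$relu
    }
  }
  if (plan$global_pool) {
    # spread the per-filter gradient uniformly over pooled positions
    C <- plan$flat
    hw <- plan$gp_hw
    delta <- aperm(array(rep(delta / hw, times = hw), c(C, B, hw)),
                   c(1, 3, 2))
    dim(delta) <- c(C * hw, B)
  }
  for (si in rev(seq_along(plan$stages))) {
    s <- plan$stages[[si]]
    cache <- fw$conv[[si]]
    GH <- s$filters * s$Ho
    if (!is.null(cache$amax)) {
      dpool <- delta
      dim(dpool) <- c(GH, s$Wp * B)
      dz <- matrix(0, GH * s$pool, s$Wp * B)
      for (p in seq_len(s$pool)) {
        rows <- ((p - 1) * GH + 1):(p * GH)
        sel <- cache$amax == p
        blk <- matrix(0, GH, s$Wp * B)
        blk[sel] <- dpool[sel]
        dz[rows, ] <- blk
      }
      dim(dz) <- c(GH, s$pool * s$Wp, B)
      if (s$pool * s$Wp < s$Wo) {
        pad <- array(0, dim = c(GH, s$Wo, B))
        pad[, seq_len(s$pool * s$Wp), ] <- dz
        dz <- pad
      }
      dim(dz) <- c(s$filters, s$Ho * s$Wo * B)
    } else {
      dz <- delta
      dim(dz) <- c(s$filters, s$Ho * s$Wo * B)
    }
    rl <- cache$relu
    dz[!rl] <- 0
    grads$conv[[si]] <- list(W = dz %*% t(cache$xcol), b = rowSums(dz))
    if (si > 1) {
      dxcol <- t(ws$conv[[si]]$W) %*% dz
      dim(dxcol) <- c(s$P * s$Ho * s$Wo, B)
      rs <- rowsum(dxcol, s$idx)  # col2im scatter-add
      full <- s$C_in * s$H_in * s$W_in
      if (nrow(rs) < full) {  # strided conv can leave positions unused
        delta <- matrix(0, full, B)
        delta[as.integer(rownames(rs)), ] <- rs
      } else {
        delta <- rs
      }
    }
  }
  grads
}

# Adam step (in place on the weight list)
adam_init <- function(ws) rapply(ws, function(w) w * 0, how = "replace")

adam_step <- function(ws, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  upd <- function(path_w, path_g, path_m, path_v) {
    m2 <- beta1 * path_m + (1 - beta1) * path_g
    v2 <- beta2 * path_v + (1 - beta2) * path_g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    list(w = path_w - lr * (mhat / (sqrt(vhat) + eps) +
                              weight_decay * path_w),
         m = m2, v = v2)
  }
  for (kind in c("conv", "dense")) {
    for (i in seq_along(ws[[kind]])) {
      for (nm in c("W", "b")) {
        r <- upd(ws[[kind]][[i]][[nm]], grads[[kind]][[i]][[nm]],
                 m[[kind]][[i]][[nm]], v[[kind]][[i]][[nm]])
        ws[[kind]][[i]][[nm]] <- r$w
        m[[kind]][[i]][[nm]] <- r$m
        v[[kind]][[i]][[nm]] <- r$v
      }
    }
  }
  list(ws = ws, m = m, v = v)
}

# weighted binary cross-entropy; w = per-observation weights (mean 1)
bce_loss <- function(p, y, w = 1) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}
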