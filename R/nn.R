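# Neural-network internals ------------------------------------------------
#
# The multitask 1-D convolutional-recurrent classifier is implemented on
# BLAS-backed matrix algebra. Sequences travel as (B*T) x C matrices with
# the T time blocks stacked rowwise (row b + (t-1)*B holds sample t of
# batch element b), which makes the input projections, the convolution
# im2col and every parameter gradient a single stacked matrix product. The
# recurrent time loop and the im2col/scatter live in compiled code
# (src/nn_kernels.cpp). Gradients of every layer are validated against
# central finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# GRU (reset-before-multiplication variant) --------------------------------

gru_forward <- function(x_stack, bsz, tlen, w, uzr, un, b) {
  out <- gru_forward_cpp(x_stack, bsz, tlen, w, uzr, un, b)
  list(h_stack = out$h_stack,
       cache = list(x_stack = x_stack, z = out$z, r = out$r, n = out$n,
                    hs = out$h_stack, bsz = bsz, tlen = tlen))
}

gru_backward <- function(dh_stack, cache, w, uzr, un) {
  gru_backward_cpp(dh_stack, cache$x_stack, cache$z, cache$r, cache$n,
                   cache$hs, w, uzr, un, cache$bsz, cache$tlen)
}

# 1-D convolution with same padding ----------------------------------------

conv_forward <- function(x_stack, bsz, tlen, w, b) {
  k <- nrow(w) / ncol(x_stack)
  xcol <- conv_unroll_cpp(x_stack, bsz, tlen, as.integer(k))
  y <- xcol %*% w
  y <- y + rep(b, each = nrow(y))
  list(y = y, cache = list(xcol = xcol, bsz = bsz, tlen = tlen,
                           cin = ncol(x_stack), k = as.integer(k)))
}

conv_backward <- function(dy, cache, w) {
  dxcol <- dy %*% t(w)
  list(
    dx = conv_scatter_cpp(dxcol, cache$bsz, cache$tlen, cache$k, cache$cin),
    dw = crossprod(cache$xcol, dy),
    db = colSums(dy)
  )
}

# Batch normalization per channel over batch and time -----------------------

bn_forward <- function(m, gamma, beta, running, training,
                       momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  ivstd <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(ivstd, each = nrow(m))
  y <- xhat * rep(gamma, each = nrow(m)) + rep(beta, each = nrow(m))
  list(y = y, running = running, cache = list(xhat = xhat, ivstd = ivstd))
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  m <- nrow(dy)
  dxhat <- dy * rep(gamma, each = m)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - xhat * rep(s2 / m, each = m) -
           rep(s1 / m, each = m)) * rep(cache$ivstd, each = m)
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

# Max pooling along time (non-overlapping pairs) ----------------------------

pool_index <- function(bsz, tlen, size = 2L) {
  t2 <- tlen %/% size
  i1 <- as.vector(outer(seq_len(bsz), (seq_len(t2) - 1L) * 2L * bsz, "+"))
  list(i1 = i1, i2 = i1 + bsz, t2 = t2, n_in = bsz * tlen)
}

pool_forward <- function(x_stack, bsz, tlen, size = 2L) {
  idx <- pool_index(bsz, tlen, size)
  a1 <- x_stack[idx$i1, , drop = FALSE]
  a2 <- x_stack[idx$i2, , drop = FALSE]
  take1 <- a1 >= a2
  list(y = pmax(a1, a2),
       cache = c(idx, list(take1 = take1, ncol = ncol(x_stack))))
}

pool_backward <- function(dy, cache) {
  dx <- matrix(0, cache$n_in, cache$ncol)
  dx[cache$i1, ] <- dy * cache$take1
  dx[cache$i2, ] <- dy * (!cache$take1)
  dx
}

# Dropout (inverted) --------------------------------------------------------

dropout_forward <- function(x, rate, active) {
  if (!active || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- array((runif(length(x)) >= rate) / (1 - rate),
                dim = dim(x) %||% length(x))
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1, max))
  z / rowSums(z)
}

# Parameter initialization --------------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_params <- function(cfg, n_seq_channels, t_len, n_ctx) {
  h1 <- cfg$gru_units[1]; h2 <- cfg$gru_units[2]
  f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
  k1 <- cfg$kernel_sizes[1]; k2 <- cfg$kernel_sizes[2]
  t_flat <- (t_len %/% cfg$pool_size) %/% cfg$pool_size
  head_in <- t_flat * f2 + n_ctx
  p <- list(
    gru1.W = glorot(n_seq_channels, 3 * h1),
    gru1.Uzr = glorot(h1, 2 * h1), gru1.Un = glorot(h1, h1),
    gru1.b = numeric(3 * h1),
    gru2.W = glorot(h1, 3 * h2),
    gru2.Uzr = glorot(h2, 2 * h2), gru2.Un = glorot(h2, h2),
    gru2.b = numeric(3 * h2),
    conv1.W = glorot(k1 * h2, f1), conv1.b = numeric(f1),
    bn1.gamma = rep(1, f1), bn1.beta = numeric(f1),
    conv2.W = glorot(k2 * f1, f2), conv2.b = numeric(f2),
    bn2.gamma = rep(1, f2), bn2.beta = numeric(f2)
  )
  heads <- list(nerve = 3L, side = 2L, position = 2L)
  for (h in names(heads)) {
    p[[paste0(h, ".W1")]] <- glorot(head_in, cfg$dense_units)
    p[[paste0(h, ".b1")]] <- numeric(cfg$dense_units)
    p[[paste0(h, ".W2")]] <- glorot(cfg$dense_units, heads[[h]])
    p[[paste0(h, ".b2")]] <- numeric(heads[[h]])
  }
  p
}

init_bn_state <- function(cfg) {
  list(
    bn1 = list(mean = numeric(cfg$conv_filters[1]),
               var = rep(1, cfg$conv_filters[1])),
    bn2 = list(mean = numeric(cfg$conv_filters[2]),
               var = rep(1, cfg$conv_filters[2]))
  )
}

is_weight_param <- function(name) {
  grepl("\\.(W|Uzr|Un|W1|W2)$", name)
}

# Full network -------------------------------------------------------------
# mode: "infer" (running BN stats, no dropout), "train" (batch BN stats,
# dropout active), "mc" (running BN stats, dropout active)

nn_forward <- function(params, state, x_seq, x_ctx, cfg, mode = "infer") {
  bsz <- nrow(x_seq)
  tlen <- ncol(x_seq)
  training <- mode == "train"
  drop_on <- mode %in% c("train", "mc")
  x1 <- matrix(as.vector(x_seq), ncol = 1L)      # (B*T) x 1 stacked
  g1 <- gru_forward(x1, bsz, tlen, params$gru1.W, params$gru1.Uzr,
                    params$gru1.Un, params$gru1.b)
  g2 <- gru_forward(g1$h_stack, bsz, tlen, params$gru2.W, params$gru2.Uzr,
                    params$gru2.Un, params$gru2.b)
  dg <- dropout_forward(g2$h_stack, cfg$dropout$gru, drop_on)
  c1 <- conv_forward(dg$y, bsz, tlen, params$conv1.W, params$conv1.b)
  b1 <- bn_forward(c1$y, params$bn1.gamma, params$bn1.beta, state$bn1,
                   training)
  state$bn1 <- b1$running
  r1 <- pmax(b1$y, 0)
  p1 <- pool_forward(r1, bsz, tlen, cfg$pool_size)
  t1 <- p1$cache$t2
  c2 <- conv_forward(p1$y, bsz, t1, params$conv2.W, params$conv2.b)
  b2 <- bn_forward(c2$y, params$bn2.gamma, params$bn2.beta, state$bn2,
                   training)
  state$bn2 <- b2$running
  r2 <- pmax(b2$y, 0)
  p2 <- pool_forward(r2, bsz, t1, cfg$pool_size)
  t2 <- p2$cache$t2
  flat <- p2$y
  dim(flat) <- c(bsz, t2 * ncol(flat))
  z <- cbind(flat, x_ctx)
  dz <- dropout_forward(z, cfg$dropout$dense, drop_on)
  heads <- list()
  hcache <- list()
  for (h in c("nerve", "side", "position")) {
    a1 <- dz$y %*% params[[paste0(h, ".W1")]]
    a1 <- a1 + rep(params[[paste0(h, ".b1")]], each = bsz)
    a1r <- pmax(a1, 0)
    ad <- dropout_forward(a1r, cfg$dropout$head, drop_on)
    logits <- ad$y %*% params[[paste0(h, ".W2")]]
    logits <- logits + rep(params[[paste0(h, ".b2")]], each = bsz)
    heads[[h]] <- softmax_rows(logits)
    hcache[[h]] <- list(a1r = a1r, ad = ad)
  }
  list(
    probs = heads, state = state,
    cache = list(g1 = g1, g2 = g2, dg = dg, c1 = c1, b1 = b1, r1 = r1,
                 p1 = p1, c2 = c2, b2 = b2, r2 = r2, p2 = p2,
                 flat_cols = t2 * ncol(p2$y), z = dz, heads = hcache,
                 bsz = bsz, ncol_p2 = ncol(p2$y), t2 = t2)
  )
}

nn_loss <- function(probs, y, params, cfg) {
  ce <- 0
  for (h in names(y)) {
    p <- pmax(probs[[h]], 1e-12)
    ce <- ce - sum(y[[h]] * log(p)) / nrow(y[[h]])
  }
  reg <- 0
  if (cfg$l1 > 0 || cfg$l2 > 0) {
    for (nm in names(params)) {
      if (is_weight_param(nm)) {
        reg <- reg + cfg$l2 * sum(params[[nm]]^2) +
          cfg$l1 * sum(abs(params[[nm]]))
      }
    }
  }
  ce + reg
}

nn_backward <- function(probs, y, cache, params, cfg) {
  g <- list()
  bsz <- cache$bsz
  dz <- NULL
  for (h in c("nerve", "side", "position")) {
    dlog <- (probs[[h]] - y[[h]]) / bsz
    hc <- cache$heads[[h]]
    g[[paste0(h, ".W2")]] <- crossprod(hc$ad$y, dlog)
    g[[paste0(h, ".b2")]] <- colSums(dlog)
    dad <- dlog %*% t(params[[paste0(h, ".W2")]])
    da1 <- dropout_backward(dad, hc$ad$mask) * (hc$a1r > 0)
    g[[paste0(h, ".W1")]] <- crossprod(cache$z$y, da1)
    g[[paste0(h, ".b1")]] <- colSums(da1)
    dzh <- da1 %*% t(params[[paste0(h, ".W1")]])
    dz <- if (is.null(dz)) dzh else dz + dzh
  }
  dz <- dropout_backward(dz, cache$z$mask)
  dflat <- dz[, seq_len(cache$flat_cols), drop = FALSE]
  dim(dflat) <- c(bsz * cache$t2, cache$ncol_p2)
  dr2 <- pool_backward(dflat, cache$p2$cache)
  db2 <- bn_backward(dr2 * (cache$r2 > 0), cache$b2$cache, params$bn2.gamma)
  g$bn2.gamma <- db2$dgamma; g$bn2.beta <- db2$dbeta
  dc2 <- conv_backward(db2$dx, cache$c2$cache, params$conv2.W)
  g$conv2.W <- dc2$dw; g$conv2.b <- dc2$db
  dp1 <- pool_backward(dc2$dx, cache$p1$cache)
  db1 <- bn_backward(dp1 * (cache$r1 > 0), cache$b1$cache, params$bn1.gamma)
  g$bn1.gamma <- db1$dgamma; g$bn1.beta <- db1$dbeta
  dc1 <- conv_backward(db1$dx, cache$c1$cache, params$conv1.W)
  g$conv1.W <- dc1$dw; g$conv1.b <- dc1$db
  ddg <- dropout_backward(dc1$dx, cache$dg$mask)
  g2b <- gru_backward(ddg, cache$g2$cache, params$gru2.W, params$gru2.Uzr,
                      params$gru2.Un)
  g$gru2.W <- g2b$dw; g$gru2.Uzr <- g2b$duzr; g$gru2.Un <- g2b$dun
  g$gru2.b <- as.vector(g2b$db)
  g1b <- gru_backward(g2b$dx_stack, cache$g1$cache, params$gru1.W,
                      params$gru1.Uzr, params$gru1.Un)
  g$gru1.W <- g1b$dw; g$gru1.Uzr <- g1b$duzr; g$gru1.Un <- g1b$dun
  g$gru1.b <- as.vector(g1b$db)
  if (cfg$l1 > 0 || cfg$l2 > 0) {
    for (nm in names(g)) {
      if (is_weight_param(nm)) {
        g[[nm]] <- g[[nm]] + 2 * cfg$l2 * params[[nm]] +
          cfg$l1 * sign(params[[nm]])
      }
    }
  }
  g
}

# chunked inference: bounds the im2col working set on large inputs; exact
# for "infer"/"mc" modes because batch norm uses its running statistics
nn_forward_chunked <- function(params, state, x_seq, x_ctx, cfg,
                               mode = "infer", chunk = 1024L) {
  n <- nrow(x_seq)
  if (n <= chunk) {
    return(nn_forward(params, state, x_seq, x_ctx, cfg, mode)$probs)
  }
  starts <- seq(1L, n, by = chunk)
  parts <- lapply(starts, function(s) {
    rows <- s:min(s + chunk - 1L, n)
    nn_forward(params, state, x_seq[rows, , drop = FALSE],
               x_ctx[rows, , drop = FALSE], cfg, mode)$probs
  })
  heads <- names(parts[[1]])
  out <- lapply(heads, function(h) do.call(rbind, lapply(parts, `[[`, h)))
  names(out) <- heads
  out
}

# Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gnm
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
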