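# Residual CNN + fusion ANN: parameter containers, forward/backward passes and
# the Adam optimizer. Convolutions run in compiled code (src/conv.cpp); dense
# layers, pooling and activations are plain matrix algebra. Everything here is
# deterministic given the initialization seed and the data order.

relu <- function(x) x * (x > 0)

# Stage layout of the backbone by nominal depth. Depth counts weighted layers:
# the stem convolution + two convolutions per residual block + the final fully
# connected feature layer, i.e. depth = 2 + 2 * sum(blocks). The 34-layer
# configuration mirrors the classic four-stage (3,4,6,3) residual network.
backbone_presets <- function() {
  list(
    `34` = list(blocks = c(3, 4, 6, 3), channels = c(64, 128, 256, 512)),
    `18` = list(blocks = c(2, 2, 2, 2), channels = c(64, 128, 256, 512)),
    `10` = list(blocks = c(1, 1, 1, 1), channels = c(16, 32, 64, 128)),
    `6`  = list(blocks = c(1, 1), channels = c(8, 16))
  )
}

# Flat description of the backbone graph: stem + a list of residual blocks
# with their strides, channel counts and whether a 1x1 projection shortcut is
# needed (channel change or spatial downsampling).
arch_spec <- function(config) {
  preset <- backbone_presets()[[as.character(config$backbone_depth)]]
  if (is.null(preset)) {
    stop("backbone_depth must be one of 6, 10, 18, 34", call. = FALSE)
  }
  blocks <- list()
  in_ch <- preset$channels[1]
  for (s in seq_along(preset$blocks)) {
    out_ch <- preset$channels[s]
    for (b in seq_len(preset$blocks[s])) {
      stride <- if (b == 1 && s > 1) 2L else 1L
      blocks[[length(blocks) + 1L]] <- list(
        id = sprintf("s%db%d", s, b), stride = stride,
        in_ch = in_ch, out_ch = out_ch,
        proj = (stride != 1L || in_ch != out_ch))
      in_ch <- out_ch
    }
  }
  list(stem_ch = preset$channels[1], blocks = blocks, final_ch = in_ch)
}

he_init <- function(dims, fan_in, scale = 1) {
  array(rnorm(prod(dims), 0, scale * sqrt(2 / fan_in)), dim = dims)
}

# Allocate and initialize all parameters as a flat named list of arrays.
nn_init_params <- function(config) {
  spec <- arch_spec(config)
  with_local_seed(config$seed, {
    p <- list()
    p[["conv1.w"]] <- he_init(c(3, 3, 1, spec$stem_ch), 9)
    p[["conv1.b"]] <- numeric(spec$stem_ch)
    for (blk in spec$blocks) {
      p[[paste0(blk$id, ".wa")]] <- he_init(c(3, 3, blk$in_ch, blk$out_ch),
                                            9 * blk$in_ch)
      p[[paste0(blk$id, ".ba")]] <- numeric(blk$out_ch)
      p[[paste0(blk$id, ".wb")]] <- he_init(c(3, 3, blk$out_ch, blk$out_ch),
                                            9 * blk$out_ch)
      p[[paste0(blk$id, ".bb")]] <- numeric(blk$out_ch)
      if (blk$proj) {
        p[[paste0(blk$id, ".wp")]] <- he_init(c(1, 1, blk$in_ch, blk$out_ch),
                                              blk$in_ch)
        p[[paste0(blk$id, ".bp")]] <- numeric(blk$out_ch)
      }
    }
    p[["feat.w"]] <- matrix(rnorm(config$feature_dim * spec$final_ch,
                                  0, sqrt(2 / spec$final_ch)),
                            config$feature_dim, spec$final_ch)
    p[["feat.b"]] <- numeric(config$feature_dim)
    h <- config$fusion_hidden
    fin <- config$feature_dim + 4L
    p[["fc1.w"]] <- matrix(rnorm(h * fin, 0, sqrt(2 / fin)), h, fin)
    p[["fc1.b"]] <- numeric(h)
    p[["fc2.w"]] <- matrix(rnorm(h * h, 0, sqrt(2 / h)), h, h)
    p[["fc2.b"]] <- numeric(h)
    p[["fc3.w"]] <- matrix(rnorm(h * h, 0, sqrt(2 / h)), h, h)
    p[["fc3.b"]] <- numeric(h)
    p[["out.w"]] <- matrix(rnorm(16 * h, 0, 0.1 * sqrt(2 / h)), 16, h)
    p[["out.b"]] <- numeric(16)
    p
  })
}

# Forward pass over a batch.
#   x:   (H, W, 1, N) image array
#   cov: 4 x N matrix of normalized [age, sex, bmi, rr]
# Returns probs (16 x N) and, when keep_cache, the activations backward needs.
nn_forward <- function(params, config, x, cov, keep_cache = FALSE) {
  spec <- arch_spec(config)
  cache <- if (keep_cache) new.env(parent = emptyenv()) else NULL
  put <- function(key, val) if (keep_cache) assign(key, val, envir = cache)

  put("x", x)
  a_pre <- conv2d_fwd(x, params[["conv1.w"]], params[["conv1.b"]], 2L, 1L)
  put("conv1.pre", a_pre)
  a <- relu(a_pre)
  for (blk in spec$blocks) {
    id <- blk$id
    put(paste0(id, ".in"), a)
    h1_pre <- conv2d_fwd(a, params[[paste0(id, ".wa")]],
                         params[[paste0(id, ".ba")]], blk$stride, 1L)
    put(paste0(id, ".h1pre"), h1_pre)
    h1 <- relu(h1_pre)
    put(paste0(id, ".h1"), h1)
    h2 <- conv2d_fwd(h1, params[[paste0(id, ".wb")]],
                     params[[paste0(id, ".bb")]], 1L, 1L)
    sc <- if (blk$proj) {
      conv2d_fwd(a, params[[paste0(id, ".wp")]],
                 params[[paste0(id, ".bp")]], blk$stride, 0L)
    } else a
    y_pre <- h2 + sc
    put(paste0(id, ".ypre"), y_pre)
    a <- relu(y_pre)
  }
  dd <- dim(a)
  gap <- matrix(colMeans(matrix(a, dd[1] * dd[2], dd[3] * dd[4])), dd[3], dd[4])
  put("gap.dim", dd)
  put("gap", gap)
  feat <- params[["feat.w"]] %*% gap + params[["feat.b"]]
  z <- rbind(cov, feat)
  put("z", z)
  a1_pre <- params[["fc1.w"]] %*% z + params[["fc1.b"]]
  a1 <- relu(a1_pre); put("a1pre", a1_pre); put("a1", a1)
  a2_pre <- params[["fc2.w"]] %*% a1 + params[["fc2.b"]]
  a2 <- relu(a2_pre); put("a2pre", a2_pre); put("a2", a2)
  a3_pre <- params[["fc3.w"]] %*% a2 + params[["fc3.b"]]
  a3 <- relu(a3_pre); put("a3pre", a3_pre); put("a3", a3)
  logits <- params[["out.w"]] %*% a3 + params[["out.b"]]
  put("logits", logits)
  list(probs = 1 / (1 + exp(-logits)), feat = feat, cache = cache)
}

# Mean per-bit binary cross-entropy (numerically stable, from logits).
bce_loss <- function(logits, targets) {
  mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
}

# Backward pass; returns gradients as a flat named list matching params.
nn_backward <- function(params, config, fwd, targets) {
  spec <- arch_spec(config)
  cache <- fwd$cache
  g <- list()
  n_out <- length(targets)
  dlogits <- (fwd$probs - targets) / n_out

  a3 <- get("a3", cache)
  g[["out.w"]] <- dlogits %*% t(a3)
  g[["out.b"]] <- rowSums(dlogits)
  da3 <- t(params[["out.w"]]) %*% dlogits
  da3 <- da3 * (get("a3pre", cache) > 0)
  a2 <- get("a2", cache)
  g[["fc3.w"]] <- da3 %*% t(a2)
  g[["fc3.b"]] <- rowSums(da3)
  da2 <- t(params[["fc3.w"]]) %*% da3
  da2 <- da2 * (get("a2pre", cache) > 0)
  a1 <- get("a1", cache)
  g[["fc2.w"]] <- da2 %*% t(a1)
  g[["fc2.b"]] <- rowSums(da2)
  da1 <- t(params[["fc2.w"]]) %*% da2
  da1 <- da1 * (get("a1pre", cache) > 0)
  z <- get("z", cache)
  g[["fc1.w"]] <- da1 %*% t(z)
  g[["fc1.b"]] <- rowSums(da1)
  dz <- t(params[["fc1.w"]]) %*% da1
  dfeat <- dz[-(1:4), , drop = FALSE]

  gap <- get("gap", cache)
  g[["feat.w"]] <- dfeat %*% t(gap)
  g[["feat.b"]] <- rowSums(dfeat)
  dgap <- t(params[["feat.w"]]) %*% dfeat
  dd <- get("gap.dim", cache)
  da <- array(rep(as.numeric(dgap), each = dd[1] * dd[2]) / (dd[1] * dd[2]),
              dim = dd)

  for (blk in rev(spec$blocks)) {
    id <- blk$id
    dy_pre <- da * (get(paste0(id, ".ypre"), cache) > 0)
    h1 <- get(paste0(id, ".h1"), cache)
    bw_b <- conv2d_bwd(h1, params[[paste0(id, ".wb")]], dy_pre, 1L, 1L)
    g[[paste0(id, ".wb")]] <- bw_b$dw
    g[[paste0(id, ".bb")]] <- bw_b$db
    dh1 <- bw_b$dx * (get(paste0(id, ".h1pre"), cache) > 0)
    a_in <- get(paste0(id, ".in"), cache)
    bw_a <- conv2d_bwd(a_in, params[[paste0(id, ".wa")]], dh1, blk$stride, 1L)
    g[[paste0(id, ".wa")]] <- bw_a$dw
    g[[paste0(id, ".ba")]] <- bw_a$db
    da_in <- bw_a$dx
    if (blk$proj) {
      bw_p <- conv2d_bwd(a_in, params[[paste0(id, ".wp")]], dy_pre,
                         blk$stride, 0L)
      g[[paste0(id, ".wp")]] <- bw_p$dw
      g[[paste0(id, ".bp")]] <- bw_p$db
      da_in <- da_in + bw_p$dx
    } else {
      da_in <- da_in + dy_pre
    }
    da <- da_in
  }
  da <- da * (get("conv1.pre", cache) > 0)
  bw1 <- conv2d_bwd(get("x", cache), params[["conv1.w"]], da, 2L, 1L)
  g[["conv1.w"]] <- bw1$dw
  g[["conv1.b"]] <- bw1$db
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
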