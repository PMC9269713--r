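# Minimal CNN forward engine.
#
# Feature maps are stored as a list(H, W, C, M) where M is an (H*W) x C
# matrix, column-major with the row index fastest (matching R matrices).
# Convolutions are evaluated as a sum over kernel offsets of gathered-row
# matrix products, which turns every layer into dense BLAS work. Only the
# pieces the three classic architectures need are implemented: convolution
# (with channel groups), ReLU, cross-channel local response normalization,
# max pooling (with ceil-mode output sizing), global average pooling and
# fully-connected layers.

conv_out_size <- function(H, k, s, p, ceil = FALSE) {
  v <- (H + 2 * p - k) / s
  (if (ceil) ceiling(v) else floor(v)) + 1L
}

# Gather index for kernel offset (di, dj): maps each output pixel to a row of
# the input matrix, or to the sentinel row N+1 for out-of-bounds taps.
gather_idx <- function(H, W, Hout, Wout, di, dj, s, p) {
  ii <- (seq_len(Hout) - 1L) * s + di - p
  jj <- (seq_len(Wout) - 1L) * s + dj - p
  ii[ii < 1L | ii > H] <- NA
  jj[jj < 1L | jj > W] <- NA
  lin <- outer(ii, jj, function(a, b) a + (b - 1L) * H)
  lin[is.na(lin)] <- H * W + 1L
  as.vector(lin)
}

fm_from_image <- function(img) {
  d <- dim(img)
  M <- matrix(img, d[[1]] * d[[2]], d[[3]])
  list(H = d[[1]], W = d[[2]], C = d[[3]], M = M)
}

conv_forward <- function(fm, ly, w) {
  k <- ly$k; s <- ly$stride; p <- ly$pad; g <- ly$groups
  Hout <- conv_out_size(fm$H, k, s, p); Wout <- conv_out_size(fm$W, k, s, p)
  cin_g <- ly$cin %/% g; cout_g <- ly$cout %/% g
  Mz <- rbind(fm$M, 0)
  out <- matrix(0, Hout * Wout, ly$cout)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      idx <- gather_idx(fm$H, fm$W, Hout, Wout, di, dj, s, p)
      for (gi in seq_len(g)) {
        cin_rng <- (gi - 1L) * cin_g + seq_len(cin_g)
        cout_rng <- (gi - 1L) * cout_g + seq_len(cout_g)
        Wmat <- matrix(w$W[di, dj, , cout_rng], cin_g, cout_g)
        out[, cout_rng] <- out[, cout_rng] + Mz[idx, cin_rng, drop = FALSE] %*% Wmat
      }
    }
  }
  out <- sweep(out, 2L, w$b, "+")
  list(H = Hout, W = Wout, C = ly$cout, M = out)
}

maxpool_forward <- function(fm, ly) {
  k <- ly$k; s <- ly$stride; p <- ly$pad %||% 0L; ceil <- isTRUE(ly$ceil)
  Hout <- conv_out_size(fm$H, k, s, p, ceil); Wout <- conv_out_size(fm$W, k, s, p, ceil)
  Mz <- rbind(fm$M, -Inf)
  out <- matrix(-Inf, Hout * Wout, fm$C)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      idx <- gather_idx(fm$H, fm$W, Hout, Wout, di, dj, s, p)
      out <- pmax(out, Mz[idx, , drop = FALSE])
    }
  }
  list(H = Hout, W = Wout, C = fm$C, M = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Krizhevsky-style cross-channel LRN: k = 2, n = 5, alpha = 1e-4, beta = 0.75.
lrn_forward <- function(fm) {
  C <- fm$C
  band <- outer(seq_len(C), seq_len(C), function(a, b) abs(a - b) <= 2) * 1
  wsum <- (fm$M^2) %*% band
  fm$M <- fm$M / (2 + (1e-4 / 5) * wsum)^0.75
  fm
}

relu_forward <- function(fm) { fm$M <- pmax(fm$M, 0); fm }

inception_forward <- function(fm, ly, w) {
  cv <- function(x, k, cin, cout, pad, wi) {
    conv_forward(x, list(k = k, cin = cin, cout = cout, stride = 1L, pad = pad, groups = 1L), wi)
  }
  cfg <- ly$cfg
  b1 <- relu_forward(cv(fm, 1L, cfg$cin, cfg$c1, 0L, w$b1))
  b2 <- relu_forward(cv(fm, 1L, cfg$cin, cfg$r3, 0L, w$b2a))
  b2 <- relu_forward(cv(b2, 3L, cfg$r3, cfg$c3, 1L, w$b2b))
  b3 <- relu_forward(cv(fm, 1L, cfg$cin, cfg$r5, 0L, w$b3a))
  b3 <- relu_forward(cv(b3, 5L, cfg$r5, cfg$c5, 2L, w$b3b))
  b4 <- maxpool_forward(fm, list(k = 3L, stride = 1L, pad = 1L))
  b4 <- relu_forward(cv(b4, 1L, cfg$cin, cfg$cp, 0L, w$b4))
  list(H = b1$H, W = b1$W, C = cfg$c1 + cfg$c3 + cfg$c5 + cfg$cp,
       M = cbind(b1$M, b2$M, b3$M, b4$M))
}

# ---- architecture tables -------------------------------------------------

conv_ly <- function(k, cin, cout, stride = 1L, pad = 0L, groups = 1L) {
  list(type = "conv", k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), pad = as.integer(pad), groups = as.integer(groups))
}
pool_ly <- function(k, stride, pad = 0L, ceil = FALSE) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), ceil = ceil)
}
fc_ly <- function(nin, nout) list(type = "fc", nin = as.integer(nin), nout = as.integer(nout))
incep_ly <- function(cin, c1, r3, c3, r5, c5, cp) {
  list(type = "inception",
       cfg = list(cin = cin, c1 = c1, r3 = r3, c3 = c3, r5 = r5, c5 = c5, cp = cp))
}

# Original 2012 architecture with grouped convolutions on layers 2, 4 and 5;
# feature tap = the last fully-connected hidden layer (4096-wide), the
# classifier head (4096 -> 1000) contributes to the parameter count only.
alexnet_arch <- function() {
  layers <- list(
    conv_ly(11, 3, 96, stride = 4), list(type = "relu"), list(type = "lrn"),
    pool_ly(3, 2),
    conv_ly(5, 96, 256, pad = 2, groups = 2), list(type = "relu"), list(type = "lrn"),
    pool_ly(3, 2),
    conv_ly(3, 256, 384, pad = 1), list(type = "relu"),
    conv_ly(3, 384, 384, pad = 1, groups = 2), list(type = "relu"),
    conv_ly(3, 384, 256, pad = 1, groups = 2), list(type = "relu"),
    pool_ly(3, 2),
    list(type = "flatten"),
    fc_ly(9216, 4096), list(type = "relu"),
    fc_ly(4096, 4096),                       # feature tap
    fc_ly(4096, 1000)                        # head, parameters only
  )
  list(name = "alexnet", input_side = 227L, feature_dim = 4096L,
       layers = layers, tap_after = length(layers) - 1L)
}

vgg16_arch <- function() {
  chans <- list(c(3, 64), c(64, 64), "M", c(64, 128), c(128, 128), "M",
                c(128, 256), c(256, 256), c(256, 256), "M",
                c(256, 512), c(512, 512), c(512, 512), "M",
                c(512, 512), c(512, 512), c(512, 512), "M")
  layers <- list()
  for (e in chans) {
    if (identical(e, "M")) layers[[length(layers) + 1L]] <- pool_ly(2, 2)
    else {
      layers[[length(layers) + 1L]] <- conv_ly(3, e[[1]], e[[2]], pad = 1)
      layers[[length(layers) + 1L]] <- list(type = "relu")
    }
  }
  layers <- c(layers, list(list(type = "flatten"),
                           fc_ly(25088, 4096), list(type = "relu"),
                           fc_ly(4096, 4096),  # feature tap
                           fc_ly(4096, 1000)))
  list(name = "vgg16", input_side = 224L, feature_dim = 4096L,
       layers = layers, tap_after = length(layers) - 1L)
}

# Inception-v1 main branch (auxiliary classifiers omitted); feature tap = the
# 1024-wide global-average-pool output, forced by the printed feature count.
googlenet_arch <- function() {
  layers <- list(
    conv_ly(7, 3, 64, stride = 2, pad = 3), list(type = "relu"),
    pool_ly(3, 2, ceil = TRUE), list(type = "lrn"),
    conv_ly(1, 64, 64), list(type = "relu"),
    conv_ly(3, 64, 192, pad = 1), list(type = "relu"), list(type = "lrn"),
    pool_ly(3, 2, ceil = TRUE),
    incep_ly(192, 64, 96, 128, 16, 32, 32),     # 3a -> 256
    incep_ly(256, 128, 128, 192, 32, 96, 64),   # 3b -> 480
    pool_ly(3, 2, ceil = TRUE),
    incep_ly(480, 192, 96, 208, 16, 48, 64),    # 4a -> 512
    incep_ly(512, 160, 112, 224, 24, 64, 64),   # 4b -> 512
    incep_ly(512, 128, 128, 256, 24, 64, 64),   # 4c -> 512
    incep_ly(512, 112, 144, 288, 32, 64, 64),   # 4d -> 528
    incep_ly(528, 256, 160, 320, 32, 128, 128), # 4e -> 832
    pool_ly(3, 2, ceil = TRUE),
    incep_ly(832, 256, 160, 320, 32, 128, 128), # 5a -> 832
    incep_ly(832, 384, 192, 384, 48, 128, 128), # 5b -> 1024
    list(type = "avgpool_global"),               # feature tap
    fc_ly(1024, 1000)                            # head, parameters only
  )
  list(name = "googlenet", input_side = 224L, feature_dim = 1024L,
       layers = layers, tap_after = length(layers) - 1L)
}

cnn_architecture <- function(name) {
  switch(name,
         alexnet = alexnet_arch(),
         vgg16 = vgg16_arch(),
         googlenet = googlenet_arch(),
         stopf("no architecture table for backbone '%s'", name))
}

conv_params <- function(k, cin, cout, groups = 1L) k * k * (cin %/% groups) * cout + cout

layer_param_count <- function(ly) {
  switch(ly$type,
         conv = conv_params(ly$k, ly$cin, ly$cout, ly$groups),
         fc = ly$nin * ly$nout + ly$nout,
         inception = {
           cfg <- ly$cfg
           conv_params(1, cfg$cin, cfg$c1) + conv_params(1, cfg$cin, cfg$r3) +
             conv_params(3, cfg$r3, cfg$c3) + conv_params(1, cfg$cin, cfg$r5) +
             conv_params(5, cfg$r5, cfg$c5) + conv_params(1, cfg$cin, cfg$cp)
         },
         0)
}

cnn_param_count <- function(arch) sum(vapply(arch$layers, layer_param_count, numeric(1)))

# Seeded He-normal weights; one RNG stream per call so the full weight set is
# a deterministic function of the seed.
cnn_init_weights <- function(arch, seed = 0) {
  he_conv <- function(k, cin_g, cout) {
    list(W = array(stats::rnorm(k * k * cin_g * cout, sd = sqrt(2 / (k * k * cin_g))),
                   dim = c(k, k, cin_g, cout)),
         b = numeric(cout))
  }
  init_layer <- function(ly) {
    switch(ly$type,
           conv = he_conv(ly$k, ly$cin %/% ly$groups, ly$cout),
           fc = list(W = matrix(stats::rnorm(ly$nin * ly$nout, sd = sqrt(2 / ly$nin)),
                                ly$nin, ly$nout),
                     b = numeric(ly$nout)),
           inception = {
             cfg <- ly$cfg
             list(b1 = he_conv(1L, cfg$cin, cfg$c1),
                  b2a = he_conv(1L, cfg$cin, cfg$r3), b2b = he_conv(3L, cfg$r3, cfg$c3),
                  b3a = he_conv(1L, cfg$cin, cfg$r5), b3b = he_conv(5L, cfg$r5, cfg$c5),
                  b4 = he_conv(1L, cfg$cin, cfg$cp))
           },
           NULL)
  }
  with_seed(seed, lapply(arch$layers, init_layer))
}

# Run the network up to its feature tap; returns the feature vector.
cnn_forward <- function(arch, weights, img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L || d[[1]] != arch$input_side || d[[2]] != arch$input_side)
    stopf("backbone '%s' expects a %dx%dx3 input image", arch$name,
          arch$input_side, arch$input_side)
  fm <- fm_from_image(img)
  vec <- NULL
  for (i in seq_len(arch$tap_after)) {
    ly <- arch$layers[[i]]
    if (ly$type == "flatten") { vec <- as.vector(fm$M); next }
    if (!is.null(vec)) {
      vec <- switch(ly$type,
                    fc = as.vector(vec %*% weights[[i]]$W + weights[[i]]$b),
                    relu = pmax(vec, 0),
                    stopf("unsupported layer after flatten: %s", ly$type))
      next
    }
    fm <- switch(ly$type,
                 conv = conv_forward(fm, ly, weights[[i]]),
                 relu = relu_forward(fm),
                 lrn = lrn_forward(fm),
                 maxpool = maxpool_forward(fm, ly),
                 inception = inception_forward(fm, ly, weights[[i]]),
                 avgpool_global = { vec <- colMeans(fm$M); fm },
                 stopf("unknown layer type '%s'", ly$type))
  }
  if (is.null(vec)) stopf("architecture '%s' has no feature tap", arch$name)
  vec
}
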