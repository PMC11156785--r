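# Compact convolutional U-Net with hand-written backpropagation.
#
# Feature maps are H x W x C arrays. Convolutions are 3x3, zero-padded
# ("same"), realised as im2col patch matrices multiplied by a
# (Cin*9) x Cout weight matrix so the heavy lifting is a BLAS gemm.

# ---- layer primitives -------------------------------------------------

# im2col gather indices for a given padded shape, memoized: for each of the
# nine 3x3 offsets, the linear indices into the zero-padded volume that form
# one column block of the patch matrix.
.conv_idx_cache <- new.env(parent = emptyenv())

.conv3_idx <- function(H, Wd, Cin) {
  key <- sprintf("%d_%d_%d", H, Wd, Cin)
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- Wd + 2L
  base_i <- rep.int(seq_len(H), Wd)
  base_j <- rep(seq_len(Wd), each = H)
  plane <- Hp * Wp
  chan <- rep((seq_len(Cin) - 1L) * plane, each = H * Wd)
  idx <- vector("list", 9)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    lin <- (base_i + di) + (base_j + dj - 1L) * Hp
    idx[[k]] <- rep.int(lin, Cin) + chan
  }
  .conv_idx_cache[[key]] <- idx
  idx
}

.conv3_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  xp <- array(0, dim = c(H + 2, Wd + 2, Cin))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  idx <- .conv3_idx(H, Wd, Cin)
  P <- matrix(0, H * Wd, Cin * 9)
  for (k in 1:9)
    P[, ((k - 1) * Cin + 1):(k * Cin)] <- xp[idx[[k]]]
  y <- P %*% W + rep(b, each = H * Wd)
  list(y = array(y, dim = c(H, Wd, ncol(W))), P = P)
}

.conv3_bwd <- function(dy, P, W, xdim) {
  H <- xdim[1]; Wd <- xdim[2]; Cin <- xdim[3]
  dY <- matrix(dy, H * Wd, dim(W)[2])
  dW <- crossprod(P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, W)   # (H*W) x (Cin*9)
  idx <- .conv3_idx(H, Wd, Cin)
  dxp <- numeric((H + 2) * (Wd + 2) * Cin)
  for (k in 1:9) {
    i <- idx[[k]]
    dxp[i] <- dxp[i] + dP[, ((k - 1) * Cin + 1):(k * Cin)]
  }
  dxp <- array(dxp, dim = c(H + 2, Wd + 2, Cin))
  list(dx = dxp[2:(H + 1), 2:(Wd + 1), , drop = FALSE], dW = dW, db = db)
}

.relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

.relu_bwd <- function(dy, x) {
  dy * (x > 0)
}

.pool2_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  a <- x[io, jo, , drop = FALSE]; b <- x[io + 1, jo, , drop = FALSE]
  cc <- x[io, jo + 1, , drop = FALSE]; dd <- x[io + 1, jo + 1, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  arg <- 1L * (y == a)
  arg[arg == 0 & y == b] <- 2L
  arg[arg == 0 & y == cc] <- 3L
  arg[arg == 0 & y == dd] <- 4L
  list(y = y, arg = arg)
}

.pool2_bwd <- function(dy, arg, xdim) {
  dx <- array(0, dim = xdim)
  H2 <- dim(dy)[1]; W2 <- dim(dy)[2]
  io <- seq(1, xdim[1], 2); jo <- seq(1, xdim[2], 2)
  for (q in 1:4) {
    sel <- (arg == q) * dy
    di <- (q - 1) %% 2; dj <- (q - 1) %/% 2
    dx[io + di, jo + dj, ] <- dx[io + di, jo + dj, , drop = FALSE] + sel
  }
  dx
}

.upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

.upsample2_bwd <- function(dy) {
  d <- dim(dy); H2 <- d[1] / 2; W2 <- d[2] / 2
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  dy[io, jo, , drop = FALSE] + dy[io + 1, jo, , drop = FALSE] +
    dy[io, jo + 1, , drop = FALSE] + dy[io + 1, jo + 1, , drop = FALSE]
}

# ---- architecture -----------------------------------------------------

#' U-Net architecture specification
#'
#' A symmetric encoder-decoder with skip connections: at every level two
#' 3x3 convolutions with ReLU; 2x2 max-pooling between encoder levels;
#' nearest-neighbour upsampling followed by a 3x3 convolution in the
#' decoder, with the matching encoder feature map concatenated. A final
#' 1x1 convolution maps to one output channel. Channel count doubles per
#' level starting at `base_channels`.
#'
#' @param in_channels Input channels — the number of repetition images
#'   (default 12).
#' @param depth Number of resolution levels (the input must be divisible
#'   by `2^(depth-1)`).
#' @param base_channels Channels at the first level.
#' @return Object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels = 12, depth = 3, base_channels = 16) {
  stopifnot(in_channels >= 1, depth >= 2, base_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 out_channels = 1L),
            class = "unet_spec")
}

# He-style initialisation; weights as (Cin*9) x Cout matrices
.conv_init <- function(cin, cout, ksize = 3) {
  fan_in <- cin * ksize * ksize
  list(W = matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                  fan_in, cout),
       b = rep(0, cout))
}

#' Initialise U-Net parameters
#'
#' @param spec A [unet_spec()].
#' @param seed Optional integer seed for the weight draw.
#' @return Named list of conv-layer parameter pairs (`W`, `b`), ordered
#'   encoder, decoder, output head.
#' @export
unet_init <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  D <- spec$depth; B <- spec$base_channels
  ch <- B * 2^(seq_len(D) - 1)
  p <- list()
  cin <- spec$in_channels
  for (l in seq_len(D)) {
    p[[sprintf("enc%d_1", l)]] <- .conv_init(cin, ch[l])
    p[[sprintf("enc%d_2", l)]] <- .conv_init(ch[l], ch[l])
    cin <- ch[l]
  }
  for (l in rev(seq_len(D - 1))) {
    p[[sprintf("up%d", l)]] <- .conv_init(ch[l + 1], ch[l])
    p[[sprintf("dec%d_1", l)]] <- .conv_init(2 * ch[l], ch[l])
    p[[sprintf("dec%d_2", l)]] <- .conv_init(ch[l], ch[l])
  }
  p[["out"]] <- list(W = matrix(stats::rnorm(ch[1], 0, sqrt(2 / ch[1])),
                                ch[1], 1),
                     b = 0)
  attr(p, "spec") <- spec
  p
}

#' Number of trainable parameters
#' @param params Output of [unet_init()].
#' @return Integer count.
#' @export
unet_n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' U-Net forward pass
#'
#' @param params Parameters from [unet_init()].
#' @param x H x W x C input array (C = `in_channels`); H and W must be
#'   divisible by `2^(depth-1)`.
#' @param training Keep the caches needed for [unet_backward()]?
#' @return List with `out` (H x W matrix, linear activation) and, when
#'   `training`, `cache`.
#' @export
unet_forward <- function(params, x, training = FALSE) {
  spec <- attr(params, "spec")
  D <- spec$depth
  d <- dim(x)
  if (length(d) != 3 || d[3] != spec$in_channels)
    stop(sprintf("input must be H x W x %d", spec$in_channels),
         call. = FALSE)
  if (d[1] %% 2^(D - 1) != 0 || d[2] %% 2^(D - 1) != 0)
    stop(sprintf("image size must be divisible by %d for depth %d",
                 2^(D - 1), D), call. = FALSE)
  cache <- list()
  skips <- list()
  h <- x
  for (l in seq_len(D)) {
    c1 <- .conv3_fwd(h, params[[sprintf("enc%d_1", l)]]$W,
                     params[[sprintf("enc%d_1", l)]]$b)
    a1 <- .relu_fwd(c1$y)
    c2 <- .conv3_fwd(a1, params[[sprintf("enc%d_2", l)]]$W,
                     params[[sprintf("enc%d_2", l)]]$b)
    a2 <- .relu_fwd(c2$y)
    if (training) cache[[sprintf("enc%d", l)]] <-
      list(xdim = dim(h), P1 = c1$P, z1 = c1$y, a1dim = dim(a1),
           P2 = c2$P, z2 = c2$y)
    skips[[l]] <- a2
    if (l < D) {
      pl <- .pool2_fwd(a2)
      if (training) cache[[sprintf("pool%d", l)]] <-
        list(arg = pl$arg, xdim = dim(a2))
      h <- pl$y
    } else h <- a2
  }
  for (l in rev(seq_len(D - 1))) {
    u <- .upsample2_fwd(h)
    cu <- .conv3_fwd(u, params[[sprintf("up%d", l)]]$W,
                     params[[sprintf("up%d", l)]]$b)
    au <- .relu_fwd(cu$y)
    hcat <- array(c(au, skips[[l]]), dim = c(dim(au)[1], dim(au)[2],
                                             dim(au)[3] + dim(skips[[l]])[3]))
    c1 <- .conv3_fwd(hcat, params[[sprintf("dec%d_1", l)]]$W,
                     params[[sprintf("dec%d_1", l)]]$b)
    a1 <- .relu_fwd(c1$y)
    c2 <- .conv3_fwd(a1, params[[sprintf("dec%d_2", l)]]$W,
                     params[[sprintf("dec%d_2", l)]]$b)
    a2 <- .relu_fwd(c2$y)
    if (training) cache[[sprintf("dec%d", l)]] <-
      list(udim = dim(u), Pu = cu$P, zu = cu$y, hcatdim = dim(hcat),
           P1 = c1$P, z1 = c1$y, a1dim = dim(a1), P2 = c2$P, z2 = c2$y,
           nup = dim(au)[3])
    h <- a2
  }
  # 1x1 output head
  d1 <- dim(h)
  Hm <- matrix(h, d1[1] * d1[2], d1[3])
  o <- Hm %*% params$out$W + params$out$b
  if (training) cache$head <- list(Hm = Hm, hdim = d1)
  list(out = matrix(o, d1[1], d1[2]), cache = if (training) cache else NULL)
}

#' U-Net backward pass
#'
#' @param params Parameters from [unet_init()].
#' @param cache Cache from [unet_forward()] with `training = TRUE`.
#' @param dout H x W gradient of the loss in the network output.
#' @return Gradient structure parallel to `params`.
#' @export
unet_backward <- function(params, cache, dout) {
  spec <- attr(params, "spec")
  D <- spec$depth
  g <- list()
  hd <- cache$head
  dO <- matrix(dout, prod(hd$hdim[1:2]), 1)
  g$out <- list(W = crossprod(hd$Hm, dO), b = sum(dO))
  dh <- array(tcrossprod(dO, params$out$W), dim = hd$hdim)

  dskips <- vector("list", D)
  for (l in seq_len(D - 1)) {
    cc <- cache[[sprintf("dec%d", l)]]
    dz2 <- .relu_bwd(dh, cc$z2)
    b2 <- .conv3_bwd(dz2, cc$P2, params[[sprintf("dec%d_2", l)]]$W,
                     cc$a1dim)
    g[[sprintf("dec%d_2", l)]] <- list(W = b2$dW, b = b2$db)
    dz1 <- .relu_bwd(b2$dx, cc$z1)
    b1 <- .conv3_bwd(dz1, cc$P1, params[[sprintf("dec%d_1", l)]]$W,
                     cc$hcatdim)
    g[[sprintf("dec%d_1", l)]] <- list(W = b1$dW, b = b1$db)
    nup <- cc$nup
    dau <- b1$dx[, , seq_len(nup), drop = FALSE]
    dskips[[l]] <- b1$dx[, , (nup + 1):cc$hcatdim[3], drop = FALSE]
    dzu <- .relu_bwd(dau, cc$zu)
    bu <- .conv3_bwd(dzu, cc$Pu, params[[sprintf("up%d", l)]]$W, cc$udim)
    g[[sprintf("up%d", l)]] <- list(W = bu$dW, b = bu$db)
    dh <- .upsample2_bwd(bu$dx)
  }
  # encoder, bottom-up
  for (l in rev(seq_len(D))) {
    da2 <- if (l == D) dh else {
      pc <- cache[[sprintf("pool%d", l)]]
      .pool2_bwd(dh, pc$arg, pc$xdim) + dskips[[l]]
    }
    cc <- cache[[sprintf("enc%d", l)]]
    dz2 <- .relu_bwd(da2, cc$z2)
    b2 <- .conv3_bwd(dz2, cc$P2, params[[sprintf("enc%d_2", l)]]$W,
                     cc$a1dim)
    g[[sprintf("enc%d_2", l)]] <- list(W = b2$dW, b = b2$db)
    dz1 <- .relu_bwd(b2$dx, cc$z1)
    b1 <- .conv3_bwd(dz1, cc$P1, params[[sprintf("enc%d_1", l)]]$W,
                     cc$xdim)
    g[[sprintf("enc%d_1", l)]] <- list(W = b1$dW, b = b1$db)
    dh <- b1$dx
  }
  g
}

# ---- Adam -------------------------------------------------------------

.adam_init <- function(params) {
  st <- lapply(params, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  attr(st, "t") <- 0L
  st
}

.adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  t <- attr(state, "t") + 1L
  for (nm in names(params)) {
    gW <- grads[[nm]]$W; gb <- grads[[nm]]$b
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * gW
    s$vW <- beta2 * s$vW + (1 - beta2) * gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gb
    s$vb <- beta2 * s$vb + (1 - beta2) * gb^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[nm]] <- s
  }
  attr(state, "t") <- t
  list(params = params, state = state)
}

.grad_accumulate <- function(acc, g, scale = 1) {
  if (is.null(acc))
    return(lapply(g, function(l) list(W = l$W * scale, b = l$b * scale)))
  for (nm in names(g)) {
    acc[[nm]]$W <- acc[[nm]]$W + g[[nm]]$W * scale
    acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b * scale
  }
  acc
}
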