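# Minimal neural-network core.
#
# No deep-learning runtime is assumed: layers are environments holding
# parameter arrays, forward caches and gradients; convolutions and
# transposed convolutions run through C++ im2col/col2im plus BLAS matrix
# products; networks are plain lists of layers walked forwards and
# backwards.  Activations and shapes follow the DCGAN family of
# architectures this package implements.
#
# Array layout is (height, width, channels, batch) throughout; dense
# layers operate on (features x batch) matrices.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

#' Equalized learning-rate scale
#'
#' The runtime weight multiplier `sqrt(2 / fan_in)` of the equalized
#' learning-rate rule, with `fan_in` the number of input channels times
#' the kernel area.  When equalization is enabled, raw weights are kept at
#' unit scale and multiplied by this constant at every forward pass, so
#' all layers see comparable effective gradient magnitudes.
#'
#' @param fan_in Positive integer, input channels x kernel area.
#' @return The scalar `sqrt(2 / fan_in)`.
#' @examples
#' equalized_scale(2)   # 1
#' equalized_scale(8)   # 0.5
#' equalized_scale(50)  # 0.2
#' @export
equalized_scale <- function(fan_in) {
  if (!is.numeric(fan_in) || length(fan_in) != 1L || !is.finite(fan_in) ||
      fan_in < 1)
    stop_hsigan("fan_in must be a number >= 1", "hsigan_value_error")
  sqrt(2 / fan_in)
}

layer_conv <- function(Cin, Cout, k, stride = 1L, pad = 0L,
                       equalized = FALSE, init_sd = 0.02) {
  # `k` may be length 2 (kh, kw) for a rectangular kernel
  kh <- as.integer(k[1]); kw <- as.integer(k[length(k)])
  gain <- if (equalized) equalized_scale(Cin * kh * kw) else 1
  # raw weights are drawn so the *effective* (gain-scaled) weights follow
  # the DCGAN N(0, 0.02) convention at initialization
  new_layer("conv", Cin = Cin, Cout = Cout, kh = kh, kw = kw,
            stride = stride, pad = pad, gain = gain,
            W = array(rnorm(kh * kw * Cin * Cout, 0, init_sd / gain),
                      c(kh, kw, Cin, Cout)),
            b = numeric(Cout), pnames = c("W", "b"), snames = character(0))
}

layer_tconv <- function(Cin, Cout, k, stride = 1L, pad = 0L,
                        equalized = FALSE, init_sd = 0.02) {
  gain <- if (equalized) equalized_scale(Cin * k * k) else 1
  new_layer("tconv", Cin = Cin, Cout = Cout, k = k, stride = stride, pad = pad,
            gain = gain,
            W = array(rnorm(k * k * Cout * Cin, 0, init_sd / gain),
                      c(k, k, Cout, Cin)),
            b = numeric(Cout), pnames = c("W", "b"), snames = character(0))
}

layer_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", C = C, momentum = momentum, eps = eps, nseen = 0,
            gamma = rep(1, C), beta = numeric(C),
            rm = numeric(C), rv = rep(1, C),
            pnames = c("gamma", "beta"), snames = c("rm", "rv", "nseen"))
}

layer_act <- function(fun = c("relu", "lrelu", "tanh", "sigmoid"),
                      slope = 0.2) {
  new_layer("act", fun = match.arg(fun), slope = slope,
            pnames = character(0), snames = character(0))
}

layer_dense <- function(In, Out, equalized = FALSE, init_sd = 0.02) {
  gain <- if (equalized) equalized_scale(In) else 1
  new_layer("dense", In = In, Out = Out, gain = gain,
            W = matrix(rnorm(Out * In, 0, init_sd / gain), Out, In),
            b = numeric(Out), pnames = c("W", "b"), snames = character(0))
}

layer_reshape <- function(dims) # feature matrix -> (h, w, c, n)
  new_layer("reshape", dims = as.integer(dims),
            pnames = character(0), snames = character(0))

layer_flatten <- function()
  new_layer("flatten", pnames = character(0), snames = character(0))

layer_crop <- function(h, w)
  new_layer("crop", h = as.integer(h), w = as.integer(w),
            pnames = character(0), snames = character(0))

layer_gap <- function() # global average pool -> (channels x batch)
  new_layer("gap", pnames = character(0), snames = character(0))

layer_resblock <- function(Cin, Cout, stride = 1L, equalized = FALSE) {
  main <- list(layer_conv(Cin, Cout, 3L, stride, 1L, equalized),
               layer_bn(Cout), layer_act("relu"),
               layer_conv(Cout, Cout, 3L, 1L, 1L, equalized),
               layer_bn(Cout))
  skip <- if (stride != 1L || Cin != Cout)
    list(layer_conv(Cin, Cout, 1L, stride, 0L, equalized), layer_bn(Cout))
  else NULL
  new_layer("resblock", main = main, skip = skip,
            pnames = character(0), snames = character(0))
}

conv_out_size <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L
tconv_out_size <- function(H, k, stride, pad) (H - 1L) * stride - 2L * pad + k

acc_grad <- function(l, name, g) {
  gname <- paste0("g_", name)
  cur <- if (exists(gname, envir = l, inherits = FALSE)) l[[gname]] else NULL
  l[[gname]] <- if (is.null(cur)) g else cur + g
}

byrow_mat <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

layer_forward <- function(l, x, training = FALSE) {
  switch(l$type,
    conv = {
      d <- dim(x)
      if (length(d) != 4L || d[3] != l$Cin)
        stop_dimension(sprintf("conv expects %d input channels, got %s",
                               l$Cin, paste(d, collapse = "x")))
      cols <- cpp_im2col(x, d[1], d[2], d[3], d[4], l$kh, l$kw, l$stride,
                         l$pad)
      Wm <- matrix(l$W, nrow = l$kh * l$kw * l$Cin) * l$gain
      out <- crossprod(Wm, cols) + l$b
      oH <- conv_out_size(d[1], l$kh, l$stride, l$pad)
      oW <- conv_out_size(d[2], l$kw, l$stride, l$pad)
      l$x_dim <- d; l$cols <- cols
      aperm(array(out, c(l$Cout, oH, oW, d[4])), c(2, 3, 1, 4))
    },
    tconv = {
      d <- dim(x)
      if (length(d) != 4L || d[3] != l$Cin)
        stop_dimension(sprintf("tconv expects %d input channels, got %s",
                               l$Cin, paste(d, collapse = "x")))
      xmat <- matrix(aperm(x, c(3, 1, 2, 4)), l$Cin)
      Wm <- matrix(l$W, nrow = l$k * l$k * l$Cout) * l$gain
      cols <- Wm %*% xmat
      oH <- tconv_out_size(d[1], l$k, l$stride, l$pad)
      oW <- tconv_out_size(d[2], l$k, l$stride, l$pad)
      y <- array(cpp_col2im(cols, oH, oW, l$Cout, d[4], l$k, l$k, l$stride,
                            l$pad),
                 c(oH, oW, l$Cout, d[4]))
      l$x_dim <- d; l$xmat <- xmat; l$o_dim <- dim(y)
      y + rep(l$b, each = oH * oW)
    },
    bn = {
      # `training` is tri-state here: TRUE uses batch statistics and
      # updates the running averages, "batch" uses batch statistics
      # without updating them (generation mode), FALSE uses the running
      # averages.
      d <- dim(x)
      xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = l$C)
      n <- nrow(xp)
      if (!identical(training, FALSE)) {
        mu <- colMeans(xp)
        xc <- xp - byrow_mat(mu, n)
        v <- colMeans(xc * xc)
        istd <- 1 / sqrt(v + l$eps)
        xhat <- xc * byrow_mat(istd, n)
        if (isTRUE(training)) {
          # cumulative average until the exponential window takes over,
          # so short runs still leave usable inference statistics
          l$nseen <- l$nseen + 1
          mom <- max(l$momentum, 1 / l$nseen)
          l$rm <- (1 - mom) * l$rm + mom * mu
          l$rv <- (1 - mom) * l$rv + mom * v
        }
      } else {
        istd <- 1 / sqrt(l$rv + l$eps)
        xhat <- (xp - byrow_mat(l$rm, n)) * byrow_mat(istd, n)
      }
      l$xhat <- xhat; l$istd <- istd; l$x_dim <- d
      l$was_training <- !identical(training, FALSE)
      y <- xhat * byrow_mat(l$gamma, n) + byrow_mat(l$beta, n)
      aperm(array(y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    },
    act = {
      switch(l$fun,
        relu = { l$mask <- x > 0; x * l$mask },
        lrelu = { l$mask <- x > 0; y <- x; y[!l$mask] <- l$slope * y[!l$mask]; y },
        tanh = { l$y <- tanh(x); l$y },
        sigmoid = { l$y <- 1 / (1 + exp(-x)); l$y })
    },
    dense = {
      l$x <- x
      (l$W * l$gain) %*% x + l$b
    },
    reshape = {
      l$n <- ncol(x)
      array(x, c(l$dims, ncol(x)))
    },
    flatten = {
      l$x_dim <- dim(x)
      dim(x) <- c(prod(dim(x)[1:3]), dim(x)[4])
      x
    },
    crop = {
      d <- dim(x); l$x_dim <- d
      l$oy <- (d[1] - l$h) %/% 2L; l$ox <- (d[2] - l$w) %/% 2L
      x[l$oy + seq_len(l$h), l$ox + seq_len(l$w), , , drop = FALSE]
    },
    gap = {
      d <- dim(x); l$x_dim <- d
      matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
    },
    resblock = {
      l$x <- x
      y <- x
      for (sl in l$main) y <- layer_forward(sl, y, training)
      s <- x
      if (!is.null(l$skip)) for (sl in l$skip) s <- layer_forward(sl, s, training)
      pre <- y + s
      l$mask <- pre > 0
      pre * l$mask
    },
    stop_config(sprintf("unknown layer type '%s'", l$type)))
}

layer_backward <- function(l, g) {
  switch(l$type,
    conv = {
      d <- l$x_dim
      gm <- matrix(aperm(g, c(3, 1, 2, 4)), l$Cout)
      acc_grad(l, "W", array((l$cols %*% t(gm)) * l$gain, dim(l$W)))
      acc_grad(l, "b", rowSums(gm))
      gcols <- (matrix(l$W, nrow = l$kh * l$kw * l$Cin) * l$gain) %*% gm
      array(cpp_col2im(gcols, d[1], d[2], d[3], d[4], l$kh, l$kw, l$stride,
                       l$pad), d)
    },
    tconv = {
      d <- l$x_dim; od <- l$o_dim
      gcols <- cpp_im2col(g, od[1], od[2], od[3], od[4], l$k, l$k, l$stride,
                          l$pad)
      acc_grad(l, "W", array((gcols %*% t(l$xmat)) * l$gain, dim(l$W)))
      gb <- rowSums(matrix(colSums(matrix(g, od[1] * od[2])), od[3], od[4]))
      acc_grad(l, "b", gb)
      gxmat <- crossprod(matrix(l$W, nrow = l$k * l$k * l$Cout) * l$gain, gcols)
      aperm(array(gxmat, c(l$Cin, d[1], d[2], d[4])), c(2, 3, 1, 4))
    },
    bn = {
      d <- l$x_dim
      gp <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = l$C)
      n <- nrow(gp)
      acc_grad(l, "gamma", colSums(gp * l$xhat))
      acc_grad(l, "beta", colSums(gp))
      dxhat <- gp * byrow_mat(l$gamma, n)
      gx <- if (isTRUE(l$was_training)) {
        (dxhat - byrow_mat(colMeans(dxhat), n) -
           l$xhat * byrow_mat(colMeans(dxhat * l$xhat), n)) *
          byrow_mat(l$istd, n)
      } else dxhat * byrow_mat(l$istd, n)
      aperm(array(gx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    },
    act = {
      switch(l$fun,
        relu = g * l$mask,
        lrelu = { y <- g; y[!l$mask] <- l$slope * y[!l$mask]; y },
        tanh = g * (1 - l$y^2),
        sigmoid = g * l$y * (1 - l$y))
    },
    dense = {
      acc_grad(l, "W", (g %*% t(l$x)) * l$gain)
      acc_grad(l, "b", rowSums(g))
      crossprod(l$W * l$gain, g)
    },
    reshape = matrix(g, prod(l$dims), l$n),
    flatten = array(g, l$x_dim),
    crop = {
      gx <- array(0, l$x_dim)
      gx[l$oy + seq_len(l$h), l$ox + seq_len(l$w), , ] <- g
      gx
    },
    gap = {
      d <- l$x_dim
      array(rep(as.vector(g), each = d[1] * d[2]) / (d[1] * d[2]), d)
    },
    resblock = {
      g0 <- g * l$mask
      gm <- g0
      for (sl in rev(l$main)) gm <- layer_backward(sl, gm)
      gs <- g0
      if (!is.null(l$skip)) for (sl in rev(l$skip)) gs <- layer_backward(sl, gs)
      gm + gs
    },
    stop_config(sprintf("unknown layer type '%s'", l$type)))
}

net_forward <- function(net, x, training = FALSE) {
  for (l in net) x <- layer_forward(l, x, training)
  x
}

net_backward <- function(net, g) {
  for (l in rev(net)) g <- layer_backward(l, g)
  g
}

collect_layers <- function(net) {
  out <- list()
  for (l in net) {
    if (l$type == "resblock")
      out <- c(out, collect_layers(l$main),
               if (!is.null(l$skip)) collect_layers(l$skip))
    else out <- c(out, list(l))
  }
  out
}

# flat named list of all parameter and state arrays ("L003.W", ...)
net_params <- function(net, include_state = TRUE) {
  layers <- collect_layers(net)
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in c(l$pnames, if (include_state) l$snames))
      out[[sprintf("L%03d.%s", i, p)]] <- l[[p]]
  }
  out
}

net_set_params <- function(net, params) {
  layers <- collect_layers(net)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in c(l$pnames, l$snames)) {
      key <- sprintf("L%03d.%s", i, p)
      if (!key %in% names(params)) next
      v <- params[[key]]
      if (!identical(dim(v), dim(l[[p]])) || length(v) != length(l[[p]]))
        stop_config(sprintf("parameter %s has incompatible shape", key))
      l[[p]] <- v
    }
  }
  invisible(net)
}

net_grads <- function(net) {
  layers <- collect_layers(net)
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$pnames) {
      gname <- paste0("g_", p)
      if (exists(gname, envir = l, inherits = FALSE) && !is.null(l[[gname]]))
        out[[sprintf("L%03d.%s", i, p)]] <- l[[gname]]
    }
  }
  out
}

net_zero_grads <- function(net) {
  for (l in collect_layers(net))
    for (p in l$pnames) l[[paste0("g_", p)]] <- NULL
  invisible(net)
}

# Adam with optional L2 weight decay on convolution/dense weights.
# `t` is the global step count (for bias correction).
adam_step <- function(net, lr, t, beta1 = 0.5, beta2 = 0.999, eps = 1e-8,
                      l2 = 0) {
  for (l in collect_layers(net)) {
    for (p in l$pnames) {
      gname <- paste0("g_", p)
      if (!exists(gname, envir = l, inherits = FALSE) || is.null(l[[gname]]))
        next
      g <- l[[gname]]
      if (!all(is.finite(g)))
        stop_numeric(sprintf("non-finite gradient in %s.%s at step %d",
                             l$type, p, t))
      if (l2 > 0 && p == "W" && l$type %in% c("conv", "tconv", "dense"))
        g <- g + l2 * l[[p]]
      mname <- paste0("m_", p); vname <- paste0("v_", p)
      if (!exists(mname, envir = l, inherits = FALSE)) {
        l[[mname]] <- g * 0; l[[vname]] <- g * 0
      }
      l[[mname]] <- beta1 * l[[mname]] + (1 - beta1) * g
      l[[vname]] <- beta2 * l[[vname]] + (1 - beta2) * g * g
      mhat <- l[[mname]] / (1 - beta1^t)
      vhat <- l[[vname]] / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(net)
}

# drop forward caches and optimizer state (used before checkpointing)
net_strip <- function(net) {
  for (l in collect_layers(net)) {
    keep <- c("type", "pnames", "snames", l$pnames, l$snames,
              "Cin", "Cout", "k", "kh", "kw", "stride", "pad", "gain", "C", "momentum",
              "eps", "fun", "slope", "In", "Out", "dims", "h", "w",
              "main", "skip")
    for (nm in setdiff(ls(l), keep)) rm(list = nm, envir = l)
  }
  invisible(net)
}

binary_cross_entropy <- function(p, target, eps = 1e-7) {
  p <- clip(p, eps, 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}
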