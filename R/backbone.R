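#' Describe a backbone stream
#'
#' Three families are available. `tiny` is a small stride-2 conv/ReLU stack
#' (configurable depth and width) sized so the full two-stream model trains
#' in minutes on one CPU; it is the family used by the tests and the
#' end-to-end experiments. `resnet50` and `densenet121` are
#' normalization-free re-implementations of the standard bottleneck-residual
#' and dense-block layouts (built from the same conv primitives,
#' random-initialized, inference only); no pretrained weights are shipped,
#' so `pretrained = TRUE` is rejected.
#'
#' @param family One of `"tiny"`, `"resnet50"`, `"densenet121"`.
#' @param output_channels Channel count of the emitted feature map. Fixed at
#'   2048 / 1024 for the large families; default 8 for `tiny`.
#' @param depth Number of stride-2 conv layers in a `tiny` stack (each
#'   halves the grid); ignored otherwise.
#' @param pretrained Must be `FALSE`; present for interface compatibility.
#' @return A list of class `backbone_spec`.
#' @export
backbone_spec <- function(family = c("tiny", "resnet50", "densenet121"),
                          output_channels = NULL, depth = 2L, pretrained = FALSE) {
  family <- match.arg(family)
  if (isTRUE(pretrained)) {
    stop("no pretrained weights are distributed with this package; use pretrained = FALSE",
         call. = FALSE)
  }
  output_channels <- switch(family,
    tiny = as.integer(if (is.null(output_channels)) 8L else output_channels),
    resnet50 = 2048L,
    densenet121 = 1024L
  )
  if (output_channels < 1L) stop("output_channels must be positive", call. = FALSE)
  structure(list(family = family, output_channels = output_channels,
                 depth = as.integer(depth), pretrained = FALSE),
            class = "backbone_spec")
}

res_bottleneck <- function(cin, mid, cout, stride) {
  body <- list(conv_layer(cin, mid, 1L, 1L, 1L, 0L), list(type = "relu"),
               conv_layer(mid, mid, 3L, 3L, stride, 1L), list(type = "relu"),
               conv_layer(mid, cout, 1L, 1L, 1L, 0L))
  shortcut <- if (stride != 1L || cin != cout) {
    list(conv_layer(cin, cout, 1L, 1L, stride, 0L))
  } else NULL
  list(type = "residual", body = body, shortcut = shortcut)
}

build_resnet50 <- function(in_channels) {
  layers <- list(conv_layer(in_channels, 64L, 7L, 7L, 2L, 3L), list(type = "relu"),
                 pool_layer("max", 3L, 2L, 1L))
  cfg <- list(c(64, 256, 3, 1), c(128, 512, 4, 2), c(256, 1024, 6, 2), c(512, 2048, 3, 2))
  cin <- 64L
  for (st in cfg) {
    mid <- st[1]; cout <- st[2]; n <- st[3]; s <- st[4]
    for (b in seq_len(n)) {
      layers <- c(layers, list(res_bottleneck(cin, mid, cout, if (b == 1L) s else 1L)))
      cin <- cout
    }
  }
  layers
}

build_densenet121 <- function(in_channels, growth = 32L) {
  layers <- list(conv_layer(in_channels, 64L, 7L, 7L, 2L, 3L), list(type = "relu"),
                 pool_layer("max", 3L, 2L, 1L))
  cin <- 64L
  sizes <- c(6L, 12L, 24L, 16L)
  for (bi in seq_along(sizes)) {
    sub <- vector("list", sizes[bi])
    for (li in seq_len(sizes[bi])) {
      sub[[li]] <- list(conv_layer(cin + (li - 1L) * growth, 4L * growth, 1L, 1L, 1L, 0L),
                        list(type = "relu"),
                        conv_layer(4L * growth, growth, 3L, 3L, 1L, 1L),
                        list(type = "relu"))
    }
    layers <- c(layers, list(list(type = "dense_block", sub = sub, growth = growth)))
    cin <- cin + sizes[bi] * growth
    if (bi < length(sizes)) {
      layers <- c(layers, list(conv_layer(cin, cin %/% 2L, 1L, 1L, 1L, 0L),
                               pool_layer("avg", 2L, 2L, 0L)))
      cin <- cin %/% 2L
    }
  }
  layers
}

# Tiny stack: `depth` stride-2 3x3 conv + ReLU pairs, widths ramping from 8
# to the requested output channel count.
build_tiny <- function(in_channels, depth, out_channels) {
  widths <- if (depth == 1L) out_channels else {
    unique_w <- round(seq(8, out_channels, length.out = depth))
    unique_w[depth] <- out_channels
    as.integer(pmax(unique_w, 1L))
  }
  layers <- list()
  cin <- in_channels
  for (i in seq_len(depth)) {
    layers <- c(layers, list(conv_layer(cin, widths[i], 3L, 3L, 2L, 1L),
                             list(type = "relu")))
    cin <- widths[i]
  }
  layers
}

#' Build a backbone instance
#'
#' Instantiates the conv stack of a [backbone_spec()] with seeded Gaussian
#' (He-scaled) weights; the same `(spec, seed)` always yields bit-identical
#' parameters.
#'
#' @param spec A [backbone_spec()].
#' @param in_channels Input image channels (3 for RGB).
#' @param seed Integer seed.
#' @return A list of class `backbone` with fields `family`, `layers`,
#'   `out_channels`.
#' @export
build_backbone <- function(spec, in_channels = 3L, seed = 0L) {
  layers <- with_seed(as.integer(seed), switch(spec$family,
    tiny = build_tiny(in_channels, spec$depth, spec$output_channels),
    resnet50 = build_resnet50(in_channels),
    densenet121 = build_densenet121(in_channels)
  ))
  structure(list(family = spec$family, layers = layers,
                 out_channels = spec$output_channels, spec = spec),
            class = "backbone")
}

forward_nodes <- function(nodes, x) {
  for (nd in nodes) x <- forward_node(nd, x)
  x
}

forward_node <- function(nd, x) {
  switch(nd$type,
    conv = conv_forward(nd, x)$out,
    relu = relu_forward(x)$out,
    pool = pool_forward(nd, x),
    residual = {
      y <- forward_nodes(nd$body, x)
      s <- if (is.null(nd$shortcut)) x else forward_nodes(nd$shortcut, x)
      relu_forward(y + s)$out
    },
    dense_block = {
      for (sub in nd$sub) {
        y <- forward_nodes(sub, x)
        d <- dim(x)
        xc <- array(0, c(d[1], d[2], d[3] + dim(y)[3], d[4]))
        xc[, , seq_len(d[3]), ] <- x
        xc[, , d[3] + seq_len(dim(y)[3]), ] <- y
        x <- xc
      }
      x
    },
    stop_shape("unknown layer type '%s'", nd$type)
  )
}

# Forward pass of a backbone over a batch (H, W, Cin, N). For the tiny
# family a cache for backprop is returned; the large families are
# inference-only.
backbone_forward <- function(bb, x, want_cache = FALSE) {
  if (bb$family != "tiny") {
    if (want_cache) stop("training (backward pass) is only supported for the 'tiny' family",
                         call. = FALSE)
    return(list(out = forward_nodes(bb$layers, x), caches = NULL))
  }
  caches <- vector("list", length(bb$layers))
  for (i in seq_along(bb$layers)) {
    nd <- bb$layers[[i]]
    if (nd$type == "conv") {
      f <- conv_forward(nd, x)
      if (want_cache) caches[[i]] <- f$cache
      x <- f$out
    } else {
      f <- relu_forward(x)
      if (want_cache) caches[[i]] <- f$cache
      x <- f$out
    }
  }
  list(out = x, caches = if (want_cache) caches else NULL)
}

# Backward through a tiny backbone; returns gradients per conv layer and dx.
backbone_backward <- function(bb, caches, dout) {
  grads <- vector("list", length(bb$layers))
  for (i in rev(seq_along(bb$layers))) {
    nd <- bb$layers[[i]]
    if (nd$type == "conv") {
      g <- conv_backward(nd, caches[[i]], dout)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dout <- g$dx
    } else {
      dout <- relu_backward(caches[[i]], dout)
    }
  }
  list(grads = grads, dx = dout)
}

# Flat views over trainable tiny-backbone parameters (used by the SGD step).
backbone_param_refs <- function(bb) {
  which(vapply(bb$layers, function(l) identical(l$type, "conv"), logical(1)))
}
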