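# Minimal convolutional-network framework used by the triplet-loss syllable
# embedder: conv2d (same padding, optional stride on the frequency axis),
# multiscale analysis modules (four parallel conv strands concatenated
# channel-wise), global mean pooling, fully connected layers and an L2
# normalization head. Forward/backward passes are hand-written matrix code
# (im2col convolutions); optimization is Adam with L2 weight decay.

.he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

.layer_conv <- function(in_ch, out_ch, k, stride = c(1L, 1L), relu = TRUE) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = as.integer(stride), relu = relu,
       W = .he_init(k * k * in_ch, c(out_ch, k * k * in_ch)),
       b = numeric(out_ch))
}

.layer_mam <- function(in_ch, width = 32L) {
  strands <- list(
    list(.layer_conv(in_ch, width, 1L)),
    list(.layer_conv(in_ch, width, 1L), .layer_conv(width, width, 3L)),
    list(.layer_conv(in_ch, width, 1L), .layer_conv(width, width, 5L)),
    list(.layer_conv(in_ch, width, 1L), .layer_conv(width, width, 7L))
  )
  list(type = "mam", in_ch = in_ch, width = width, out_ch = 4L * width,
       strands = strands)
}

.layer_pool <- function() list(type = "pool")

.layer_dense <- function(n_in, n_out, relu = TRUE) {
  list(type = "dense", relu = relu,
       W = .he_init(n_in, c(n_out, n_in)),
       b = numeric(n_out))
}

.layer_l2norm <- function() list(type = "l2norm")

# index map for im2col on a zero-padded input of shape (h, w, c):
# returns list(idx matrix [k*k*c, oh*ow], oh, ow, ph, pw)
.conv_geometry <- function(h, w, c, k, stride) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  oh <- ceiling(h / stride[1]); ow <- ceiling(w / stride[2])
  oi <- (seq_len(oh) - 1L) * stride[1]       # top-left row offset in padded
  oj <- (seq_len(ow) - 1L) * stride[2]
  ki <- rep(seq_len(k), times = k)           # kernel row, col-major over (ki, kj)
  kj <- rep(seq_len(k), each = k)
  # linear index in padded array (h-major): r + (cc-1)*hp*wp ... layout (hp, wp, c)
  base <- outer(ki, oi, `+`)                 # k*k x oh  (rows)
  colo <- outer(kj, oj, `+`)                 # k*k x ow  (cols)
  idx <- matrix(0L, k * k * c, oh * ow)
  for (cc in seq_len(c)) {
    off <- (cc - 1L) * hp * wp
    for (jo in seq_len(ow)) {
      col_block <- (jo - 1L) * oh + seq_len(oh)
      # rows: base[,io]; cols in padded: colo[,jo]
      idx[(cc - 1L) * k * k + seq_len(k * k), col_block] <-
        off + base + (colo[, jo] - 1L) * hp
    }
  }
  list(idx = idx, oh = oh, ow = ow, p = p, hp = hp, wp = wp)
}

.conv_forward <- function(layer, x) {
  d <- dim(x)                                # (h, w, c, n)
  geo <- .conv_geometry(d[1], d[2], d[3], layer$k, layer$stride)
  n <- d[4]
  xp <- array(0, c(geo$hp, geo$wp, d[3], n))
  xp[geo$p + seq_len(d[1]), geo$p + seq_len(d[2]), , ] <- x
  samp <- geo$hp * geo$wp * d[3]
  idx_all <- rep(as.numeric(geo$idx), n) +
    rep((seq_len(n) - 1) * samp, each = length(geo$idx))
  Xcol <- matrix(xp[idx_all], nrow = nrow(geo$idx))
  Z <- layer$W %*% Xcol + layer$b
  act <- if (layer$relu) pmax(Z, 0) else Z
  out <- aperm(array(act, c(layer$out_ch, geo$oh, geo$ow, n)), c(2, 3, 1, 4))
  list(out = out,
       cache = list(Xcol = Xcol, Z = Z, dims = d, geo = geo, n = n))
}

.conv_backward <- function(layer, cache, dout) {
  geo <- cache$geo; d <- cache$dims; n <- cache$n
  dZ <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = layer$out_ch)
  if (layer$relu) dZ <- dZ * (cache$Z > 0)
  dW <- tcrossprod(dZ, cache$Xcol)
  db <- rowSums(dZ)
  dXcol <- crossprod(layer$W, dZ)
  # col2im scatter-add: within one kernel-offset row all target positions
  # are distinct, so accumulate one vectorized add per row
  samp <- geo$hp * geo$wp * d[3]
  offs <- rep((seq_len(n) - 1L) * samp, each = ncol(geo$idx))
  dxp <- numeric(samp * n)
  for (r in seq_len(nrow(geo$idx))) {
    ind <- rep(geo$idx[r, ], n) + offs
    dxp[ind] <- dxp[ind] + dXcol[r, ]
  }
  dim(dxp) <- c(geo$hp, geo$wp, d[3], n)
  dx <- dxp[geo$p + seq_len(d[1]), geo$p + seq_len(d[2]), , , drop = FALSE]
  dim(dx) <- d
  list(dx = dx, grads = list(W = dW, b = db))
}

.mam_forward <- function(layer, x) {
  outs <- list(); caches <- list()
  for (s in seq_along(layer$strands)) {
    cur <- x; sc <- list()
    for (li in seq_along(layer$strands[[s]])) {
      f <- .conv_forward(layer$strands[[s]][[li]], cur)
      cur <- f$out; sc[[li]] <- f$cache
    }
    outs[[s]] <- cur; caches[[s]] <- sc
  }
  d <- dim(outs[[1]])
  out <- array(0, c(d[1], d[2], layer$out_ch, d[4]))
  ch0 <- 0L
  for (s in seq_along(outs)) {
    w <- dim(outs[[s]])[3]
    out[, , ch0 + seq_len(w), ] <- outs[[s]]
    ch0 <- ch0 + w
  }
  list(out = out, cache = caches)
}

.mam_backward <- function(layer, cache, dout) {
  dx <- NULL; grads <- list()
  ch0 <- 0L
  for (s in seq_along(layer$strands)) {
    w <- layer$width
    dcur <- dout[, , ch0 + seq_len(w), , drop = FALSE]
    ch0 <- ch0 + w
    sgrads <- vector("list", length(layer$strands[[s]]))
    for (li in rev(seq_along(layer$strands[[s]]))) {
      bk <- .conv_backward(layer$strands[[s]][[li]], cache[[s]][[li]], dcur)
      dcur <- bk$dx
      sgrads[[li]] <- bk$grads
    }
    grads[[s]] <- sgrads
    dx <- if (is.null(dx)) dcur else dx + dcur
  }
  list(dx = dx, grads = grads)
}

.net_forward <- function(net, x) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
      conv = .conv_forward(ly, x),
      mam = .mam_forward(ly, x),
      pool = {
        d <- dim(x)
        out <- apply(x, c(3, 4), mean)             # (c, n)
        list(out = out, cache = d)
      },
      dense = {
        Z <- ly$W %*% x + ly$b
        act <- if (ly$relu) pmax(Z, 0) else Z
        list(out = act, cache = list(x = x, Z = Z))
      },
      l2norm = {
        nrm <- sqrt(colSums(x^2)) + 1e-12
        list(out = sweep(x, 2, nrm, "/"), cache = list(x = x, nrm = nrm))
      },
      stop("unknown layer type ", ly$type))
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches)
}

.net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      bk <- .conv_backward(ly, caches[[i]], dout)
      dout <- bk$dx; grads[[i]] <- bk$grads
    } else if (ly$type == "mam") {
      bk <- .mam_backward(ly, caches[[i]], dout)
      dout <- bk$dx; grads[[i]] <- bk$grads
    } else if (ly$type == "pool") {
      d <- caches[[i]]
      # broadcast dout (c, n) over spatial positions, scaled by 1/(h*w)
      dx <- array(rep(as.numeric(dout), each = d[1] * d[2]), dim = d)
      dout <- dx / (d[1] * d[2])
    } else if (ly$type == "dense") {
      cc <- caches[[i]]
      dZ <- if (ly$relu) dout * (cc$Z > 0) else dout
      grads[[i]] <- list(W = dZ %*% t(cc$x), b = rowSums(dZ))
      dout <- crossprod(ly$W, dZ)
    } else if (ly$type == "l2norm") {
      cc <- caches[[i]]
      y <- sweep(cc$x, 2, cc$nrm, "/")
      dot <- colSums(dout * y)
      dout <- sweep(dout - sweep(y, 2, dot, "*"), 2, cc$nrm, "/")
    }
  }
  grads
}

# flatten / apply parameter updates -----------------------------------------

.walk_params <- function(net, fn) {
  # fn(layer_path, W, b) applied to every parameterized conv/dense layer;
  # layer_path is a list index vector into net$layers (with strand indices)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      fn(list(i), ly)
    } else if (ly$type == "mam") {
      for (s in seq_along(ly$strands)) {
        for (li in seq_along(ly$strands[[s]])) {
          fn(list(i, s, li), ly$strands[[s]][[li]])
        }
      }
    }
  }
}

.get_layer <- function(net, path) {
  if (length(path) == 1L) net$layers[[path[[1]]]]
  else net$layers[[path[[1]]]]$strands[[path[[2]]]][[path[[3]]]]
}

.set_layer <- function(net, path, layer) {
  if (length(path) == 1L) net$layers[[path[[1]]]] <- layer
  else net$layers[[path[[1]]]]$strands[[path[[2]]]][[path[[3]]]] <- layer
  net
}

.grad_of <- function(grads, path) {
  if (length(path) == 1L) grads[[path[[1]]]]
  else grads[[path[[1]]]][[path[[2]]]][[path[[3]]]]
}

.adam_step <- function(net, grads, state, lr, wd = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  paths <- list()
  .walk_params(net, function(path, ly) paths[[length(paths) + 1L]] <<- path)
  for (p in paths) {
    key <- paste(unlist(p), collapse = ".")
    ly <- .get_layer(net, p)
    g <- .grad_of(grads, p)
    if (is.null(g)) next
    gW <- g$W + wd * ly$W
    gb <- g$b
    st <- state$m[[key]]
    if (is.null(st)) st <- list(mW = gW * 0, vW = gW * 0, mb = gb * 0, vb = gb * 0)
    st$mW <- beta1 * st$mW + (1 - beta1) * gW
    st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gb
    st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
    state$m[[key]] <- st
    bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
    ly$W <- ly$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    ly$b <- ly$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    net <- .set_layer(net, p, ly)
  }
  list(net = net, state = state)
}

#' Build the triplet-loss syllable embedder
#'
#' Constructs the convolutional metric-learning network: five convolutional
#' layers (the first with 32 3x3 kernels, the rest 64 3x3 kernels with
#' stride 2 along the frequency axis) alternating with four multiscale
#' analysis modules — each four parallel strands (1x1; 1x1 then 3x3; 1x1
#' then 5x5; 1x1 then 7x7; 32 kernels each) concatenated to 128 channels —
#' followed by global mean pooling, three fully connected layers and an
#' L2-normalized 8-dimensional output, ReLU throughout. The `"desk"` preset
#' keeps the same layer pattern at reduced width and depth (three convs,
#' two modules) for training at desk scale.
#'
#' @param input_shape `c(n_freq, n_time)` of the input spectrograms.
#' @param preset `"full"` (publication-scale widths) or `"desk"` (reduced).
#' @param embed_dim Output embedding dimensionality (default 8).
#' @param seed Seed for weight initialization.
#' @return Object of class `song_embedder`.
#' @export
build_embedder <- function(input_shape, preset = c("desk", "full"),
                           embed_dim = 8L, seed = 1L) {
  preset <- match.arg(preset)
  if (length(input_shape) != 2L || any(input_shape < 8L)) {
    stop("input_shape must be c(n_freq, n_time), both >= 8", call. = FALSE)
  }
  set.seed(as.integer(seed))
  layers <- list()
  if (preset == "full") {
    conv_ch <- c(32L, 64L, 64L, 64L, 64L)
    mam_w <- 32L
    fc <- c(128L, 64L)
    n_mam <- 4L
  } else {
    conv_ch <- c(8L, 16L, 16L)
    mam_w <- 4L
    fc <- c(24L, 16L)
    n_mam <- 2L
  }
  in_ch <- 1L
  h <- input_shape[1]
  for (i in seq_along(conv_ch)) {
    stride <- if (i == 1L) c(1L, 1L) else c(2L, 1L)
    layers[[length(layers) + 1L]] <- .layer_conv(in_ch, conv_ch[i], 3L, stride)
    if (i > 1L) h <- ceiling(h / 2)
    in_ch <- conv_ch[i]
    if (i <= n_mam) {
      layers[[length(layers) + 1L]] <- .layer_mam(in_ch, mam_w)
      in_ch <- 4L * mam_w
    }
  }
  layers[[length(layers) + 1L]] <- .layer_pool()
  n_in <- in_ch
  for (f in fc) {
    layers[[length(layers) + 1L]] <- .layer_dense(n_in, f)
    n_in <- f
  }
  layers[[length(layers) + 1L]] <- .layer_dense(n_in, embed_dim, relu = FALSE)
  layers[[length(layers) + 1L]] <- .layer_l2norm()
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 embed_dim = as.integer(embed_dim), preset = preset),
            class = "song_embedder")
}

#' Triplet loss
#'
#' `max(dAP - dAN + alpha, 0)` on plain (unsquared) Euclidean embedding
#' distances. Setting `squared = TRUE` switches to the squared-distance
#' variant common elsewhere in the metric-learning literature.
#'
#' @param dAP,dAN Anchor-positive and anchor-negative distances (`>= 0`).
#' @param alpha Margin.
#' @param squared Use squared distances.
#' @return Numeric loss value(s).
#' @export
triplet_loss <- function(dAP, dAN, alpha, squared = FALSE) {
  stopifnot(all(dAP >= 0), all(dAN >= 0))
  if (squared) {
    pmax(dAP^2 - dAN^2 + alpha, 0)
  } else {
    pmax(dAP - dAN + alpha, 0)
  }
}

#' Classify a triplet's hardness
#'
#' `"hard"` when the positive is farther from the anchor than the negative
#' (`dAP > dAN`); `"semi_hard"` when the negative is farther but by less
#' than the margin (`0 < dAN - dAP < alpha`); `"zero"` when the margin is
#' already satisfied.
#'
#' @param dAP,dAN Distances (`>= 0`), vectorized.
#' @param alpha Margin.
#' @return Character vector in `{"zero", "semi_hard", "hard"}`.
#' @export
classify_triplet <- function(dAP, dAN, alpha) {
  ifelse(dAP > dAN, "hard",
         ifelse(dAN - dAP < alpha, "semi_hard", "zero"))
}

#' Embed syllable spectrograms with a trained model
#'
#' @param model A `song_embedder`.
#' @param x Matrix of flattened spectrograms (rows = syllables) whose
#'   dimensions match `model$input_shape`, or a set produced by
#'   [prep_similarity_spectrograms()].
#' @param batch_size Forward-pass batch size.
#' @return `n x embed_dim` matrix with unit-norm rows.
#' @export
embed_syllables <- function(model, x, batch_size = 256L) {
  if (inherits(x, "syllable_spectrogram_set")) x <- x$vectors
  x <- as.matrix(x)
  hw <- model$input_shape
  stopifnot(ncol(x) == prod(hw))
  n <- nrow(x)
  out <- matrix(0, n, model$embed_dim)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    xb <- array(t(x[s:e, , drop = FALSE]), c(hw[1], hw[2], 1L, e - s + 1L))
    out[s:e, ] <- t(.net_forward(model, xb)$out)
  }
  out
}

#' Train the syllable embedder with dynamic triplet loss
#'
#' Per mini-batch, a forward pass embeds all candidate syllables; all valid
#' triplets (anchor and positive sharing a label within one bird, negative
#' labelled differently) are classified by hardness and sampled at a 75:25
#' semi-hard:hard ratio for the gradient step (Adam, L2 weight decay
#' 1e-4). The margin starts at 0.1 and is raised by 0.2 — up to 0.7 — each
#' time an epoch averages fewer than `nonzero_threshold` non-zero-loss
#' triplets per batch. All randomness flows from `seed`.
#'
#' @param x Matrix of flattened spectrograms or a set from
#'   [prep_similarity_spectrograms()].
#' @param labels Character syllable labels (one per row).
#' @param birds Character bird ids (one per row); at least 2 birds with at
#'   least 2 labelled types each are required.
#' @param model A `song_embedder` from [build_embedder()] (built to match
#'   the input shape if `NULL`).
#' @param input_shape Required if `model` is `NULL` and `x` is a bare
#'   matrix.
#' @param epochs,batch_size,lr Optimization parameters.
#' @param max_triplets Triplets sampled per batch.
#' @param nonzero_threshold Margin-schedule trigger (mean non-zero triplets
#'   per batch); defaults to `max_triplets / 4`, a desk-scale analogue of
#'   the full-scale batch threshold.
#' @param semi_hard_frac Fraction of sampled triplets drawn semi-hard.
#' @param weight_decay L2 weight decay coefficient.
#' @param seed Integer seed.
#' @return List of class `triplet_fit`: `model`, `history` (data.frame:
#'   epoch, margin, mean_nonzero, loss).
#' @export
train_embedder <- function(x, labels, birds, model = NULL,
                           input_shape = NULL, epochs = 30L,
                           batch_size = 48L, lr = 1e-3,
                           max_triplets = 200L, nonzero_threshold = NULL,
                           semi_hard_frac = 0.75, weight_decay = 1e-4,
                           seed = 1L) {
  if (inherits(x, "syllable_spectrogram_set")) {
    if (is.null(input_shape)) input_shape <- c(x$n_freq, x$n_time)
    x <- x$vectors
  }
  x <- as.matrix(x)
  labels <- as.character(labels); birds <- as.character(birds)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(birds))
  per_bird_types <- tapply(labels, birds, function(l) length(unique(l)))
  if (length(per_bird_types) < 2L || any(per_bird_types < 2L)) {
    stop("training needs >= 2 birds with >= 2 syllable types each",
         call. = FALSE)
  }
  if (is.null(model)) {
    if (is.null(input_shape)) stop("input_shape required", call. = FALSE)
    model <- build_embedder(input_shape, seed = seed)
  }
  if (is.null(nonzero_threshold)) nonzero_threshold <- max_triplets / 4
  set.seed(as.integer(seed) + 1L)
  n <- nrow(x)
  hw <- model$input_shape
  margin <- 0.1
  state <- list(t = 0L, m = list())
  history <- data.frame(epoch = integer(), margin = numeric(),
                        mean_nonzero = numeric(), loss = numeric())
  group <- paste(birds, labels)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    nz_counts <- integer(0); ep_loss <- 0; n_batches <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      bi <- ord[s:min(n, s + batch_size - 1L)]
      if (length(bi) < 6L) next
      xb <- array(t(x[bi, , drop = FALSE]), c(hw[1], hw[2], 1L, length(bi)))
      fw <- .net_forward(model, xb)
      E <- fw$out                              # embed_dim x b
      b <- ncol(E)
      D <- .gram_dist(t(E))
      gb <- group[bi]; lb <- labels[bi]
      trip <- .enumerate_triplets(gb, lb)
      if (nrow(trip) == 0L) next
      dAP <- D[cbind(trip$a, trip$p)]
      dAN <- D[cbind(trip$a, trip$ng)]
      hardness <- classify_triplet(dAP, dAN, margin)
      nz <- hardness != "zero"
      nz_counts <- c(nz_counts, sum(nz))
      sel <- .sample_ratio(which(hardness == "semi_hard"),
                           which(hardness == "hard"),
                           max_triplets, semi_hard_frac)
      if (length(sel) == 0L) next
      ta <- trip$a[sel]; tp <- trip$p[sel]; tn <- trip$ng[sel]
      dap <- pmax(D[cbind(ta, tp)], 1e-8)
      dan <- pmax(D[cbind(ta, tn)], 1e-8)
      active <- (dap - dan + margin) > 0
      if (!any(active)) next
      ta <- ta[active]; tp <- tp[active]; tn <- tn[active]
      dap <- dap[active]; dan <- dan[active]
      ep_loss <- ep_loss + sum(dap - dan + margin)
      m <- length(ta)
      dE <- matrix(0, nrow(E), b)
      # dL/dA = (A-P)/dAP - (A-N)/dAN ; dL/dP = -(A-P)/dAP ; dL/dN = (A-N)/dAN
      gAP <- (E[, ta, drop = FALSE] - E[, tp, drop = FALSE]) / rep(dap, each = nrow(E))
      gAN <- (E[, ta, drop = FALSE] - E[, tn, drop = FALSE]) / rep(dan, each = nrow(E))
      add_to <- function(dE, idx, val) {
        agg <- rowsum(t(val), idx)
        ii <- as.integer(rownames(agg))
        dE[, ii] <- dE[, ii] + t(agg)
        dE
      }
      dE <- add_to(dE, ta, gAP - gAN)
      dE <- add_to(dE, tp, -gAP)
      dE <- add_to(dE, tn, gAN)
      dE <- dE / m
      grads <- .net_backward(model, fw$caches, dE)
      upd <- .adam_step(model, grads, state, lr, wd = weight_decay)
      model <- upd$net; state <- upd$state
      n_batches <- n_batches + 1L
    }
    mean_nz <- if (length(nz_counts)) mean(nz_counts) else 0
    history <- rbind(history,
                     data.frame(epoch = ep, margin = margin,
                                mean_nonzero = mean_nz,
                                loss = if (n_batches) ep_loss / n_batches else 0))
    if (mean_nz < nonzero_threshold && margin < 0.7 - 1e-9) {
      margin <- round(min(0.7, margin + 0.2), 1)
    }
  }
  structure(list(model = model, history = history), class = "triplet_fit")
}

# all (anchor, positive, negative) index triples within a batch
.enumerate_triplets <- function(group, labels, cap = 20000L) {
  b <- length(group)
  pairs <- which(outer(group, group, `==`) & upper.tri(matrix(0, b, b)),
                 arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(data.frame(a = integer(), p = integer(),
                                           ng = integer()))
  # anchors in both orders
  a <- c(pairs[, 1], pairs[, 2])
  p <- c(pairs[, 2], pairs[, 1])
  negs_of <- lapply(unique(labels), function(l) which(labels != l))
  names(negs_of) <- unique(labels)
  nneg <- lengths(negs_of)[labels[a]]
  keep <- nneg > 0L
  a <- a[keep]; p <- p[keep]; nneg <- nneg[keep]
  if (length(a) == 0L) return(data.frame(a = integer(), p = integer(),
                                         ng = integer()))
  trip <- data.frame(a = rep(a, nneg), p = rep(p, nneg),
                     ng = unlist(negs_of[labels[a]], use.names = FALSE))
  if (nrow(trip) > cap) trip <- trip[sample.int(nrow(trip), cap), , drop = FALSE]
  trip
}

.sample_ratio <- function(semi, hard, total, frac_semi) {
  n_semi <- min(length(semi), round(total * frac_semi))
  n_hard <- min(length(hard), total - n_semi)
  c(if (n_semi > 0) sample(semi, n_semi) else integer(),
    if (n_hard > 0) sample(hard, n_hard) else integer())
}
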