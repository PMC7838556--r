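## Compact U-Net semantic segmenter written in base R.
##
## Activations are stored as [H, W, N, C] arrays (batch in dim 3, channels
## last) so that im2col blocks flatten to [H*W*N, C] matrices without
## permutation; all heavy arithmetic is BLAS matrix multiplication.
## Architecture: `depth` encoder levels of (conv3x3-BN-ReLU) x2 + 2x2 maxpool,
## a bottleneck block, and mirrored decoder levels of 2x2 transposed
## convolution + skip concatenation + (conv3x3-BN-ReLU) x2, ending in a 1x1
## convolution and per-pixel softmax over the tissue classes. Trained with
## Adam on cross-entropy.

#' U-Net configuration
#'
#' @param input_size Network input side in pixels; must be divisible by
#'   `2^depth`. Default 512 (training patches are reflect-padded up to this).
#' @param depth Number of down/up-sampling levels (default 4).
#' @param base_filters Channels of the first encoder level; doubled per level
#'   (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 8).
#' @param max_epochs Hard epoch cap (default 100).
#' @param patience Early-stop patience in epochs (default 10).
#' @param min_gain Minimum relative validation-DSC improvement, default 0.001
#'   (i.e. 0.1%; read as a relative gain — at DSC near 0.9 the absolute
#'   reading would differ by under 10%).
#' @param classes Class codes the softmax head predicts (default the seven
#'   tissue classes).
#' @param seed RNG seed for initialization and batch shuffling.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(input_size = 512L, depth = 4L, base_filters = 16L,
                        learning_rate = 1e-3, batch_size = 8L,
                        max_epochs = 100L, patience = 10L, min_gain = 0.001,
                        classes = tissue_classes(), seed = 1L) {
  input_size <- as.integer(input_size); depth <- as.integer(depth)
  if (input_size %% 2L^depth != 0L)
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  if (patience < 1L) stop("patience must be >= 1", call. = FALSE)
  if (min_gain < 0) stop("min_gain must be >= 0", call. = FALSE)
  structure(list(input_size = input_size, depth = depth,
                 base_filters = as.integer(base_filters),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_gain = min_gain,
                 classes = classes, seed = as.integer(seed)),
            class = "unet_config")
}

## ---- layer primitives -----------------------------------------------------

flat <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2] * d[3], d[4]); x }

conv_init <- function(cin, cout, k = 3L) {
  list(W = matrix(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = k)
}

# 3x3 same-padding convolution forward; returns output and im2col cache
conv_fwd <- function(ly, X) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  Xp <- array(0, c(H + 2L, W + 2L, N, C))
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  blocks <- vector("list", 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blocks[[k]] <- flat(Xp[di + (1:H), dj + (1:W), , , drop = FALSE])
  }
  M <- do.call(cbind, blocks)
  out <- M %*% ly$W
  out <- sweep(out, 2, ly$b, `+`)
  dim(out) <- c(H, W, N, ncol(ly$W))
  list(out = out, M = M, in_dim = d)
}

conv_bwd <- function(ly, cache, dOut) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  dmat <- flat(dOut)
  dW <- crossprod(cache$M, dmat)
  db <- colSums(dmat)
  dM <- dmat %*% t(ly$W)
  dXp <- array(0, c(H + 2L, W + 2L, N, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    blk <- dM[, (k - 1L) * C + (1:C), drop = FALSE]
    dim(blk) <- c(H, W, N, C)
    dXp[di + (1:H), dj + (1:W), , ] <- dXp[di + (1:H), dj + (1:W), , , drop = FALSE] + blk
  }
  list(dX = dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE],
       grads = list(W = dW, b = db))
}

conv1x1_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

conv1x1_fwd <- function(ly, X) {
  d <- dim(X)
  M <- flat(X)
  out <- sweep(M %*% ly$W, 2, ly$b, `+`)
  dim(out) <- c(d[1], d[2], d[3], ncol(ly$W))
  list(out = out, M = M, in_dim = d)
}

conv1x1_bwd <- function(ly, cache, dOut) {
  dmat <- flat(dOut)
  dX <- dmat %*% t(ly$W)
  dim(dX) <- cache$in_dim
  list(dX = dX, grads = list(W = crossprod(cache$M, dmat), b = colSums(dmat)))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_fwd <- function(ly, X, train) {
  d <- dim(X)
  M <- flat(X)
  if (train) {
    mu <- colMeans(M)
    ctr <- sweep(M, 2, mu)
    va <- colMeans(ctr^2)
  } else {
    mu <- ly$run_mean; va <- ly$run_var
    ctr <- sweep(M, 2, mu)
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(ctr, 2, invstd, `*`)
  out <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
  dim(out) <- d
  list(out = out, xhat = xhat, invstd = invstd, in_dim = d,
       batch_mean = if (train) mu else NULL,
       batch_var = if (train) va else NULL)
}

bn_bwd <- function(ly, cache, dOut) {
  d <- cache$in_dim
  m <- d[1] * d[2] * d[3]
  dmat <- flat(dOut)
  dgamma <- colSums(dmat * cache$xhat)
  dbeta <- colSums(dmat)
  dxhat <- sweep(dmat, 2, ly$gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dX <- sweep(t1 - t2, 2, cache$invstd, `*`)
  dim(dX) <- d
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(out = X, mask = mask)
}

maxpool_fwd <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  q <- list(X[ro, co, , , drop = FALSE], X[re, co, , , drop = FALSE],
            X[ro, ce, , , drop = FALSE], X[re, ce, , , drop = FALSE])
  out <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    masks[[k]] <- (q[[k]] == out) & !taken
    taken <- taken | masks[[k]]
  }
  list(out = out, masks = masks, in_dim = d)
}

maxpool_bwd <- function(cache, dOut) {
  d <- cache$in_dim
  dX <- array(0, d)
  ro <- seq(1L, d[1], 2L); re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L); ce <- seq(2L, d[2], 2L)
  dX[ro, co, , ] <- dOut * cache$masks[[1]]
  dX[re, co, , ] <- dX[re, co, , , drop = FALSE] + dOut * cache$masks[[2]]
  dX[ro, ce, , ] <- dX[ro, ce, , , drop = FALSE] + dOut * cache$masks[[3]]
  dX[re, ce, , ] <- dX[re, ce, , , drop = FALSE] + dOut * cache$masks[[4]]
  dX
}

tconv_init <- function(cin, cout) {
  # 2x2 kernel, stride 2: one [cin, cout] matrix per output sub-position
  list(W = lapply(1:4, function(i)
         matrix(stats::rnorm(cin * cout, 0, sqrt(2 / (4 * cin))), cin, cout)),
       b = numeric(cout))
}

tconv_fwd <- function(ly, X) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]
  cout <- ncol(ly$W[[1]])
  M <- flat(X)
  out <- array(0, c(2L * H, 2L * W, N, cout))
  pos <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (k in 1:4) {
    Y <- sweep(M %*% ly$W[[k]], 2, ly$b, `+`)
    dim(Y) <- c(H, W, N, cout)
    out[seq(pos[[k]][1], 2L * H, 2L), seq(pos[[k]][2], 2L * W, 2L), , ] <- Y
  }
  list(out = out, M = M, in_dim = d)
}

tconv_bwd <- function(ly, cache, dOut) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]
  pos <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  dW <- vector("list", 4L)
  db <- numeric(length(ly$b))
  dM <- 0
  for (k in 1:4) {
    dY <- flat(dOut[seq(pos[[k]][1], 2L * H, 2L),
                    seq(pos[[k]][2], 2L * W, 2L), , , drop = FALSE])
    dW[[k]] <- crossprod(cache$M, dY)
    db <- db + colSums(dY)
    dM <- dM + dY %*% t(ly$W[[k]])
  }
  dim(dM) <- d
  list(dX = dM, grads = list(W = dW, b = db))
}

## ---- network assembly -----------------------------------------------------

block_init <- function(cin, cout) {
  list(conv1 = conv_init(cin, cout), bn1 = bn_init(cout),
       conv2 = conv_init(cout, cout), bn2 = bn_init(cout))
}

block_fwd <- function(bl, X, train) {
  c1 <- conv_fwd(bl$conv1, X)
  b1 <- bn_fwd(bl$bn1, c1$out, train)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(bl$conv2, r1$out)
  b2 <- bn_fwd(bl$bn2, c2$out, train)
  r2 <- relu_fwd(b2$out)
  list(out = r2$out, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2)
}

block_bwd <- function(bl, cache, dOut) {
  dOut <- dOut * cache$r2$mask
  bb2 <- bn_bwd(bl$bn2, cache$b2, dOut)
  cb2 <- conv_bwd(bl$conv2, cache$c2, bb2$dX)
  dr1 <- cb2$dX * cache$r1$mask
  bb1 <- bn_bwd(bl$bn1, cache$b1, dr1)
  cb1 <- conv_bwd(bl$conv1, cache$c1, bb1$dX)
  list(dX = cb1$dX,
       grads = list(conv1 = cb1$grads, bn1 = bb1$grads,
                    conv2 = cb2$grads, bn2 = bb2$grads))
}

block_run_stats <- function(bl, cache) {
  pairs <- c(bn1 = "b1", bn2 = "b2")
  for (nm in names(pairs)) {
    cc <- cache[[pairs[[nm]]]]
    bl[[nm]]$run_mean <- BN_MOMENTUM * bl[[nm]]$run_mean +
      (1 - BN_MOMENTUM) * cc$batch_mean
    bl[[nm]]$run_var <- BN_MOMENTUM * bl[[nm]]$run_var +
      (1 - BN_MOMENTUM) * cc$batch_var
  }
  bl
}

unet_init <- function(config, in_channels = 3L) {
  f <- config$base_filters; d <- config$depth
  n_classes <- length(config$classes)
  enc <- vector("list", d)
  cin <- in_channels
  for (i in seq_len(d)) {
    enc[[i]] <- block_init(cin, f * 2L^(i - 1L))
    cin <- f * 2L^(i - 1L)
  }
  bott <- block_init(cin, f * 2L^d)
  dec <- vector("list", d)
  cin <- f * 2L^d
  for (i in rev(seq_len(d))) {
    cf <- f * 2L^(i - 1L)
    dec[[i]] <- list(up = tconv_init(cin, cf), block = block_init(2L * cf, cf))
    cin <- cf
  }
  list(enc = enc, bott = bott, dec = dec,
       final = conv1x1_init(cin, n_classes))
}

unet_fwd <- function(net, X, train = FALSE) {
  d <- length(net$enc)
  skips <- vector("list", d); ecache <- vector("list", d)
  pcache <- vector("list", d)
  A <- X
  for (i in seq_len(d)) {
    ecache[[i]] <- block_fwd(net$enc[[i]], A, train)
    skips[[i]] <- ecache[[i]]$out
    pcache[[i]] <- maxpool_fwd(ecache[[i]]$out)
    A <- pcache[[i]]$out
  }
  bcache <- block_fwd(net$bott, A, train)
  A <- bcache$out
  dcache <- vector("list", d)
  for (i in rev(seq_len(d))) {
    up <- tconv_fwd(net$dec[[i]]$up, A)
    nup <- dim(up$out)[4]
    cat_out <- array(0, dim(up$out) + c(0, 0, 0, dim(skips[[i]])[4]))
    cat_out[, , , seq_len(nup)] <- up$out
    cat_out[, , , nup + seq_len(dim(skips[[i]])[4])] <- skips[[i]]
    blk <- block_fwd(net$dec[[i]]$block, cat_out, train)
    dcache[[i]] <- list(up = up, nup = nup, blk = blk)
    A <- blk$out
  }
  fin <- conv1x1_fwd(net$final, A)
  list(logits = fin$out,
       cache = list(ecache = ecache, pcache = pcache, bcache = bcache,
                    dcache = dcache, fin = fin))
}

unet_bwd <- function(net, cache, dLogits) {
  d <- length(net$enc)
  grads <- list(enc = vector("list", d), dec = vector("list", d))
  fb <- conv1x1_bwd(net$final, cache$fin, dLogits)
  grads$final <- fb$grads
  dA <- fb$dX
  dskips <- vector("list", d)
  for (i in seq_len(d)) {  # decoder levels, innermost-out order i=1..d
    dc <- cache$dcache[[i]]
    bb <- block_bwd(net$dec[[i]]$block, dc$blk, dA)
    grads$dec[[i]]$block <- bb$grads
    nup <- dc$nup
    dup <- bb$dX[, , , seq_len(nup), drop = FALSE]
    dskips[[i]] <- bb$dX[, , , nup + seq_len(dim(bb$dX)[4] - nup), drop = FALSE]
    tb <- tconv_bwd(net$dec[[i]]$up, dc$up, dup)
    grads$dec[[i]]$up <- tb$grads
    dA <- tb$dX
  }
  bb <- block_bwd(net$bott, cache$bcache, dA)
  grads$bott <- bb$grads
  dA <- bb$dX
  for (i in rev(seq_len(d))) {
    dpool <- maxpool_bwd(cache$pcache[[i]], dA)
    eb <- block_bwd(net$enc[[i]], cache$ecache[[i]], dpool + dskips[[i]])
    grads$enc[[i]] <- eb$grads
    dA <- eb$dX
  }
  grads
}

unet_update_run_stats <- function(net, cache) {
  d <- length(net$enc)
  for (i in seq_len(d)) {
    net$enc[[i]] <- block_run_stats(net$enc[[i]], cache$ecache[[i]])
    net$dec[[i]]$block <- block_run_stats(net$dec[[i]]$block,
                                          cache$dcache[[i]]$blk)
  }
  net$bott <- block_run_stats(net$bott, cache$bcache)
  net
}

## ---- Adam over the nested parameter tree ----------------------------------

TRAINABLE <- c("W", "b", "gamma", "beta")

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      if (is.null(m)) { m <- p * 0; v <- p * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      return(list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v))
    }
    if (is.null(m)) { m <- vector("list", length(p)); names(m) <- names(p) }
    if (is.null(v)) { v <- vector("list", length(p)); names(v) <- names(p) }
    nm <- names(p)
    for (i in seq_along(p)) {
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
      gi <- g[[key]]
      if (is.null(gi)) next  # non-trainable leaf (running stats, k, ...)
      r <- walk(p[[i]], gi, m[[key]], v[[key]])
      p[[i]] <- r$p; m[[key]] <- r$m; v[[key]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  walk(params, grads, state$m, state$v)
}

## ---- training and prediction ----------------------------------------------

# one-hot encode a padded label map against the class vector
one_hot <- function(labels_list, classes) {
  S <- nrow(labels_list[[1]]); N <- length(labels_list); K <- length(classes)
  Y <- array(0, c(S, S, N, K))
  for (n in seq_len(N)) {
    idx <- match(as.vector(labels_list[[n]]), classes)
    if (anyNA(idx)) stop("label map contains classes the model does not predict",
                         call. = FALSE)
    Y[, , n, ][seq_len(S * S) + (idx - 1L) * S * S] <- 1
  }
  Y
}

softmax_mat <- function(M) {
  M <- M - apply(M, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

#' Train the U-Net tissue segmenter
#'
#' Minimizes per-pixel cross-entropy with Adam. After every epoch the mean
#' validation DSC (pooled over patches and present classes, as in
#' [evaluate_dsc()]) is recorded; training stops when that quantity has not
#' improved by at least `min_gain` relative for `patience` epochs past its
#' best, and the weights from the best epoch — not the last — are returned.
#' Deterministic for a fixed config seed.
#'
#' @param train,validation Lists of `(tile, labels)` pairs (tiles integer RGB
#'   0-255, already stain/histogram normalized when emulating the full
#'   pipeline); tiles are reflect-padded to `config$input_size`.
#' @param config A [unet_config()].
#' @param validation_dsc_fn Optional override used by the stopping-rule tests:
#'   a `function(model, epoch)` returning the validation mean DSC instead of
#'   evaluating the network.
#' @param verbose Print per-epoch progress.
#' @return Object of class `unet_segmenter`: list with the network weights
#'   (`net`, at the best epoch), `config`, `history` (epoch, loss, val_dsc),
#'   `best_epoch`, `stop_epoch`.
#' @export
train_segmenter <- function(train, validation, config,
                            validation_dsc_fn = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "unet_config"))
  if (length(train) < 1L || length(validation) < 1L)
    stop("train and validation sets must be nonempty", call. = FALSE)
  S <- config$input_size
  K <- length(config$classes)
  prep <- function(pairs) {
    X <- array(0, c(S, S, length(pairs), 3L))
    labs <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
      X[, , i, ] <- reflect_pad(pairs[[i]]$tile, S) / 255
      labs[[i]] <- reflect_pad(pairs[[i]]$labels, S)
    }
    list(X = X, labels = labs)
  }
  tr <- prep(train); va <- prep(validation)
  Ytr <- one_hot(tr$labels, config$classes)
  with_seed(config$seed, {
    net <- unet_init(config)
    state <- list(m = NULL, v = NULL)
    t_adam <- 0L
    ntr <- length(train)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_dsc = numeric(0))
    best <- -Inf; best_epoch <- 0L; best_net <- net
    model_of <- function(net) {
      structure(list(net = net, config = config, history = history),
                class = "unet_segmenter")
    }
    stop_epoch <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(ntr)
      epoch_loss <- 0; nbatch <- 0L
      for (b0 in seq(1L, ntr, config$batch_size)) {
        idx <- ord[b0:min(ntr, b0 + config$batch_size - 1L)]
        X <- tr$X[, , idx, , drop = FALSE]
        Y <- Ytr[, , idx, , drop = FALSE]
        fw <- unet_fwd(net, X, train = TRUE)
        P <- softmax_mat(flat(fw$logits))
        Ymat <- flat(Y)
        npix <- nrow(P)
        loss <- -sum(Ymat * log(pmax(P, 1e-12))) / npix
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (batch starting %d); %s",
                       epoch, b0, "check learning rate and input scaling"),
               call. = FALSE)
        }
        dlog <- (P - Ymat) / npix
        dim(dlog) <- dim(fw$logits)
        grads <- unet_bwd(net, fw$cache, dlog)
        net <- unet_update_run_stats(net, fw$cache)
        t_adam <- t_adam + 1L
        up <- adam_step(net, grads, state, config$learning_rate, t_adam)
        net <- up$p; state <- list(m = up$m, v = up$v)
        epoch_loss <- epoch_loss + loss; nbatch <- nbatch + 1L
      }
      dsc <- if (is.null(validation_dsc_fn)) {
        preds <- lapply(seq_len(dim(va$X)[3]), function(i) {
          fw <- unet_fwd(net, va$X[, , i, , drop = FALSE], train = FALSE)
          decode_labels(softmax_probs(fw$logits), config$classes)
        })
        rep_ <- evaluate_dsc(preds, va$labels, config$classes)
        rep_$mean[rep_$class == "Total"]
      } else {
        validation_dsc_fn(model_of(net), epoch)
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = epoch_loss / nbatch,
                                           val_dsc = dsc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val DSC %.4f",
                        epoch, epoch_loss / nbatch, dsc))
      st <- early_stopping_status(history$val_dsc, config$patience,
                                  config$min_gain)
      if (st$best_epoch == epoch) { best_net <- net; best <- dsc }
      best_epoch <- st$best_epoch
      if (st$stopped) { stop_epoch <- epoch; break }
      stop_epoch <- epoch
    }
    structure(list(net = best_net, config = config, history = history,
                   best_epoch = best_epoch, stop_epoch = stop_epoch),
              class = "unet_segmenter")
  })
}

#' @export
print.unet_segmenter <- function(x, ...) {
  count_values <- function(p)
    if (is.list(p)) sum(vapply(p, count_values, numeric(1))) else length(p)
  npar <- count_values(x$net)
  cat(sprintf("U-Net segmenter: depth %d, base %d filters, input %d px, %d classes\n",
              x$config$depth, x$config$base_filters, x$config$input_size,
              length(x$config$classes)))
  cat(sprintf("  ~%d parameters; trained %d epochs (best epoch %d, val DSC %.4f)\n",
              npar, nrow(x$history), x$best_epoch,
              if (x$best_epoch > 0) x$history$val_dsc[x$best_epoch] else NA))
  invisible(x)
}

softmax_probs <- function(logits) {
  d <- dim(logits)
  P <- softmax_mat(flat(logits))
  dim(P) <- d
  P
}

# per-pixel argmax of an [h, w, 1, K] or [h, w, K] probability array
decode_labels <- function(prob, classes) {
  d <- dim(prob)
  if (length(d) == 4L) { dim(prob) <- c(d[1], d[2], d[4]); d <- dim(prob) }
  M <- matrix(prob, d[1] * d[2], d[3])
  matrix(classes[max.col(M, ties.method = "first")], d[1], d[2])
}

#' Predict a label map for a tile
#'
#' Reflect-pads the tile to the network input size (tiling larger images into
#' input-size windows), runs the network in inference mode, crops the padding
#' back and decodes the per-pixel argmax. Optionally forces non-tissue pixels
#' (from [tissue_threshold()]) to background.
#'
#' @param model A trained [train_segmenter()] model.
#' @param tile Integer RGB array `h x w x 3` in 0-255, preprocessed the same
#'   way as the training tiles.
#' @param tissue_mask Optional logical matrix; pixels `FALSE` are set to
#'   `BACKGROUND` in the returned label map.
#' @return List with `prob` (`h x w x K` array, per-pixel softmax, rows sum
#'   to 1) and `labels` (integer label map).
#' @export
predict_labelmap <- function(model, tile, tissue_mask = NULL) {
  stopifnot(inherits(model, "unet_segmenter"))
  S <- model$config$input_size
  d <- dim(tile); h <- d[1]; w <- d[2]
  K <- length(model$config$classes)
  prob <- array(0, c(h, w, K))
  if (h <= S && w <= S) {
    X <- array(reflect_pad(tile, S) / 255, c(S, S, 1L, 3L))
    fw <- unet_fwd(model$net, X, train = FALSE)
    P <- softmax_probs(fw$logits)
    dim(P) <- c(S, S, K)
    prob <- center_crop(P, h, w)
  } else {
    # tile into S x S windows over a padded canvas, stitch, crop
    H2 <- S * ceiling(h / S); W2 <- S * ceiling(w / S)
    big <- array(0L, c(H2, W2, 3L))
    big[seq_len(h), seq_len(w), ] <- tile
    if (h < H2) big[(h + 1L):H2, seq_len(w), ] <-
      tile[reflect_idx(h, 0L, H2 - h)[-seq_len(h)], seq_len(w), , drop = FALSE]
    if (w < W2) big[, (w + 1L):W2, ] <-
      big[, reflect_idx(w, 0L, W2 - w)[-seq_len(w)], , drop = FALSE]
    pbig <- array(0, c(H2, W2, K))
    for (i0 in seq(1L, H2, S)) for (j0 in seq(1L, W2, S)) {
      X <- array(big[i0 + 0:(S - 1L), j0 + 0:(S - 1L), , drop = FALSE] / 255,
                 c(S, S, 1L, 3L))
      fw <- unet_fwd(model$net, X, train = FALSE)
      P <- softmax_probs(fw$logits)
      dim(P) <- c(S, S, K)
      pbig[i0 + 0:(S - 1L), j0 + 0:(S - 1L), ] <- P
    }
    prob <- pbig[seq_len(h), seq_len(w), , drop = FALSE]
  }
  labels <- decode_labels(prob, model$config$classes)
  if (!is.null(tissue_mask)) labels[!tissue_mask] <- TISSUE_CLASSES[["BACKGROUND"]]
  list(prob = prob, labels = labels)
}
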