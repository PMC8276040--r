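# VGG-style convolutional classifier for the four phenotype classes,
# implemented on dense linear algebra (im2col convolutions, 2x2 max
# pooling, batch normalization, dropout, Adam). Two presets: the
# full-scale network (13 convolutional layers, five max-pooling layers,
# two fully connected layers, four-node softmax; 128 x 128 input) and a
# width- and depth-reduced preset for CPU-scale training.

#' Model specification
#'
#' @param preset `"full_vgg16"` (13 conv layers in blocks of 2-2-3-3-3,
#'   five max-pool layers, two 4096-wide fully connected layers, four-node
#'   softmax; input 128) or `"reduced"` (same topology family - 3x3
#'   convolutions, five pooling stages with doubling widths, two fully
#'   connected layers - thinned by `width_factor` and shortened to one
#'   convolution per block for CPU training; input 64).
#' @param input_side square input image side.
#' @param width_factor channel width multiplier for the reduced preset.
#' @param n_classes number of output classes.
#' @return list of class `model_spec` with the per-layer channel plan.
#' @export
model_spec <- function(preset = c("reduced", "full_vgg16"),
                       input_side = NULL, width_factor = NULL,
                       n_classes = 4L) {
  preset <- match.arg(preset)
  if (preset == "full_vgg16") {
    input_side <- input_side %||% 128L
    widths <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512,
                512)
    pool_after <- c(2L, 4L, 7L, 10L, 13L)
    fc <- c(4096L, 4096L)
  } else {
    input_side <- input_side %||% 64L
    width_factor <- width_factor %||% (1 / 8)
    if (width_factor <= 0) stop("width_factor must be positive")
    widths <- pmax(4L, as.integer(round(c(64, 128, 256, 512, 512) *
                                          width_factor)))
    pool_after <- seq_along(widths)
    fc <- rep(pmax(16L, as.integer(round(4096 * width_factor))), 2L)
  }
  if (input_side %% 32L != 0L)
    stop("input side must be divisible by 32 (five pooling stages)")
  structure(list(preset = preset, input_side = as.integer(input_side),
                 width_factor = width_factor, widths = widths,
                 pool_after = pool_after, fc = fc,
                 n_classes = as.integer(n_classes)),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an untrained network from a specification
#'
#' Layer order is convolution, ReLU, batch normalization (normalization
#' after each activation), pooling per the layer plan; then two fully
#' connected layers each followed by ReLU, batch normalization and
#' dropout; then a linear layer to `n_classes` logits (softmax applied in
#' the loss/prediction).
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for He-uniform-initialized weights.
#' @return list of class `cnn_model` with `spec` and `layers`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    layers <- list()
    cin <- 1L
    side <- spec$input_side
    for (i in seq_along(spec$widths)) {
      cout <- spec$widths[i]
      fan_in <- cin * 9
      lim <- sqrt(6 / fan_in)
      layers[[length(layers) + 1L]] <- list(
        type = "conv", cin = cin, cout = cout,
        W = matrix(runif(cout * fan_in, -lim, lim), cout, fan_in),
        b = numeric(cout))
      layers[[length(layers) + 1L]] <- list(type = "relu")
      layers[[length(layers) + 1L]] <- list(
        type = "bn", c = cout, gamma = rep(1, cout), beta = numeric(cout),
        running_mean = numeric(cout), running_var = rep(1, cout))
      if (i %in% spec$pool_after) {
        layers[[length(layers) + 1L]] <- list(type = "pool")
        side <- side %/% 2L
      }
      cin <- cout
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten", c = cin,
                                          side = side)
    din <- side * side * cin
    for (width in spec$fc) {
      lim <- sqrt(6 / din)
      layers[[length(layers) + 1L]] <- list(
        type = "fc", din = din, dout = width,
        W = matrix(runif(width * din, -lim, lim), width, din),
        b = numeric(width))
      layers[[length(layers) + 1L]] <- list(type = "relu")
      layers[[length(layers) + 1L]] <- list(
        type = "bnfc", c = width, gamma = rep(1, width),
        beta = numeric(width), running_mean = numeric(width),
        running_var = rep(1, width))
      layers[[length(layers) + 1L]] <- list(type = "dropout")
      din <- width
    }
    lim <- sqrt(6 / din)
    layers[[length(layers) + 1L]] <- list(
      type = "fc", din = din, dout = spec$n_classes,
      W = matrix(runif(spec$n_classes * din, -lim, lim),
                 spec$n_classes, din),
      b = numeric(spec$n_classes))
    structure(list(spec = spec, layers = layers), class = "cnn_model")
  })
}

#' Count convolutional layers of a model
#' @param model a `cnn_model`.
#' @return integer count.
#' @export
n_conv_layers <- function(model) {
  sum(vapply(model$layers, function(l) l$type == "conv", logical(1)))
}

#' Count trainable parameters of a model
#' @param model a `cnn_model`.
#' @return numeric parameter count.
#' @export
n_parameters <- function(model) {
  s <- 0
  for (l in model$layers) {
    if (l$type %in% c("conv", "fc")) s <- s + length(l$W) + length(l$b)
    if (l$type %in% c("bn", "bnfc")) s <- s + length(l$gamma) +
        length(l$beta)
  }
  s
}

# forward pass; X: array (H, W, N) single-channel. Returns logits (K x N)
# and, when keep_cache, per-layer caches for backprop.
cnn_forward <- function(model, X, training = FALSE, dropout = 0.5,
                        keep_cache = FALSE, bn_momentum = 0.9) {
  N <- dim(X)[3]
  cur <- X
  C <- 1L
  is_cube <- TRUE
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      if (keep_cache) caches[[i]] <- list(X = cur, C = C)
      cur <- cpp_conv_fwd(cur, l$W, l$b, C, N)
      C <- l$cout
    } else if (l$type == "relu") {
      mask <- cur > 0
      cur <- cur * mask
      if (keep_cache) caches[[i]] <- list(mask = mask)
    } else if (l$type == "bn") {
      r <- cpp_bn_fwd(cur, l$gamma, l$beta, C, N, training,
                      l$running_mean, l$running_var, bn_momentum, 1e-5)
      if (training) {
        model$layers[[i]]$running_mean <- as.numeric(r$running_mean)
        model$layers[[i]]$running_var <- as.numeric(r$running_var)
      }
      if (keep_cache) caches[[i]] <- list(xhat = r$xhat,
                                          invstd = as.numeric(r$invstd))
      cur <- r$Y
    } else if (l$type == "pool") {
      if (keep_cache) caches[[i]] <- list(H = dim(cur)[1], W = dim(cur)[2])
      r <- cpp_pool_fwd(cur)
      if (keep_cache) caches[[i]]$argmax <- r$argmax
      cur <- r$Y
    } else if (l$type == "flatten") {
      cur <- cpp_flatten(cur, C, N)
      if (keep_cache) caches[[i]] <- list(H = l$side, W = l$side, C = C)
      is_cube <- FALSE
    } else if (l$type == "fc") {
      if (keep_cache) caches[[i]] <- list(X = cur)
      cur <- l$W %*% cur + l$b
    } else if (l$type == "bnfc") {
      if (training) {
        mu <- rowMeans(cur)
        v <- rowMeans(cur^2) - mu^2
        v[v < 0] <- 0
        model$layers[[i]]$running_mean <-
          bn_momentum * l$running_mean + (1 - bn_momentum) * mu
        model$layers[[i]]$running_var <-
          bn_momentum * l$running_var + (1 - bn_momentum) * v
      } else {
        mu <- l$running_mean
        v <- l$running_var
      }
      invstd <- 1 / sqrt(v + 1e-5)
      xhat <- (cur - mu) * invstd
      cur <- l$gamma * xhat + l$beta
      if (keep_cache) caches[[i]] <- list(xhat = xhat, invstd = invstd)
    } else if (l$type == "dropout") {
      if (training && dropout > 0) {
        mask <- matrix((runif(length(cur)) >= dropout) / (1 - dropout),
                       nrow(cur), ncol(cur))
        cur <- cur * mask
        if (keep_cache) caches[[i]] <- list(mask = mask)
      } else if (keep_cache) caches[[i]] <- list(mask = NULL)
    }
  }
  list(logits = cur, caches = caches, model = model, is_cube = is_cube)
}

softmax_mat <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}

# backward pass; returns list of gradients parallel to model$layers
cnn_backward <- function(model, caches, dlogits, N) {
  grads <- vector("list", length(model$layers))
  cur <- dlogits
  C <- NULL
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (l$type == "fc") {
      X <- caches[[i]]$X
      grads[[i]] <- list(dW = cur %*% t(X), db = rowSums(cur))
      cur <- t(l$W) %*% cur
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) cur <- cur * caches[[i]]$mask
    } else if (l$type == "bnfc") {
      xhat <- caches[[i]]$xhat
      invstd <- caches[[i]]$invstd
      m <- ncol(cur)
      dgamma <- rowSums(cur * xhat)
      dbeta <- rowSums(cur)
      grads[[i]] <- list(dgamma = dgamma, dbeta = dbeta)
      cur <- (l$gamma * invstd / m) *
        (m * cur - dbeta - xhat * dgamma)
    } else if (l$type == "flatten") {
      cur <- cpp_unflatten(cur, caches[[i]]$H, caches[[i]]$W,
                           caches[[i]]$C, N)
    } else if (l$type == "pool") {
      cur <- cpp_pool_bwd(cur, caches[[i]]$argmax, caches[[i]]$H,
                          caches[[i]]$W)
    } else if (l$type == "bn") {
      r <- cpp_bn_bwd(cur, caches[[i]]$xhat, l$gamma, caches[[i]]$invstd,
                      l$c, N)
      grads[[i]] <- list(dgamma = as.numeric(r$dgamma),
                         dbeta = as.numeric(r$dbeta))
      cur <- r$dX
    } else if (l$type == "relu") {
      cur <- cur * caches[[i]]$mask
    } else if (l$type == "conv") {
      r <- cpp_conv_bwd(caches[[i]]$X, l$W, cur, caches[[i]]$C, N)
      grads[[i]] <- list(dW = r$dW, db = as.numeric(r$db))
      cur <- r$dX
    }
  }
  grads
}

#' Training configuration
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param dropout dropout rate on the fully connected layers.
#' @param epochs maximum training epochs.
#' @param folds folds for cross-validated training.
#' @param seed integer seed (fixes weight init, shuffling and dropout).
#' @param augment apply the eight dihedral transforms to training images.
#' @param early_stop_val_acc stop once validation accuracy reaches this
#'   level (compute-budget guard for the easy synthetic fixtures; set to
#'   `Inf`, or above 1, to disable).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         dropout = 0.5, epochs = 30L, folds = 3L,
                         seed = 1L, augment = TRUE,
                         early_stop_val_acc = 0.99) {
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), augment = augment,
                 early_stop_val_acc = early_stop_val_acc),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Deterministic under `seed`; per class, `floor(n * fraction)` items go
#' to validation and test and the remainder to training.
#'
#' @param labels factor (or character) of class labels.
#' @param fractions (train, val, test) fractions summing to 1.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
split_dataset <- function(labels, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1")
  labels <- as.factor(labels)
  with_seed(seed, {
    tr <- va <- te <- integer(0)
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_va <- floor(n * fractions[2])
      n_te <- floor(n * fractions[3])
      va <- c(va, idx[seq_len(n_va)])
      te <- c(te, idx[n_va + seq_len(n_te)])
      tr <- c(tr, idx[-(seq_len(n_va + n_te))])
    }
    list(train = sort(tr), val = sort(va), test = sort(te))
  })
}

# the 8 dihedral transforms of a matrix
d4_transforms <- function(m) {
  r1 <- t(m)[, nrow(m):1, drop = FALSE]          # rot 90
  r2 <- m[nrow(m):1, ncol(m):1, drop = FALSE]    # rot 180
  r3 <- t(m)[ncol(m):1, , drop = FALSE]          # rot 270
  list(m, r1, r2, r3,
       m[, ncol(m):1, drop = FALSE],             # horizontal flip
       m[nrow(m):1, , drop = FALSE],             # vertical flip
       t(m),                                     # transpose
       r2[, ncol(m):1, drop = FALSE])            # anti-transpose
}

#' Dihedral augmentation of an image stack
#'
#' Applies the eight rotation/reflection transforms of the square to each
#' image; labels are replicated accordingly. Apply to training folds
#' only - never to validation or test data.
#'
#' @param images array (side, side, N).
#' @param labels labels of length N.
#' @return list `images` (side, side, 8N), `labels` (length 8N),
#'   `source` (index of the originating image, for leakage checks).
#' @export
augment_dihedral <- function(images, labels) {
  n <- dim(images)[3]
  side <- dim(images)[1]
  out <- array(0, c(side, side, 8L * n))
  for (i in seq_len(n)) {
    tr <- d4_transforms(images[, , i])
    for (k in 1:8) out[, , (i - 1L) * 8L + k] <- tr[[k]]
  }
  list(images = out, labels = rep(labels, each = 8L),
       source = rep(seq_len(n), each = 8L))
}

#' Train a network
#'
#' Minibatch Adam with softmax cross-entropy. Records per-epoch training
#' loss, validation loss and validation accuracy; optionally stops early
#' once validation accuracy reaches `cfg$early_stop_val_acc`.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param x_train,y_train training images (side, side, N) and labels.
#' @param x_val,y_val validation data (disjoint from training).
#' @param cfg a [train_config()]; when `cfg$augment` is `TRUE` the
#'   training set is expanded with [augment_dihedral()] first.
#' @return list: `model` (trained), `history` (data.frame epoch,
#'   train_loss, val_loss, val_acc).
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val,
                      cfg = train_config()) {
  if (dim(x_train)[3] == 0L) stop("empty training set")
  y_train <- factor(y_train, levels = phenotype_classes())
  y_val <- factor(y_val, levels = phenotype_classes())
  if (cfg$augment) {
    aug <- augment_dihedral(x_train, y_train)
    x_train <- aug$images
    y_train <- aug$labels
  }
  K <- model$spec$n_classes
  Y <- diag(K)[, as.integer(y_train), drop = FALSE]
  n <- dim(x_train)[3]
  state <- new_adam_state(model)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- x_train[, , idx, drop = FALSE]
        yb <- Y[, idx, drop = FALSE]
        fw <- cnn_forward(model, xb, training = TRUE,
                          dropout = cfg$dropout, keep_cache = TRUE)
        model <- fw$model # updated BN running stats
        p <- softmax_mat(fw$logits)
        losses <- c(losses, -mean(colSums(yb * log(pmax(p, 1e-12)))))
        dlogits <- (p - yb) / length(idx)
        grads <- cnn_backward(model, fw$caches, dlogits, length(idx))
        upd <- adam_update(model, grads, state, cfg$learning_rate)
        model <- upd$model
        state <- upd$state
      }
      ev <- evaluate_cnn(model, x_val, y_val,
                         batch_size = cfg$batch_size)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  val_loss = ev$loss,
                                  val_acc = ev$accuracy))
      if (ev$accuracy >= cfg$early_stop_val_acc) break
    }
  })
  list(model = model, history = history)
}

new_adam_state <- function(model) {
  st <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type %in% c("conv", "fc"))
      st[[i]] <- list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0,
                      vb = l$b * 0)
    if (l$type %in% c("bn", "bnfc"))
      st[[i]] <- list(mg = l$gamma * 0, vg = l$gamma * 0,
                      mb = l$beta * 0, vb = l$beta * 0)
  }
  list(t = 0L, layers = st)
}

adam_update <- function(model, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(m = m, v = v, d = lr * (m / bc1) / (sqrt(v / bc2) + eps))
  }
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- model$layers[[i]]
    s <- state$layers[[i]]
    if (l$type %in% c("conv", "fc")) {
      rW <- step(s$mW, s$vW, g$dW)
      rb <- step(s$mb, s$vb, g$db)
      model$layers[[i]]$W <- l$W - rW$d
      model$layers[[i]]$b <- l$b - rb$d
      state$layers[[i]] <- list(mW = rW$m, vW = rW$v, mb = rb$m, vb = rb$v)
    } else if (l$type %in% c("bn", "bnfc")) {
      rg <- step(s$mg, s$vg, g$dgamma)
      rb <- step(s$mb, s$vb, g$dbeta)
      model$layers[[i]]$gamma <- l$gamma - rg$d
      model$layers[[i]]$beta <- l$beta - rb$d
      state$layers[[i]] <- list(mg = rg$m, vg = rg$v, mb = rb$m, vb = rb$v)
    }
  }
  list(model = model, state = state)
}

#' Predict class probabilities for an image stack
#'
#' @param model a trained `cnn_model`.
#' @param images array (side, side, N) matching the training input side.
#' @param batch_size prediction batch size.
#' @return list: `labels` (factor in the fixed class order; ties broken
#'   by class order), `probs` (N x 4 matrix, rows summing to 1).
#' @export
predict_cnn <- function(model, images, batch_size = 64L) {
  side <- model$spec$input_side
  if (dim(images)[1] != side || dim(images)[2] != side)
    stop("input side ", dim(images)[1], " does not match the model (",
         side, ")")
  n <- dim(images)[3]
  probs <- matrix(0, n, model$spec$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- cnn_forward(model, images[, , idx, drop = FALSE],
                      training = FALSE)
    probs[idx, ] <- t(softmax_mat(fw$logits))
  }
  colnames(probs) <- phenotype_classes()
  lab <- factor(phenotype_classes()[apply(probs, 1L, which.max)],
                levels = phenotype_classes())
  list(labels = lab, probs = probs)
}

#' Evaluate a network on a labelled test set
#'
#' @param model a trained `cnn_model`.
#' @param images array (side, side, N).
#' @param labels true labels.
#' @param batch_size prediction batch size.
#' @return list: `accuracy`, `loss` (mean cross-entropy), `confusion`
#'   (4 x 4 matrix, rows = true class, columns = predicted class),
#'   `per_class_recall`.
#' @export
evaluate_cnn <- function(model, images, labels, batch_size = 64L) {
  if (dim(images)[3] == 0L) stop("empty test set")
  labels <- factor(labels, levels = phenotype_classes())
  pr <- predict_cnn(model, images, batch_size)
  cm <- table(true = labels, predicted = pr$labels)
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(true = phenotype_classes(),
                               predicted = phenotype_classes()))
  p_true <- pr$probs[cbind(seq_along(labels), as.integer(labels))]
  list(accuracy = sum(diag(cm)) / sum(cm),
       loss = -mean(log(pmax(p_true, 1e-12))),
       confusion = cm,
       per_class_recall = diag(cm) / pmax(rowSums(cm), 1L))
}

#' Prepare a segmented cell for classification
#'
#' Crops the cell to its bounding box, pads to a square preserving the
#' aspect ratio, and rescales to `side` x `side`. In `"mask"` mode the
#' result is tri-level (background 0, processes mid-level, soma
#' max-level); in `"gray"` mode the grayscale crop is used.
#'
#' @param cell a `cell_extract`.
#' @param mode `"mask"` or `"gray"`.
#' @param side output side (128 for the full-scale network).
#' @return `side` x `side` numeric matrix in \[0, 1\].
#' @export
prepare_input <- function(cell, mode = c("mask", "gray"), side = 128L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cell, "cell_extract"))
  if (sum(cell$cell_mask) == 0L) stop("empty cell")
  side <- as.integer(side)
  if (mode == "mask") {
    # rescale cell and soma masks separately and re-threshold so the
    # output stays exactly tri-level (no edge antialiasing)
    cm <- pad_square(cell$cell_mask + 0)
    sm <- pad_square(cell$soma_mask + 0)
    cmr <- cpp_rescale(cm, side, side) >= 0.5
    smr <- cpp_rescale(sm, side, side) >= 0.5
    img <- matrix(0, side, side)
    img[cmr] <- 0.5
    img[smr] <- 1
    return(img)
  }
  cpp_rescale(pad_square(cell$gray_crop), side, side)
}

# center a matrix in a square zero canvas (aspect-preserving pad)
pad_square <- function(img) {
  sq <- max(dim(img))
  pad <- matrix(0, sq, sq)
  r0 <- floor((sq - nrow(img)) / 2)
  c0 <- floor((sq - ncol(img)) / 2)
  pad[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))] <- img
  pad
}

#' Cross-validated training
#'
#' Folds are formed at source-image level before augmentation, so
#' augmented variants of one image never straddle a fold boundary.
#'
#' @param images array (side, side, N); @param labels labels of length N.
#' @param model_spec a [model_spec()].
#' @param cfg a [train_config()]; `cfg$folds` folds are trained.
#' @param leaky_order reproduce the literal augment-then-fold order (for
#'   comparison only; introduces train/validation leakage).
#' @return list of per-fold results from [train_cnn()] plus
#'   `fold_accuracy`.
#' @export
train_cv <- function(images, labels, model_spec, cfg = train_config(),
                     leaky_order = FALSE) {
  labels <- factor(labels, levels = phenotype_classes())
  n <- dim(images)[3]
  if (leaky_order) {
    aug <- augment_dihedral(images, labels)
    images <- aug$images
    labels <- aug$labels
    n <- dim(images)[3]
    cfg$augment <- FALSE
  }
  folds <- with_seed(cfg$seed, sample(rep_len(seq_len(cfg$folds), n)))
  out <- vector("list", cfg$folds)
  for (k in seq_len(cfg$folds)) {
    tr <- which(folds != k)
    va <- which(folds == k)
    model <- build_model(model_spec, seed = cfg$seed + k)
    out[[k]] <- train_cnn(model, images[, , tr, drop = FALSE], labels[tr],
                          images[, , va, drop = FALSE], labels[va], cfg)
  }
  list(folds = out,
       fold_accuracy = vapply(out, function(f)
         f$history$val_acc[nrow(f$history)], numeric(1)))
}

#' Save / load a model as JSON (text checkpoint)
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `path` (save) or the restored `cnn_model` (load).
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(serialize_model(model), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

serialize_model <- function(model) {
  list(spec = unclass(model$spec),
       layers = lapply(model$layers, function(l) {
         if (l$type %in% c("conv", "fc"))
           l$W <- list(dim = dim(l$W), data = as.numeric(l$W))
         l
       }))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- lapply(obj$spec, function(x)
    if (is.list(x)) unlist(x) else x)
  spec$input_side <- as.integer(spec$input_side)
  spec$n_classes <- as.integer(spec$n_classes)
  class(spec) <- "model_spec"
  num <- function(x) as.numeric(unlist(x))
  layers <- lapply(obj$layers, function(l) {
    out <- list(type = l$type)
    for (f in setdiff(names(l), c("type", "W"))) {
      v <- l[[f]]
      out[[f]] <- if (f %in% c("cin", "cout", "din", "dout", "c"))
        as.integer(unlist(v)) else num(v)
    }
    if (!is.null(l$W)) {
      d <- as.integer(unlist(l$W$dim))
      out$W <- matrix(num(l$W$data), d[1], d[2])
    }
    out
  })
  structure(list(spec = spec, layers = layers), class = "cnn_model")
}
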