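# ------------------------------------------------------------------------
# Compact feed-forward neural-network engine: dense, 3x3 same-padding 2-D
# convolution, 2x2 max-pooling, flatten; softmax output with categorical
# cross-entropy; Adam optimizer with mini-batches. Written in base R matrix
# operations (convolution via im2col). Sized for the small networks and
# desk-scale cohorts this package trains; not a general-purpose framework.
# ------------------------------------------------------------------------

#' Layer constructors for [nn_network()]
#'
#' `nn_dense(units, activation)` — fully connected layer;
#' `nn_conv2d(filters)` — 3x3 2-D convolution, "same" padding, relu;
#' `nn_maxpool()` — 2x2 max-pooling (stride 2, floor semantics);
#' `nn_flatten()` — flattens feature maps to a vector.
#'
#' @param units,filters layer width / number of filters.
#' @param activation `"relu"`, `"linear"` or `"softmax"` (output layer).
#' @param kernel convolution kernel size (square).
#' @param size pooling window.
#' @return a layer spec (list) consumed by [nn_network()].
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
nn_dense <- function(units, activation = c("relu", "linear", "softmax")) {
  list(type = "dense", units = as.integer(units),
       activation = match.arg(activation))
}

#' @rdname nn_layers
#' @export
nn_conv2d <- function(filters, kernel = 3, activation = "relu") {
  stopifnot(kernel %% 2 == 1)
  list(type = "conv2d", filters = as.integer(filters),
       kernel = as.integer(kernel), activation = activation)
}

#' @rdname nn_layers
#' @export
nn_maxpool <- function(size = 2) list(type = "maxpool", size = as.integer(size))

#' @rdname nn_layers
#' @export
nn_flatten <- function() list(type = "flatten")

#' Build and initialize a feed-forward network
#'
#' @param input_shape integer vector: a single length (feature-vector input)
#'   or `c(height, width)` / `c(height, width, channels)` (image input).
#' @param layers list of layer specs (see [nn_layers]).
#' @param seed integer seed for the (He-uniform) weight initialization.
#' @return object of class `octnet`.
#' @export
nn_network <- function(input_shape, layers, seed = 1) {
  set.seed(seed)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  shape <- input_shape
  params <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      if (length(shape) != 1L) {
        stop("dense layer needs a flat input; add nn_flatten() first",
             call. = FALSE)
      }
      fan_in <- shape
      lim <- sqrt(6 / fan_in)
      params[[i]] <- list(
        W = matrix(stats::runif(fan_in * ly$units, -lim, lim), fan_in, ly$units),
        b = numeric(ly$units))
      shape <- ly$units
    } else if (ly$type == "conv2d") {
      if (length(shape) != 3L) stop("conv2d layer needs an image input",
                                    call. = FALSE)
      fan_in <- ly$kernel^2 * shape[3]
      lim <- sqrt(6 / fan_in)
      params[[i]] <- list(
        W = matrix(stats::runif(fan_in * ly$filters, -lim, lim),
                   fan_in, ly$filters),
        b = numeric(ly$filters))
      shape <- c(shape[1], shape[2], ly$filters)
    } else if (ly$type == "maxpool") {
      if (length(shape) != 3L) stop("maxpool needs an image input", call. = FALSE)
      out <- shape[1:2] %/% ly$size
      if (any(out < 1)) {
        stop("input too small: pooling exhausts a spatial dimension",
             call. = FALSE)
      }
      shape <- c(out, shape[3])
    } else if (ly$type == "flatten") {
      shape <- prod(shape)
    } else stop("unknown layer type '", ly$type, "'", call. = FALSE)
  }
  if (length(shape) != 1L) {
    stop("network must end in a flat (dense) output", call. = FALSE)
  }
  structure(list(input_shape = input_shape, layers = layers, params = params,
                 output_units = shape),
            class = "octnet")
}

#' @export
print.octnet <- function(x, ...) {
  cat(sprintf("octnet: input %s -> %d layer(s) -> %d output unit(s)\n",
              paste(x$input_shape, collapse = "x"), length(x$layers),
              x$output_units))
  invisible(x)
}

.relu <- function(x) { x[x < 0] <- 0; x }

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# im2col for a (H, W, C) array, odd square kernel, same (zero) padding:
# returns (H*W) x (k*k*C) matrix whose row j holds the receptive field of
# output pixel j (column-major over H then W).
.im2col <- function(a, k) {
  d <- dim(a)
  H <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  pad <- array(0, c(H + 2L * p, W + 2L * p, C))
  pad[p + seq_len(H), p + seq_len(W), ] <- a
  cols <- matrix(0, H * W, k * k * C)
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    j <- j + 1L
    cols[, j] <- as.vector(pad[(dy - 1L) + seq_len(H), (dx - 1L) + seq_len(W), c])
  }
  cols
}

# adjoint of .im2col: scatter-add column gradients back onto the input
.col2im <- function(dcols, H, W, C, k) {
  p <- (k - 1L) %/% 2L
  pad <- array(0, c(H + 2L * p, W + 2L * p, C))
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    j <- j + 1L
    pad[(dy - 1L) + seq_len(H), (dx - 1L) + seq_len(W), c] <-
      pad[(dy - 1L) + seq_len(H), (dx - 1L) + seq_len(W), c] +
      matrix(dcols[, j], H, W)
  }
  pad[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

# forward pass; x: matrix n x d (flat input) or list of (H, W, C) arrays.
# Returns list(prob, caches) when cache = TRUE.
.nn_forward <- function(net, x, cache = FALSE) {
  caches <- if (cache) vector("list", length(net$layers))
  cur <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      z <- sweep(cur %*% net$params[[i]]$W, 2, net$params[[i]]$b, `+`)
      out <- switch(ly$activation,
                    relu = .relu(z), linear = z, softmax = .softmax_rows(z))
      if (cache) caches[[i]] <- list(input = cur, z = z)
      cur <- out
    } else if (ly$type == "conv2d") {
      k <- ly$kernel
      res <- lapply(cur, function(a) {
        cols <- .im2col(a, k)
        z <- sweep(cols %*% net$params[[i]]$W, 2, net$params[[i]]$b, `+`)
        list(cols = cols, z = z, dim = dim(a))
      })
      if (cache) caches[[i]] <- res
      cur <- lapply(res, function(r) {
        array(.relu(r$z), c(r$dim[1], r$dim[2], ncol(r$z)))
      })
    } else if (ly$type == "maxpool") {
      s <- ly$size
      res <- lapply(cur, function(a) .maxpool_fwd(a, s))
      if (cache) caches[[i]] <- res
      cur <- lapply(res, `[[`, "out")
    } else if (ly$type == "flatten") {
      dims <- lapply(cur, dim)
      if (cache) caches[[i]] <- dims
      cur <- do.call(rbind, lapply(cur, as.vector))
    }
  }
  if (cache) list(prob = cur, caches = caches) else cur
}

.maxpool_fwd <- function(a, s) {
  d <- dim(a)
  Ho <- d[1] %/% s; Wo <- d[2] %/% s; C <- d[3]
  out <- array(-Inf, c(Ho, Wo, C))
  which_dy <- array(1L, c(Ho, Wo, C))
  which_dx <- array(1L, c(Ho, Wo, C))
  for (dy in seq_len(s)) for (dx in seq_len(s)) {
    sub <- a[seq(dy, by = s, length.out = Ho),
             seq(dx, by = s, length.out = Wo), , drop = FALSE]
    better <- sub > out
    out[better] <- sub[better]
    which_dy[better] <- dy
    which_dx[better] <- dx
  }
  list(out = out, which_dy = which_dy, which_dx = which_dx, in_dim = d, s = s)
}

.maxpool_bwd <- function(cache, dout) {
  d <- cache$in_dim; s <- cache$s
  Ho <- dim(dout)[1]; Wo <- dim(dout)[2]; C <- d[3]
  dx_full <- array(0, d)
  for (dy in seq_len(s)) for (dx in seq_len(s)) {
    sel <- cache$which_dy == dy & cache$which_dx == dx
    if (!any(sel)) next
    grad <- array(0, dim(dout))
    grad[sel] <- dout[sel]
    rows <- seq(dy, by = s, length.out = Ho)
    cols <- seq(dx, by = s, length.out = Wo)
    dx_full[rows, cols, ] <- dx_full[rows, cols, ] + grad
  }
  dx_full
}

# one forward + backward pass on a batch; returns loss and gradients
.nn_backprop <- function(net, x, y) {
  fw <- .nn_forward(net, x, cache = TRUE)
  p <- fw$prob
  n <- nrow(y)
  loss <- -mean(rowSums(y * log(pmax(p, 1e-12))))
  grads <- vector("list", length(net$layers))
  delta <- (p - y) / n   # matrix n x K (softmax + cross-entropy)
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      cache <- fw$caches[[i]]
      if (ly$activation == "relu") delta <- delta * (cache$z > 0)
      grads[[i]] <- list(W = crossprod(cache$input, delta),
                         b = colSums(delta))
      delta <- delta %*% t(net$params[[i]]$W)
    } else if (ly$type == "flatten") {
      dims <- fw$caches[[i]]
      delta <- lapply(seq_along(dims), function(j) {
        array(delta[j, ], dims[[j]])
      })
    } else if (ly$type == "maxpool") {
      caches <- fw$caches[[i]]
      delta <- lapply(seq_along(caches), function(j) {
        .maxpool_bwd(caches[[j]], delta[[j]])
      })
    } else if (ly$type == "conv2d") {
      caches <- fw$caches[[i]]
      k <- ly$kernel
      dW <- matrix(0, nrow(net$params[[i]]$W), ncol(net$params[[i]]$W))
      db <- numeric(ly$filters)
      new_delta <- vector("list", length(caches))
      for (j in seq_along(caches)) {
        cj <- caches[[j]]
        dmat <- matrix(delta[[j]], nrow(cj$z), ncol(cj$z)) * (cj$z > 0)
        dW <- dW + crossprod(cj$cols, dmat)
        db <- db + colSums(dmat)
        dcols <- dmat %*% t(net$params[[i]]$W)
        new_delta[[j]] <- .col2im(dcols, cj$dim[1], cj$dim[2], cj$dim[3], k)
      }
      grads[[i]] <- list(W = dW, b = db)
      delta <- new_delta
    }
  }
  list(loss = loss, grads = grads)
}

#' Train a network with Adam and categorical cross-entropy
#'
#' Mini-batch gradient descent with the Adam update (learning rate 0.001 by
#' default), categorical cross-entropy on a softmax output, batch size 32,
#' seeded shuffling. When `validation_split > 0`, a held-back slice of the
#' training data is scored each epoch and the parameters with the best
#' validation loss are kept.
#'
#' @param net an `octnet`.
#' @param x inputs: matrix (n x features) or list of (H, W, C) arrays.
#' @param y class labels: factor/character/integer vector, or an n x K
#'   one-hot matrix.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param validation_split fraction held back for checkpointing (0 to 0.5).
#' @param seed integer seed (shuffling and the validation split).
#' @param augment optional function `function(x_batch)` applied to each
#'   training mini-batch (data augmentation); `NULL` for none.
#' @return the trained `octnet`, with a `history` element (per-epoch train /
#'   validation loss) and `classes` (when `y` was a label vector).
#' @export
nn_train <- function(net, x, y, epochs = 30, batch_size = 32, lr = 0.001,
                     validation_split = 0.1, seed = 1, augment = NULL) {
  stopifnot(epochs > 0)
  classes <- NULL
  if (!is.matrix(y)) {
    f <- factor(y)
    classes <- levels(f)
    y <- diag(nlevels(f))[as.integer(f), , drop = FALSE]
  }
  n <- nrow(y)
  get_x <- function(idx) if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  set.seed(seed)
  val_idx <- integer(0)
  if (validation_split > 0 && n >= 10) {
    val_idx <- sample(n, max(1, round(validation_split * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  m_state <- v_state <- lapply(net$params, function(p) {
    if (is.null(p)) NULL else lapply(p, function(q) q * 0)
  })
  t_step <- 0
  best <- list(loss = Inf, params = net$params)
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_idx)
    losses <- c()
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, length(ord))]
      xb <- get_x(idx)
      if (!is.null(augment)) xb <- augment(xb)
      bp <- .nn_backprop(net, xb, y[idx, , drop = FALSE])
      losses <- c(losses, bp$loss)
      t_step <- t_step + 1
      for (i in seq_along(net$params)) {
        if (is.null(net$params[[i]])) next
        for (nm in names(net$params[[i]])) {
          g <- bp$grads[[i]][[nm]]
          m_state[[i]][[nm]] <- 0.9 * m_state[[i]][[nm]] + 0.1 * g
          v_state[[i]][[nm]] <- 0.999 * v_state[[i]][[nm]] + 0.001 * g^2
          mhat <- m_state[[i]][[nm]] / (1 - 0.9^t_step)
          vhat <- v_state[[i]][[nm]] / (1 - 0.999^t_step)
          net$params[[i]][[nm]] <- net$params[[i]][[nm]] -
            lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
    }
    history$train_loss[ep] <- mean(losses)
    if (length(val_idx)) {
      pv <- .nn_forward(net, get_x(val_idx))
      vl <- -mean(rowSums(y[val_idx, , drop = FALSE] * log(pmax(pv, 1e-12))))
      history$val_loss[ep] <- vl
      if (vl < best$loss) best <- list(loss = vl, params = net$params)
    }
  }
  if (length(val_idx) && is.finite(best$loss)) net$params <- best$params
  net$history <- history
  net$classes <- classes
  net
}

#' Predict class probabilities
#'
#' @param net a (trained) `octnet`.
#' @param x inputs as in [nn_train()].
#' @return matrix n x K of probabilities (rows sum to 1); column names are
#'   the training classes when known.
#' @export
nn_predict <- function(net, x) {
  p <- .nn_forward(net, x)
  if (!is.null(net$classes)) colnames(p) <- net$classes
  p
}
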