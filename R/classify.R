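#' The four tumor/healthy classification tasks
#'
#' Task I separates healthy white matter from highly infiltrated white
#' matter; each later task adds data and difficulty:
#' \describe{
#'   \item{I}{WM>60% (tumor) vs WM0% (healthy)}
#'   \item{II}{adds WM30-60% to the tumor side}
#'   \item{III}{adds WM0-30% to the tumor side}
#'   \item{IV}{adds GM0% to the healthy side}
#' }
#'
#' @param task_id `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return list with `task_id`, `positive_labels` (tumor side) and
#'   `negative_labels` (healthy side); the sides are disjoint.
#' @export
classification_task <- function(task_id = c("I", "II", "III", "IV")) {
  task_id <- match.arg(task_id)
  pos <- switch(task_id,
                I = "WM>60%",
                II = c("WM>60%", "WM30-60%"),
                III = c("WM>60%", "WM30-60%", "WM0-30%"),
                IV = c("WM>60%", "WM30-60%", "WM0-30%"))
  neg <- switch(task_id, I = , II = , III = "WM0%",
                IV = c("WM0%", "GM0%"))
  list(task_id = task_id, positive_labels = pos, negative_labels = neg)
}

#' Assemble a binary dataset for one classification task
#'
#' Filters a fits table (or patch manifest) to the task's labels and
#' binarizes them to `"tumor"` / `"healthy"`, preserving provenance.
#'
#' @param table data.frame with at least `label`, `patient_id`, `sample_id`
#'   columns (e.g. from [batch_fit()]).
#' @param task a task from [classification_task()] or a task id string.
#' @return the filtered data.frame with an added factor column `class`
#'   (levels healthy, tumor) and an attribute `"task_id"`; row order is
#'   preserved, and a `row_index` column records the source rows (so
#'   aligned patch lists can be subset identically).
#' @export
assemble_task <- function(table, task) {
  if (is.character(task)) task <- classification_task(task)
  stopifnot(is.data.frame(table),
            all(c("label", "patient_id", "sample_id") %in% names(table)))
  keep <- table$label %in% c(task$positive_labels, task$negative_labels)
  out <- table[keep, , drop = FALSE]
  out$row_index <- which(keep)
  out$class <- factor(ifelse(out$label %in% task$positive_labels,
                             "tumor", "healthy"),
                      levels = c("healthy", "tumor"))
  for (side in c("healthy", "tumor")) {
    if (!any(out$class == side)) {
      stop("task ", task$task_id, ": the '", side,
           "' side has zero examples", call. = FALSE)
    }
  }
  attr(out, "task_id") <- task$task_id
  out
}

#' Rebalance a training set by random duplication
#'
#' Two seeded passes of duplication with replacement, never deletion:
#' first every under-represented sample is topped up to the patch count of
#' the most prominent sample, then every under-represented class is topped
#' up to the count of the most prominent class. After both passes the class
#' counts are equal.
#'
#' @param train data.frame with `sample_id` and `class` columns.
#' @param seed integer seed.
#' @return data.frame of the resampled training set (original rows plus
#'   duplicates).
#' @export
rebalance <- function(train, seed = 1) {
  stopifnot(all(c("sample_id", "class") %in% names(train)))
  set.seed(seed)
  # pass 1: per-sample duplication to the most prominent sample
  counts <- table(train$sample_id)
  target <- max(counts)
  extra <- lapply(names(counts), function(s) {
    need <- target - counts[[s]]
    if (need <= 0) return(NULL)
    rows <- which(train$sample_id == s)
    train[sample(rows, need, replace = TRUE), , drop = FALSE]
  })
  out <- rbind(train, do.call(rbind, extra))
  # pass 2: per-class duplication to the most prominent class
  ccounts <- table(out$class)
  ctarget <- max(ccounts)
  extra2 <- lapply(names(ccounts), function(cl) {
    need <- ctarget - ccounts[[cl]]
    if (need <= 0) return(NULL)
    rows <- which(out$class == cl)
    out[sample(rows, need, replace = TRUE), , drop = FALSE]
  })
  out <- rbind(out, do.call(rbind, extra2))
  rownames(out) <- NULL
  out
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fp,tn,fn nonnegative confusion counts (tumor = positive).
#' @return list with `sensitivity` (TP / (TP + FN)) and `specificity`
#'   (TN / (TN + FP)); an undefined ratio (zero denominator) is `NA`.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Optical-feature classifier (two fully connected layers)
#'
#' Takes the two optical features (attenuation coefficient mu and
#' backscattered intensity I0) of a patch and outputs a two-way class
#' probability through two hidden fully connected layers and a softmax
#' output.
#'
#' @param hidden widths of the two hidden layers.
#' @param seed weight-initialization seed.
#' @return an `octnet` with input size 2 and a 2-way probability output.
#' @export
build_fcnn <- function(hidden = c(32, 32), seed = 1) {
  stopifnot(length(hidden) == 2)
  nn_network(2L, list(
    nn_dense(hidden[1], "relu"),
    nn_dense(hidden[2], "relu"),
    nn_dense(2L, "softmax")
  ), seed = seed)
}

#' Image-patch classifier (VGG-style convolutional network)
#'
#' Four convolutional blocks of (2, 2, 3, 3) convolution layers with
#' (64, 128, 256, 512) filters, 3x3 kernels, same padding and relu, each
#' block closed by 2x2 max-pooling; then flatten and two fully connected
#' layers (256, 64) before the softmax output. Inputs smaller than 16
#' pixels in either dimension are rejected (four poolings would exhaust
#' them).
#'
#' @param input_shape `c(height, width)` of the patch in pixels (50 x 50 on
#'   the "ss" profile, 100 x 50 on "sd").
#' @param filters filter counts of the four blocks.
#' @param layers_per_block convolution layers per block.
#' @param dense widths of the two fully connected head layers.
#' @param seed weight-initialization seed.
#' @return an `octnet` with a 2-way probability output.
#' @export
build_cnn <- function(input_shape, filters = c(64, 128, 256, 512),
                      layers_per_block = c(2, 2, 3, 3),
                      dense = c(256, 64), seed = 1) {
  stopifnot(length(input_shape) == 2, length(filters) == length(layers_per_block))
  if (any(input_shape < 16)) {
    stop("input must be at least 16 px in each dimension (", length(filters),
         " max-pool stages)", call. = FALSE)
  }
  layers <- list()
  for (b in seq_along(filters)) {
    for (l in seq_len(layers_per_block[b])) {
      layers[[length(layers) + 1L]] <- nn_conv2d(filters[b])
    }
    layers[[length(layers) + 1L]] <- nn_maxpool(2)
  }
  layers[[length(layers) + 1L]] <- nn_flatten()
  layers[[length(layers) + 1L]] <- nn_dense(dense[1], "relu")
  layers[[length(layers) + 1L]] <- nn_dense(dense[2], "relu")
  layers[[length(layers) + 1L]] <- nn_dense(2L, "softmax")
  nn_network(c(input_shape, 1L), layers, seed = seed)
}

#' Training configuration
#'
#' Defaults follow the protocol used throughout the package: Adam with
#' learning rate 0.001, categorical cross-entropy, batch size 32,
#' horizontal flip + shift augmentation (image inputs), zero-mean input
#' standardization.
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param augment logical: augment training batches (image inputs only).
#' @param shift_frac maximum horizontal shift as a fraction of patch width.
#' @param validation_split held-back fraction for checkpointing.
#' @param hidden FCNN hidden widths.
#' @param cnn_args named list of overrides for [build_cnn()] (`filters`,
#'   `layers_per_block`, `dense`); empty for the full architecture.
#' @param seed root seed for training.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 32, lr = 0.001,
                         augment = TRUE, shift_frac = 0.1,
                         validation_split = 0.1, hidden = c(32, 32),
                         cnn_args = list(), seed = 1) {
  stopifnot(epochs > 0, batch_size > 0, lr > 0)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 augment = augment, shift_frac = shift_frac,
                 validation_split = validation_split, hidden = hidden,
                 cnn_args = cnn_args, seed = seed),
            class = "train_config")
}

# random horizontal flip + horizontal shift (edge replication) on a list of
# (H, W, 1) arrays
.augment_images <- function(xs, shift_frac = 0.1) {
  lapply(xs, function(a) {
    W <- dim(a)[2]
    if (stats::runif(1) < 0.5) a <- a[, W:1, , drop = FALSE]
    smax <- floor(shift_frac * W)
    if (smax > 0) {
      s <- sample(-smax:smax, 1)
      if (s != 0) {
        idx <- pmin(pmax(seq_len(W) - s, 1L), W)
        a <- a[, idx, , drop = FALSE]
      }
    }
    a
  })
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: that patient's patches form the test set and every
#' other patient's the training set. Rebalancing ([rebalance()]) and
#' augmentation are applied to the training fold only; inputs are
#' standardized to zero mean (feature-wise centering on training-fold means
#' for optical features; per-image mean subtraction for patches). Per-fold
#' confusion counts, sensitivity and specificity are returned together with
#' their mean and standard deviation across folds.
#'
#' @param dataset an assembled task table from [assemble_task()] — for the
#'   `"fcnn"` classifier it must carry `mu` and `i0` columns.
#' @param classifier `"fcnn"` (optical features) or `"cnn"` (image patches).
#' @param config a [train_config()].
#' @param patches list of `oct_patch` aligned with the *source* table rows
#'   (indexed by `dataset$row_index`); required for `"cnn"`.
#' @return object of class `lopo_result`: `folds` (data.frame: patient,
#'   counts, sensitivity, specificity, skipped/reason), `mean_sensitivity`,
#'   `sd_sensitivity`, `mean_specificity`, `sd_specificity`, `task_id`,
#'   `classifier`.
#' @export
run_lopo_cv <- function(dataset, classifier = c("fcnn", "cnn"),
                        config = train_config(), patches = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(is.data.frame(dataset), "class" %in% names(dataset))
  patients <- unique(dataset$patient_id)
  if (length(patients) < 2) {
    stop("leave-one-patient-out needs at least 2 patients", call. = FALSE)
  }
  if (classifier == "fcnn" && !all(c("mu", "i0") %in% names(dataset))) {
    stop("fcnn needs 'mu' and 'i0' feature columns", call. = FALSE)
  }
  if (classifier == "cnn" && is.null(patches)) {
    stop("cnn needs the aligned patch list", call. = FALSE)
  }
  get_images <- function(rows) {
    lapply(dataset$row_index[rows], function(j) {
      px <- patches[[j]]$pixels
      a <- array(px, c(nrow(px), ncol(px), 1L))
      a - mean(a)   # per-image zero-mean standardization
    })
  }
  folds <- data.frame(patient = patients, tp = NA_integer_, fp = NA_integer_,
                      tn = NA_integer_, fn = NA_integer_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      skipped = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
  for (k in seq_along(patients)) {
    test_rows <- which(dataset$patient_id == patients[k])
    train_rows <- which(dataset$patient_id != patients[k])
    stopifnot(!any(train_rows %in% test_rows))
    tr <- dataset[train_rows, , drop = FALSE]
    tr$.row <- train_rows
    if (length(unique(tr$class)) < 2) {
      folds$skipped[k] <- TRUE
      folds$reason[k] <- "training split lacks a class"
      next
    }
    fold_seed <- (config$seed + 1009L * k) %% .Machine$integer.max
    tr <- rebalance(tr, seed = fold_seed)
    if (classifier == "fcnn") {
      xtr <- as.matrix(tr[, c("mu", "i0")])
      ctr <- colMeans(xtr)
      xtr <- sweep(xtr, 2, ctr)
      xte <- sweep(as.matrix(dataset[test_rows, c("mu", "i0")]), 2, ctr)
      net <- build_fcnn(hidden = config$hidden, seed = fold_seed)
      aug <- NULL
    } else {
      xtr <- get_images(tr$.row)
      xte <- get_images(test_rows)
      shp <- dim(xtr[[1]])[1:2]
      net <- do.call(build_cnn, c(list(input_shape = shp, seed = fold_seed),
                                  config$cnn_args))
      aug <- if (config$augment) {
        function(xb) .augment_images(xb, config$shift_frac)
      }
    }
    net <- nn_train(net, xtr, tr$class, epochs = config$epochs,
                    batch_size = config$batch_size, lr = config$lr,
                    validation_split = config$validation_split,
                    seed = fold_seed, augment = aug)
    prob <- nn_predict(net, xte)
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    truth <- as.character(dataset$class[test_rows])
    folds$tp[k] <- sum(pred == "tumor" & truth == "tumor")
    folds$fp[k] <- sum(pred == "tumor" & truth == "healthy")
    folds$tn[k] <- sum(pred == "healthy" & truth == "healthy")
    folds$fn[k] <- sum(pred == "healthy" & truth == "tumor")
    m <- compute_metrics(folds$tp[k], folds$fp[k], folds$tn[k], folds$fn[k])
    folds$sensitivity[k] <- m$sensitivity
    folds$specificity[k] <- m$specificity
  }
  structure(list(
    folds = folds,
    mean_sensitivity = mean(folds$sensitivity, na.rm = TRUE),
    sd_sensitivity = stats::sd(folds$sensitivity[!is.na(folds$sensitivity)]),
    mean_specificity = mean(folds$specificity, na.rm = TRUE),
    sd_specificity = stats::sd(folds$specificity[!is.na(folds$specificity)]),
    task_id = attr(dataset, "task_id"), classifier = classifier
  ), class = "lopo_result")
}

#' @export
print.lopo_result <- function(x, ...) {
  cat(sprintf("Leave-one-patient-out CV (%s, task %s): %d fold(s), %d skipped\n",
              x$classifier, x$task_id %||% "?", nrow(x$folds),
              sum(x$folds$skipped)))
  cat(sprintf("  sensitivity %.2f +/- %.2f   specificity %.2f +/- %.2f\n",
              x$mean_sensitivity, x$sd_sensitivity %||% NA,
              x$mean_specificity, x$sd_specificity %||% NA))
  invisible(x)
}
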