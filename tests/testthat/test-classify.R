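fits_table <- function(n_per, labels, patients = c("P1", "P2", "P3"),
                       mu_by_label = NULL, i0_by_label = NULL, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(patient_id = patients, label = labels,
                      idx = seq_len(n_per), stringsAsFactors = FALSE)
  rows$sample_id <- paste0(rows$patient_id, "_S1")
  rows$mu <- vapply(rows$label, function(l) {
    m <- if (is.null(mu_by_label)) 1 else mu_by_label[[l]]
    stats::rlnorm(1, log(m), 0.1)
  }, 0)
  rows$i0 <- vapply(rows$label, function(l) {
    m <- if (is.null(i0_by_label)) 1 else i0_by_label[[l]]
    stats::rlnorm(1, log(m), 0.1)
  }, 0)
  rows
}

test_that("task definitions grow as specified", {
  t1 <- classification_task("I")
  expect_identical(t1$positive_labels, "WM>60%")
  expect_identical(t1$negative_labels, "WM0%")
  t2 <- classification_task("II")
  expect_setequal(t2$positive_labels, c("WM>60%", "WM30-60%"))
  t3 <- classification_task("III")
  expect_setequal(t3$positive_labels, c("WM>60%", "WM30-60%", "WM0-30%"))
  expect_identical(t3$negative_labels, "WM0%")
  t4 <- classification_task("IV")
  expect_setequal(t4$negative_labels, c("WM0%", "GM0%"))
  expect_length(intersect(t4$positive_labels, t4$negative_labels), 0)
  expect_error(classification_task("V"))
})

test_that("task assembly filters, binarizes and validates", {
  tab <- fits_table(4, tissue_labels())
  ds <- assemble_task(tab, "I")
  expect_setequal(unique(ds$label), c("WM0%", "WM>60%"))
  expect_identical(levels(ds$class), c("healthy", "tumor"))
  ds4 <- assemble_task(tab, "IV")
  expect_true(all(ds4$class[ds4$label == "GM0%"] == "healthy"))
  no_tumor <- tab[tab$label != "WM>60%", ]
  expect_error(assemble_task(no_tumor, "I"), "zero examples")
})

test_that("rebalancing equalizes samples then classes by duplication only", {
  tab <- rbind(
    data.frame(sample_id = "A", class = "tumor", x = 1:100),
    data.frame(sample_id = "B", class = "healthy", x = 1:40)
  )
  out <- rebalance(tab, seed = 3)
  expect_equal(unname(table(out$class)), c(100L, 100L),
               ignore_attr = TRUE)
  # duplication only: the original rows all survive
  expect_true(all(tab$x[tab$sample_id == "B"] %in% out$x[out$sample_id == "B"]))
  expect_gte(nrow(out), nrow(tab))
  # balanced input passes through with equal class sizes
  bal <- rbind(data.frame(sample_id = "A", class = "tumor", x = 1:50),
               data.frame(sample_id = "B", class = "healthy", x = 1:50))
  expect_equal(unname(table(rebalance(bal, 1)$class)), c(50L, 50L),
               ignore_attr = TRUE)
  # seeded determinism
  expect_identical(rebalance(tab, seed = 9), rebalance(tab, seed = 9))
})

test_that("sensitivity and specificity follow the confusion counts", {
  m <- compute_metrics(tp = 9, fp = 2, tn = 8, fn = 1)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(compute_metrics(5, 0, 0, 0)$sensitivity, 1.0)
  expect_true(is.na(compute_metrics(0, 3, 2, 0)$sensitivity))
  expect_true(is.na(compute_metrics(1, 0, 0, 1)$specificity))
})

test_that("network outputs are valid probability distributions", {
  fc <- build_fcnn(seed = 2)
  p <- nn_predict(fc, matrix(rnorm(20), 10, 2))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p >= 0))
  cnn <- build_cnn(c(16, 16), filters = c(4, 4, 8, 8), dense = c(16, 8))
  x <- list(array(rnorm(256), c(16, 16, 1)), array(rnorm(256), c(16, 16, 1)))
  pc <- nn_predict(cnn, x)
  expect_equal(rowSums(pc), c(1, 1), tolerance = 1e-6)
})

test_that("the image network's pooling arithmetic matches its contract", {
  # 50 x 50 -> 25 -> 12 -> 6 -> 3 after four 2x2 pools
  cnn <- build_cnn(c(50, 50), filters = c(2, 2, 2, 2), dense = c(4, 4))
  flat_idx <- which(vapply(cnn$layers, function(l) l$type == "flatten", TRUE))
  dense1 <- cnn$params[[flat_idx + 1L]]
  expect_identical(nrow(dense1$W), 3L * 3L * 2L)
  # the tall "sd" patch shape is accepted
  cnn2 <- build_cnn(c(100, 50), filters = c(2, 2, 2, 2), dense = c(4, 4))
  dense2 <- cnn2$params[[flat_idx + 1L]]
  expect_identical(nrow(dense2$W), 6L * 3L * 2L)
  expect_error(build_cnn(c(12, 50)), "at least 16")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(31)
  net <- nn_network(c(6, 6, 1), list(
    nn_conv2d(2), nn_maxpool(), nn_flatten(), nn_dense(4, "relu"),
    nn_dense(2, "softmax")), seed = 31)
  x <- list(array(rnorm(36), c(6, 6, 1)), array(rnorm(36), c(6, 6, 1)))
  y <- diag(2)
  bp <- octatten:::.nn_backprop(net, x, y)
  eps <- 1e-6
  for (li in c(1, 4, 5)) {
    W <- net$params[[li]]$W
    for (j in sample(length(W), 3)) {
      net_p <- net; net_p$params[[li]]$W[j] <- W[j] + eps
      net_m <- net; net_m$params[[li]]$W[j] <- W[j] - eps
      lp <- octatten:::.nn_backprop(net_p, x, y)$loss
      lm_ <- octatten:::.nn_backprop(net_m, x, y)$loss
      expect_equal(bp$grads[[li]]$W[j], (lp - lm_) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("training separates linearly separable optical features", {
  set.seed(5)
  x <- rbind(matrix(rnorm(200, mean = 2), 100, 2),
             matrix(rnorm(200, mean = -2), 100, 2))
  y <- rep(c("tumor", "healthy"), each = 100)
  net <- nn_train(build_fcnn(seed = 4), x, y, epochs = 20, seed = 4)
  pred <- colnames(nn_predict(net, x))[max.col(nn_predict(net, x))]
  expect_gte(mean(pred == y), 0.95)
})

test_that("leave-one-patient-out produces one clean fold per patient", {
  mu_map <- list("WM0%" = 4.93, "WM>60%" = 1.22)
  i0_map <- list("WM0%" = 0.40, "WM>60%" = 0.11)
  tab <- fits_table(20, c("WM0%", "WM>60%"), c("P1", "P2", "P3"),
                    mu_map, i0_map, seed = 6)
  ds <- assemble_task(tab, "I")
  res <- run_lopo_cv(ds, "fcnn", train_config(epochs = 12, seed = 2))
  expect_identical(nrow(res$folds), 3L)
  expect_false(any(res$folds$skipped))
  # counts sum to the held-out patch count
  for (k in 1:3) {
    n_test <- sum(ds$patient_id == res$folds$patient[k])
    expect_equal(sum(unlist(res$folds[k, c("tp", "fp", "tn", "fn")])), n_test)
  }
  # strongly separated classes classify perfectly
  expect_equal(res$mean_sensitivity, 1.0)
  expect_equal(res$mean_specificity, 1.0)
})

test_that("folds with a single-class training split are skipped with a reason", {
  tab <- rbind(
    fits_table(5, "WM0%", "P1"),
    fits_table(5, c("WM0%", "WM>60%"), "P2")
  )
  ds <- assemble_task(tab, "I")
  res <- run_lopo_cv(ds, "fcnn", train_config(epochs = 2, seed = 1))
  expect_true(res$folds$skipped[res$folds$patient == "P2"])
  expect_match(res$folds$reason[res$folds$patient == "P2"], "lacks a class")
})

test_that("metrics are invariant to class-preserving shuffles of the test set", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  y <- rep(c("tumor", "healthy"), each = 20)
  net <- nn_train(build_fcnn(seed = 1), x, y, epochs = 8, seed = 1)
  prob <- nn_predict(net, x)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  conf <- function(pred, truth) {
    compute_metrics(sum(pred == "tumor" & truth == "tumor"),
                    sum(pred == "tumor" & truth == "healthy"),
                    sum(pred == "healthy" & truth == "healthy"),
                    sum(pred == "healthy" & truth == "tumor"))
  }
  perm <- sample(length(y))
  expect_equal(conf(pred, y), conf(pred[perm], y[perm]))
})

test_that("the image classifier trains end-to-end on tiny patches", {
  # two texture classes: bright-top vs bright-bottom gradients
  set.seed(12)
  make_img <- function(cls) {
    base <- if (cls == "tumor") seq(1, 0, length.out = 16) else
      seq(0, 1, length.out = 16)
    array(outer(base, rep(1, 16)) + 0.1 * rnorm(256), c(16, 16, 1))
  }
  n <- 30
  ds <- data.frame(
    patient_id = rep(c("P1", "P2"), each = n),
    sample_id = rep(c("P1_S", "P2_S"), each = n),
    label = rep(c("WM>60%", "WM0%"), n),
    row_index = seq_len(2 * n)
  )
  ds$class <- factor(ifelse(ds$label == "WM>60%", "tumor", "healthy"),
                     levels = c("healthy", "tumor"))
  attr(ds, "task_id") <- "I"
  patches <- lapply(as.character(ds$class), function(cl) {
    list(pixels = make_img(cl)[, , 1])
  })
  cfg <- train_config(epochs = 15, seed = 9, validation_split = 0,
                      cnn_args = list(filters = c(4, 4, 8, 8),
                                      dense = c(16, 8)))
  res <- run_lopo_cv(ds, "cnn", cfg, patches = patches)
  expect_identical(nrow(res$folds), 2L)
  ba <- (res$mean_sensitivity + res$mean_specificity) / 2
  expect_gte(ba, 0.9)
})
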