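# Dense feed-forward classifier over cluster summary features:
# training-set assembly (encounter splitting, balancing, augmentation),
# the network itself (4 x 512 leaky-ReLU layers with dropout and a softmax
# output), an Adam training loop with early stopping, and prediction.

#' Training configuration
#'
#' Defaults follow the balanced-training regime: 1,500 examples per class
#' (subsampling the majority classes, Gaussian-noise augmentation of the
#' minority classes), a per-class 1,000/500 train/test subdivision with an
#' 80/20 train/validation split, encounter-level isolation with a 15-min
#' gap rule and 70/10/20 proportions, and a network of four 512-node
#' fully-connected leaky-ReLU layers with 50% dropout trained by Adam at a
#' constant learning rate of 0.0003, batch size 100, at most 15 epochs and
#' early stopping after 3 epochs without validation improvement.
#'
#' @param examples_per_class Balanced examples per class (an ad-hoc
#'   5,000-example variant is supported by changing this and
#'   `n_train_test` proportionally).
#' @param n_train_test Per-class train/test counts after balancing.
#' @param train_val_fraction Train fraction of the per-class training pool.
#' @param encounter_gap Gap defining encounters, minutes.
#' @param top_split Encounter-level train/validate/test proportions.
#' @param batch_size,learning_rate,max_epochs,patience Optimizer settings.
#' @param dropout Dropout probability between hidden layers.
#' @param hidden Hidden layer widths.
#' @param leaky_alpha Negative-side slope of the leaky ReLU.
#' @param augment_noise_sd Gaussian augmentation noise on \[0, 1\] features.
#' @return A `train_config` list.
#' @export
train_config <- function(examples_per_class = 1500L,
                         n_train_test = c(1000L, 500L),
                         train_val_fraction = 0.8, encounter_gap = 15,
                         top_split = c(0.7, 0.1, 0.2), batch_size = 100L,
                         learning_rate = 3e-4, max_epochs = 15L,
                         patience = 3L, dropout = 0.5,
                         hidden = c(512L, 512L, 512L, 512L),
                         leaky_alpha = 0.01, augment_noise_sd = 0.05) {
  stopifnot(abs(sum(top_split) - 1) < 1e-9, patience < max_epochs,
            sum(n_train_test) == examples_per_class)
  structure(list(
    examples_per_class = as.integer(examples_per_class),
    n_train_test = as.integer(n_train_test),
    train_val_fraction = train_val_fraction, encounter_gap = encounter_gap,
    top_split = top_split, batch_size = as.integer(batch_size),
    learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
    patience = as.integer(patience), dropout = dropout,
    hidden = as.integer(hidden), leaky_alpha = leaky_alpha,
    augment_noise_sd = augment_noise_sd
  ), class = "train_config")
}

#' Feature-vector layout for cluster summaries
#'
#' Records how a [cluster_summary()] maps onto the classifier's input
#' vector: the spectral band and bin count, the 80-bin ICI histogram and
#' the 200-point envelope.
#'
#' @param freq_khz Frequency axis of the summaries' spectra.
#' @param band Spectral band retained, kHz.
#' @return A `feature_layout` list with the segment lengths and total
#'   input length.
#' @export
feature_layout <- function(freq_khz, band = c(10, 90)) {
  keep <- freq_khz >= band[1L] & freq_khz <= band[2L]
  structure(list(band = band, freq_khz = freq_khz, spec_keep = keep,
                 n_spec = sum(keep), n_ici = length(seq(0, ICI_MAX_S, ICI_BIN_S)) - 1L,
                 n_env = ENV_POINTS,
                 length = sum(keep) + length(seq(0, ICI_MAX_S, ICI_BIN_S)) - 1L +
                   ENV_POINTS),
            class = "feature_layout")
}

#' Build the classifier input vector for one cluster summary
#'
#' Concatenates the band-truncated mean spectrum, the ICI histogram and
#' the mean envelope, each min-max normalized onto \[0, 1\] (constant
#' segments map to zeros).
#'
#' @param summary A [cluster_summary()].
#' @param layout A [feature_layout()]; defaults to one derived from the
#'   summary's own frequency axis.
#' @return Numeric vector of length `layout$length`, values in \[0, 1\].
#' @export
feature_vector <- function(summary, layout = NULL) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (is.null(layout)) layout <- feature_layout(summary$freq_khz)
  if (length(summary$mean_spectrum) != length(layout$spec_keep) ||
      !isTRUE(all.equal(summary$freq_khz, layout$freq_khz)))
    stop("cluster summary does not match the feature layout")
  c(minmax_norm(summary$mean_spectrum[layout$spec_keep]),
    minmax_norm(summary$ici_hist),
    minmax_norm(summary$mean_envelope))
}

#' Feature matrix for a list of clusters
#'
#' @param clusters List of `click_cluster` objects.
#' @param layout A [feature_layout()].
#' @return Matrix with one row per cluster.
#' @export
cluster_features <- function(clusters, layout = NULL) {
  stopifnot(length(clusters) >= 1L)
  if (is.null(layout)) layout <- feature_layout(clusters[[1L]]$summary$freq_khz)
  t(vapply(clusters, function(cl) feature_vector(cl$summary, layout),
           numeric(layout$length)))
}

#' Encounter-preserving train/validate/test assignment
#'
#' Sorts examples into encounters — runs of detections on one site not
#' separated by more than `encounter_gap` minutes — and randomly assigns
#' whole encounters to the train/validate/test sets in the configured
#' proportions, so no encounter is partitioned across sets. Assignment is
#' greedy on shuffled encounters, always filling the set furthest below
#' its target example count.
#'
#' @param times_min Example timestamps, minutes.
#' @param sites Site identifier per example (encounters never span sites).
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return List with `set` (factor `train`/`validate`/`test` per example)
#'   and `encounter` (integer encounter id per example).
#' @export
split_encounters <- function(times_min, sites = rep(1L, length(times_min)),
                             config = train_config(), seed = 1L) {
  n <- length(times_min)
  enc <- integer(n)
  next_id <- 0L
  for (s in unique(sites)) {
    idx <- which(sites == s)
    o <- idx[order(times_min[idx])]
    gaps <- c(Inf, diff(times_min[o]))
    enc[o] <- next_id + cumsum(gaps > config$encounter_gap)
    next_id <- max(enc[o])
  }
  enc_ids <- unique(enc)
  sets <- c("train", "validate", "test")
  if (length(enc_ids) == 1L) {
    warning("single encounter: all examples assigned to the training set")
    return(list(set = factor(rep("train", n), levels = sets), encounter = enc))
  }
  enc_sizes <- as.numeric(table(enc)[as.character(enc_ids)])
  assign_enc <- with_seed(seed, {
    ord <- sample(seq_along(enc_ids))
    target <- config$top_split * n
    filled <- numeric(3L)
    a <- integer(length(enc_ids))
    for (e in ord) {
      pick <- which.max((target - filled) / pmax(target, 1))
      a[e] <- pick
      filled[pick] <- filled[pick] + enc_sizes[e]
    }
    a
  })
  set <- factor(sets[assign_enc[match(enc, enc_ids)]], levels = sets)
  list(set = set, encounter = enc)
}

#' Balance classes by subsampling and noise augmentation
#'
#' Produces exactly `examples_per_class` examples per class: majority
#' classes are subsampled uniformly; minority classes are augmented with
#' copies perturbed by Gaussian noise (sd `augment_noise_sd`), clipped to
#' \[0, 1\]. Each balanced class is then subdivided at random into
#' train/test pools (1,000/500 under defaults) and the training pool into
#' train/validation in 80/20 proportions.
#'
#' @param x Feature matrix, one row per example, values in \[0, 1\].
#' @param y Class label per row.
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return List with `x`, `y`, and `split` (factor `train`/`validate`/
#'   `test` per row of the balanced set).
#' @export
balance_classes <- function(x, y, config = train_config(), seed = 1L) {
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  counts <- table(factor(y, classes))
  if (any(counts == 0L))
    stop("class without examples: ", names(counts)[counts == 0L][1L])
  epc <- config$examples_per_class
  with_seed(seed, {
    xs <- list(); ys <- list(); splits <- list()
    for (cl in classes) {
      rows <- which(y == cl)
      if (length(rows) >= epc) {
        sel <- sample(rows, epc)
        xb <- x[sel, , drop = FALSE]
      } else {
        extra <- epc - length(rows)
        src <- sample(rows, extra, replace = TRUE)
        noise <- matrix(stats::rnorm(extra * ncol(x), 0, config$augment_noise_sd),
                        extra, ncol(x))
        aug <- pmin(pmax(x[src, , drop = FALSE] + noise, 0), 1)
        xb <- rbind(x[rows, , drop = FALSE], aug)
      }
      perm <- sample.int(epc)
      n_tr <- config$n_train_test[1L]
      n_tr_tr <- round(n_tr * config$train_val_fraction)
      sp <- character(epc)
      sp[perm[seq_len(n_tr_tr)]] <- "train"
      sp[perm[(n_tr_tr + 1L):n_tr]] <- "validate"
      sp[perm[(n_tr + 1L):epc]] <- "test"
      xs[[cl]] <- xb; ys[[cl]] <- rep(cl, epc); splits[[cl]] <- sp
    }
    list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
         split = factor(unlist(splits, use.names = FALSE),
                        levels = c("train", "validate", "test")))
  })
}

# --- network internals -----------------------------------------------------

.lrelu <- function(z, alpha) ifelse(z > 0, z, alpha * z)

.init_net <- function(d_in, hidden, d_out) {
  dims <- c(d_in, hidden, d_out)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], 0,
                                  sqrt(2 / dims[l])), dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass; returns softmax probabilities and (when training) the
# cached pre/post activations needed for backpropagation.
.forward <- function(net, X, alpha, drop_p = 0, training = FALSE) {
  L <- length(net$W)
  A <- X; cache <- if (training) list(A0 = X)
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A %*% net$W[[l]], 2L, net$b[[l]], `+`)
    A <- .lrelu(Z, alpha)
    if (training && drop_p > 0) {
      mask <- matrix(stats::runif(length(A)) >= drop_p, nrow(A), ncol(A)) /
        (1 - drop_p)
      A <- A * mask
      cache[[paste0("M", l)]] <- mask
    }
    if (training) { cache[[paste0("Z", l)]] <- Z; cache[[paste0("A", l)]] <- A }
  }
  Z <- sweep(A %*% net$W[[L]], 2L, net$b[[L]], `+`)
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  list(P = P, cache = cache)
}

.xent <- function(P, Yidx) {
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), Yidx)], 1e-12)))
}

# Backpropagation of the mean cross-entropy; returns gradients.
.backward <- function(net, fw, Yidx, alpha, drop_p) {
  L <- length(net$W)
  n <- nrow(fw$P)
  dZ <- fw$P
  dZ[cbind(seq_len(n), Yidx)] <- dZ[cbind(seq_len(n), Yidx)] - 1
  dZ <- dZ / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    A_prev <- if (l == 1L) fw$cache$A0 else fw$cache[[paste0("A", l - 1L)]]
    gW[[l]] <- crossprod(A_prev, dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dA <- tcrossprod(dZ, net$W[[l]])
      if (drop_p > 0) dA <- dA * fw$cache[[paste0("M", l - 1L)]]
      Z <- fw$cache[[paste0("Z", l - 1L)]]
      dZ <- dA * ifelse(Z > 0, 1, alpha)
    }
  }
  list(W = gW, b = gb)
}

#' Build and train the dense classifier
#'
#' Architecture: input, four 512-node fully-connected layers with leaky
#' ReLU activations and 50% dropout between layers, and a softmax output
#' over the class labels. Trained by Adam at a constant learning rate on
#' mini-batches, with early stopping when validation loss has not
#' improved for `patience` epochs; the weights of the best validation
#' epoch are restored. Training is deterministic for a given seed.
#'
#' @param balanced Output of [balance_classes()] (with at least 2 classes).
#' @param config A [train_config()].
#' @param layout The [feature_layout()] the features were built with
#'   (stored in the model for prediction-time checks).
#' @param seed Integer seed.
#' @return A `trained_network`: layer weights, class list, layout,
#'   per-epoch training history, the configuration and seed.
#' @export
build_and_train <- function(balanced, config = train_config(), layout = NULL,
                            seed = 1L) {
  classes <- sort(unique(balanced$y))
  if (length(classes) < 2L) stop("need at least 2 classes to train")
  tr <- balanced$split == "train"
  va <- balanced$split == "validate"
  Xtr <- balanced$x[tr, , drop = FALSE]
  Ytr <- match(balanced$y[tr], classes)
  Xva <- balanced$x[va, , drop = FALSE]
  Yva <- match(balanced$y[va], classes)
  alpha <- config$leaky_alpha
  with_seed(seed, {
    net <- .init_net(ncol(Xtr), config$hidden, length(classes))
    mW <- lapply(net$W, function(w) w * 0); vW <- mW
    mb <- lapply(net$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), val_accuracy = numeric(0))
    best <- list(loss = Inf, net = net, epoch = 0L)
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(nrow(Xtr))
      losses <- c()
      for (start in seq(1L, length(perm), by = config$batch_size)) {
        bi <- perm[start:min(start + config$batch_size - 1L, length(perm))]
        fw <- .forward(net, Xtr[bi, , drop = FALSE], alpha,
                       config$dropout, training = TRUE)
        loss <- .xent(fw$P, Ytr[bi])
        if (!is.finite(loss)) {
          err <- simpleError("training diverged (non-finite loss)")
          err$history <- history
          stop(err)
        }
        losses <- c(losses, loss)
        g <- .backward(net, fw, Ytr[bi], alpha, config$dropout)
        t_step <- t_step + 1
        for (l in seq_along(net$W)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]] ^ 2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]] ^ 2
          mhW <- mW[[l]] / (1 - beta1 ^ t_step)
          vhW <- vW[[l]] / (1 - beta2 ^ t_step)
          mhb <- mb[[l]] / (1 - beta1 ^ t_step)
          vhb <- vb[[l]] / (1 - beta2 ^ t_step)
          net$W[[l]] <- net$W[[l]] - config$learning_rate * mhW / (sqrt(vhW) + eps)
          net$b[[l]] <- net$b[[l]] - config$learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      fw_va <- .forward(net, Xva, alpha)
      val_loss <- .xent(fw_va$P, Yva)
      val_acc <- mean(max.col(fw_va$P) == Yva)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = val_loss,
        val_accuracy = val_acc))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, net = net, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
    structure(list(weights = best$net$W, biases = best$net$b,
                   classes = classes, layout = layout, history = history,
                   config = config, seed = as.integer(seed),
                   leaky_alpha = alpha),
              class = "trained_network")
  })
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf(
    "<trained_network> %d classes, input %d, %s hidden, %d epochs trained\n",
    length(x$classes), nrow(x$weights[[1L]]),
    paste(x$config$hidden, collapse = "x"), nrow(x$history)))
  invisible(x)
}

#' Number of trainable parameters in a trained network
#' @param model A `trained_network`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$weights, length, 0L)) + sum(vapply(model$biases, length, 0L))
}

#' Classify clusters (or feature rows) with a trained network
#'
#' Each cluster receives the label of the maximum softmax probability and
#' that probability as its score; batch prediction equals the
#' concatenation of single predictions.
#'
#' @param object A `trained_network`.
#' @param newdata List of `click_cluster` objects, a feature matrix, or a
#'   single `cluster_summary`.
#' @param ... Unused.
#' @return Data frame with `label` and `score`, one row per cluster; the
#'   full softmax matrix is attached as attribute `"prob"`.
#' @export
predict.trained_network <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
  else if (inherits(newdata, "cluster_summary"))
    matrix(feature_vector(newdata, object$layout), 1L)
  else cluster_features(newdata, object$layout)
  if (ncol(X) != nrow(object$weights[[1L]]))
    stop("feature length does not match the model's input layout")
  net <- list(W = object$weights, b = object$biases)
  P <- .forward(net, X, object$leaky_alpha)$P
  colnames(P) <- object$classes
  out <- data.frame(label = object$classes[max.col(P, ties.method = "first")],
                    score = apply(P, 1L, max))
  attr(out, "prob") <- P
  out
}

#' Save / load a trained network
#'
#' Serialization round-trips bit-exactly, including weights, class list,
#' layout and history.
#'
#' @param model A `trained_network`.
#' @param path File path.
#' @return `load_model` returns the `trained_network`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
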