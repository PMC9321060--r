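# Fully connected neural-network classification of whole metagene portraits
# ("portrait recognition"). One tanh hidden layer, softmax output, trained by
# seeded mini-batch gradient descent with momentum on the cross-entropy.
#
# Initialization is chosen to be pixel-permutation equivariant: the hidden
# weights start at zero (their updates then depend on pixels only through
# their values) while the output weights are drawn per hidden unit, which
# breaks the hidden-unit symmetry. Relabeling the pixels consistently at
# training and prediction time therefore leaves predictions unchanged.

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_forward <- function(X, w) {
  H <- tanh(sweep(X %*% w$W1, 2L, w$b1, `+`))
  prob <- softmax_rows(sweep(H %*% w$W2, 2L, w$b2, `+`))
  list(H = H, prob = prob)
}

cross_entropy <- function(prob, Y) -mean(rowSums(Y * log(pmax(prob, 1e-12))))

#' Train a portrait classifier
#'
#' @param P pixels x samples portrait matrix (see [portraits()]).
#' @param labels named class labels covering the samples of `P`.
#' @param hidden hidden layer size.
#' @param epochs maximum training epochs.
#' @param lr learning rate (SGD with momentum 0.9).
#' @param batch_size mini-batch size; `Inf` for full batch.
#' @param val_fraction fraction held out per class for validation
#'   (stratified); 0 disables validation and early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed (weights, split, batch order).
#' @return an object of class `PortraitClassifier` with the weights,
#'   per-pixel standardization statistics, class levels, loss traces and
#'   validation accuracy.
#' @export
train_portrait_classifier <- function(P, labels, hidden = 64L, epochs = 200L,
                                      lr = 0.05, batch_size = 32L,
                                      val_fraction = 0.2, patience = 10L,
                                      seed = 1L) {
  labels <- labels[colnames(P)]
  if (any(is.na(labels))) stop("labels missing for some samples")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("need at least two classes")
  small <- names(which(table(labels) < 10L))
  if (length(small))
    warning("fewer than 10 samples in class(es): ",
            paste(small, collapse = ", "))
  X <- t(P)                                   # samples x pixels
  set.seed(seed)
  val <- integer()
  if (val_fraction > 0) {
    for (cl in classes) {
      idx <- which(labels == cl)
      n_val <- max(1L, floor(val_fraction * length(idx)))
      if (n_val < length(idx)) val <- c(val, sample(idx, n_val))
    }
  }
  train <- setdiff(seq_len(nrow(X)), val)
  mu <- colMeans(X[train, , drop = FALSE])
  sdv <- apply(X[train, , drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  Y <- outer(as.character(labels), classes, `==`) * 1

  n_pix <- ncol(X); n_cls <- length(classes)
  w <- list(W1 = matrix(0, n_pix, hidden), b1 = numeric(hidden),
            W2 = matrix(stats::rnorm(hidden * n_cls, 0, 0.5), hidden, n_cls),
            b2 = numeric(n_cls))
  vel <- lapply(w, function(z) z * 0)
  momentum <- 0.9
  best <- list(loss = Inf, w = w, epoch = 0L)
  train_loss <- val_loss <- rep(NA_real_, epochs)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(train)
    bs <- if (is.finite(batch_size)) min(batch_size, length(ord)) else length(ord)
    for (start in seq(1L, length(ord), by = bs)) {
      b <- ord[start:min(start + bs - 1L, length(ord))]
      fw <- nn_forward(Xs[b, , drop = FALSE], w)
      delta <- (fw$prob - Y[b, , drop = FALSE]) / length(b)
      grad <- list(
        W1 = t(Xs[b, , drop = FALSE]) %*% ((delta %*% t(w$W2)) * (1 - fw$H^2)),
        b1 = colSums((delta %*% t(w$W2)) * (1 - fw$H^2)),
        W2 = t(fw$H) %*% delta,
        b2 = colSums(delta))
      for (k in names(w)) {
        vel[[k]] <- momentum * vel[[k]] - lr * grad[[k]]
        w[[k]] <- w[[k]] + vel[[k]]
      }
    }
    train_loss[ep] <- cross_entropy(
      nn_forward(Xs[train, , drop = FALSE], w)$prob, Y[train, , drop = FALSE])
    if (length(val)) {
      val_loss[ep] <- cross_entropy(
        nn_forward(Xs[val, , drop = FALSE], w)$prob, Y[val, , drop = FALSE])
      if (val_loss[ep] < best$loss - 1e-8) {
        best <- list(loss = val_loss[ep], w = w, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (length(val) && is.finite(best$loss)) w <- best$w
  fitted <- nn_forward(Xs, w)$prob
  pred <- classes[max.col(fitted, ties.method = "first")]
  val_acc <- if (length(val)) mean(pred[val] == labels[val]) else NA_real_
  structure(list(weights = w, classes = classes, mu = mu, sd = sdv,
                 train_loss = train_loss[!is.na(train_loss)],
                 val_loss = val_loss[!is.na(val_loss)],
                 val_accuracy = val_acc, val_idx = val,
                 meta = list(hidden = hidden, epochs = epochs, lr = lr,
                             batch_size = batch_size, seed = seed)),
            class = "PortraitClassifier")
}

#' @export
print.PortraitClassifier <- function(x, ...) {
  cat(sprintf("PortraitClassifier: %d pixels -> %d hidden -> %d classes; val accuracy %.3f\n",
              length(x$mu), x$meta$hidden, length(x$classes),
              x$val_accuracy))
  invisible(x)
}

#' Predict class probabilities for portraits
#'
#' @param object a `PortraitClassifier`.
#' @param P pixels x samples portrait matrix.
#' @param ... unused.
#' @return list with `prob` (samples x classes; rows sum to 1) and `labels`
#'   (argmax class per sample).
#' @export
predict.PortraitClassifier <- function(object, P, ...) {
  if (nrow(P) != length(object$mu))
    stop(sprintf("portrait length %d does not match input layer %d",
                 nrow(P), length(object$mu)))
  Xs <- sweep(sweep(t(P), 2L, object$mu), 2L, object$sd, `/`)
  prob <- nn_forward(Xs, object$weights)$prob
  dimnames(prob) <- list(colnames(P), object$classes)
  list(prob = prob,
       labels = stats::setNames(
         object$classes[max.col(prob, ties.method = "first")], colnames(P)))
}
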