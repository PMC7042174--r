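#' Fit a single-hidden-layer neural-network regressor
#'
#' Supervised scoring model: one hidden layer with ReLU activation
#' (`f(x) = max(x, 0)`) and a single linear output node, trained as a
#' regression of the numeric label (active = 1, decoy = 0) under squared
#' error with full-batch Adam. Inputs are standardized internally. A
#' fraction of the rows is held out to monitor the loss; training stops
#' early when it has not improved for `patience` epochs and the best-epoch
#' weights are kept. The raw (unbounded) linear output is the activity
#' score. With `balance_by_oversampling` the active rows are duplicated
#' until the active:decoy row counts match, countering heavy class
#' imbalance.
#'
#' @param x Numeric matrix (one descriptor per row) or descriptor tibble.
#' @param labels Character (`"active"`/`"decoy"`) or numeric (1/0) labels,
#'   one per row; both classes must be present.
#' @param hidden_size Hidden-layer width (default 100).
#' @param epochs Maximum training epochs (default 300).
#' @param learning_rate Adam step size (default 0.01).
#' @param balance_by_oversampling Duplicate active rows to a 1:1 ratio.
#' @param validation_fraction,patience Early-stopping controls.
#' @param seed Integer seed (initialization and the validation split).
#' @return An object of class `usrml_ann`.
#' @export
fit_ann <- function(x, labels, hidden_size = 100, epochs = 300,
                    learning_rate = 0.01, balance_by_oversampling = FALSE,
                    validation_fraction = 0.1, patience = 25, seed = 1) {
  x <- as_descriptor_matrix(x)
  y <- label_to_numeric(labels)
  if (length(y) != nrow(x)) abort("One label per descriptor row is required.")
  if (length(unique(y)) < 2L) abort("ANN training needs both actives and decoys.")
  hidden_size <- as.integer(hidden_size)
  if (hidden_size < 1L) abort("`hidden_size` must be >= 1.")

  if (balance_by_oversampling) {
    idx <- oversample_indices(y)
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
  }
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  n <- nrow(xs)
  d <- ncol(xs)

  withr::with_seed(seed, {
    n_val <- max(1L, round(validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr <- setdiff(seq_len(n), val_idx)
    if (length(unique(y[tr])) < 2L) tr <- seq_len(n)  # tiny-data fallback
    W1 <- matrix(rnorm(d * hidden_size, sd = sqrt(2 / d)), d, hidden_size)
    b1 <- numeric(hidden_size)
    W2 <- matrix(rnorm(hidden_size, sd = sqrt(1 / hidden_size)), hidden_size, 1L)
    b2 <- 0

    adam <- function() list(m = 0, v = 0)
    st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- function(state, grad, t) {
      state$m <- beta1 * state$m + (1 - beta1) * grad
      state$v <- beta2 * state$v + (1 - beta2) * grad^2
      mhat <- state$m / (1 - beta1^t)
      vhat <- state$v / (1 - beta2^t)
      list(state = state, delta = learning_rate * mhat / (sqrt(vhat) + eps))
    }

    xt <- xs[tr, , drop = FALSE]; yt <- y[tr]
    xv <- xs[val_idx, , drop = FALSE]; yv <- y[val_idx]
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = 0L)
    wait <- 0L
    loss_trace <- numeric(0)
    for (t in seq_len(epochs)) {
      h_pre <- sweep(xt %*% W1, 2L, b1, "+")
      h <- relu(h_pre)
      out <- as.vector(h %*% W2) + b2
      err <- out - yt
      m <- length(yt)
      g_out <- 2 * err / m
      gW2 <- crossprod(h, g_out)
      gb2 <- sum(g_out)
      g_h <- (matrix(g_out) %*% t(W2)) * (h_pre > 0)
      gW1 <- crossprod(xt, g_h)
      gb1 <- colSums(g_h)
      s <- step(st$W1, gW1, t); st$W1 <- s$state; W1 <- W1 - s$delta
      s <- step(st$b1, gb1, t); st$b1 <- s$state; b1 <- b1 - s$delta
      s <- step(st$W2, gW2, t); st$W2 <- s$state; W2 <- W2 - s$delta
      s <- step(st$b2, gb2, t); st$b2 <- s$state; b2 <- b2 - s$delta

      vout <- as.vector(relu(sweep(xv %*% W1, 2L, b1, "+")) %*% W2) + b2
      vloss <- mean((vout - yv)^2)
      loss_trace <- c(loss_trace, vloss)
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = t)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(
      list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
           center = center, scale = scale, hidden_size = hidden_size,
           epochs_run = length(loss_trace), best_epoch = best$epoch,
           loss_trace = loss_trace, seed = seed,
           balance_by_oversampling = balance_by_oversampling),
      class = "usrml_ann"
    )
  })
}

relu <- function(x) pmax(x, 0)

label_to_numeric <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0 (decoy) or 1 (active).")
    return(as.double(labels))
  }
  if (!all(labels %in% c("active", "decoy"))) {
    abort("Labels must be 'active'/'decoy' (or 1/0).")
  }
  as.double(labels == "active")
}

# row indices implementing 1:1 oversampling: all rows, plus the active rows
# repeated until the active count equals the decoy count
oversample_indices <- function(y) {
  act <- which(y == 1)
  dec <- which(y == 0)
  if (length(act) >= length(dec)) return(seq_along(y))
  c(dec, rep_len(act, length(dec)))
}

#' Activity score of descriptors under a fitted network
#'
#' Raw linear output of the regressor; higher means more active-like.
#'
#' @param model A fitted [fit_ann()] object.
#' @param x Descriptor vector, matrix or tibble.
#' @return Numeric vector of scores (unbounded).
#' @export
ann_score <- function(model, x) {
  stopifnot(inherits(model, "usrml_ann"))
  x <- as_descriptor_matrix(x, length(model$center))
  xs <- sweep(sweep(x, 2L, model$center, "-"), 2L, model$scale, "/")
  as.vector(relu(sweep(xs %*% model$W1, 2L, model$b1, "+")) %*% model$W2) + model$b2
}

#' @export
print.usrml_ann <- function(x, ...) {
  cat(sprintf("<usrml_ann: hidden %d, %d epochs (best %d), val loss %.5f>\n",
              x$hidden_size, x$epochs_run, x$best_epoch, min(x$loss_trace)))
  invisible(x)
}
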