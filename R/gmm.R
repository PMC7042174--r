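#' Fit a Gaussian mixture model by expectation-maximization
#'
#' Fits a full-covariance Gaussian mixture to descriptor vectors with EM.
#' The density is the standard multivariate normal mixture
#' `f(x) = sum_k c_k N(x; mu_k, Sigma_k)`; a small diagonal regularization
#' is added to every covariance at each M step to keep it positive
#' definite. The training log-likelihood is non-decreasing across
#' iterations and is stored in the fitted object. Initialization uses
#' k-means on the data (with a jittered-row fallback for degenerate data),
#' so the fit is reproducible given the seed.
#'
#' In screening, the mixture is fitted to the descriptors of the *active*
#' conformers only (one-class learning) and its log-density is used as the
#' activity score of a candidate descriptor.
#'
#' @param x Numeric matrix (one descriptor per row) or a descriptor tibble.
#' @param n_components Number of Gaussian components M (n >= M required).
#' @param reg Diagonal covariance regularization (default 1e-6).
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood improvement falls below `tol` or after `max_iter`
#'   iterations.
#' @param seed Integer seed for the initialization.
#' @return An object of class `usrml_gmm` with elements `weights`, `means`
#'   (M x d), `covariances` (list of d x d), `log_likelihood` (trace),
#'   `n_iter`, `converged`, `n_components`, `dim`, `n`, `reg`, `seed`.
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' fit <- fit_gmm(x, n_components = 1, seed = 1)
#' gmm_score(fit, c(0, 0))
#' @export
fit_gmm <- function(x, n_components, reg = 1e-6, max_iter = 500, tol = 1e-8,
                    seed = 1) {
  x <- as_descriptor_matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  M <- as.integer(n_components)
  if (M < 1L) abort("`n_components` must be >= 1.")
  if (n < M) abort(sprintf("Need at least M = %d rows to fit %d components.", M, M))
  assert_number(reg, "reg", 0)

  resp <- withr::with_seed(seed, init_responsibilities(x, M))
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M step
    Nk <- pmax(colSums(resp), 1e-12)
    weights <- Nk / n
    means <- crossprod(resp, x) / Nk
    covariances <- vector("list", M)
    for (k in seq_len(M)) {
      xc <- sweep(x, 2L, means[k, ], "-")
      covariances[[k]] <- crossprod(xc * resp[, k], xc) / Nk[k] + diag(reg, d)
    }
    # E step
    comp_ll <- component_loglik(x, weights, means, covariances)
    lse <- row_logsumexp(comp_ll)
    loglik <- c(loglik, sum(lse))
    resp <- exp(comp_ll - lse)
    it <- length(loglik)
    if (it >= 2L && loglik[it] - loglik[it - 1L] < tol * (abs(loglik[it - 1L]) + 1)) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(weights = as.double(weights), means = means,
         covariances = covariances, log_likelihood = loglik,
         n_iter = length(loglik), converged = converged,
         n_components = M, dim = d, n = n, reg = reg, seed = seed),
    class = "usrml_gmm"
  )
}

# hard-assignment initialization: k-means where feasible, jittered rows
# otherwise (covers data with fewer distinct rows than components)
init_responsibilities <- function(x, M) {
  n <- nrow(x)
  if (M == 1L) return(matrix(1, n, 1L))
  assign <- tryCatch({
    km <- suppressWarnings(kmeans(x, centers = M, nstart = 5L, iter.max = 50L))
    km$cluster
  }, error = function(e) sample.int(M, n, replace = TRUE))
  if (length(unique(assign)) < M) assign <- sample.int(M, n, replace = TRUE)
  resp <- matrix(1e-3 / (M - 1), n, M)
  resp[cbind(seq_len(n), assign)] <- 1 - 1e-3
  resp
}

# n x M matrix of log(c_k) + log N(x; mu_k, Sigma_k)
component_loglik <- function(x, weights, means, covariances) {
  n <- nrow(x)
  d <- ncol(x)
  M <- length(weights)
  out <- matrix(0, n, M)
  for (k in seq_len(M)) {
    ch <- tryCatch(chol(covariances[[k]]), error = function(e) {
      abort(sprintf("Component %d covariance is singular despite regularization (d = %d).", k, d))
    })
    xc <- sweep(x, 2L, means[k, ], "-")
    z <- xc %*% backsolve(ch, diag(d), transpose = TRUE)
    quad <- rowSums(z^2)
    logdet <- 2 * sum(log(diag(ch)))
    out[, k] <- log(weights[k]) - 0.5 * (d * log(2 * pi) + logdet + quad)
  }
  out
}

#' Log-density score of descriptors under a fitted mixture
#'
#' Evaluates the log of the mixture density at each descriptor; higher
#' means more active-like.
#'
#' @param model A fitted [fit_gmm()] object.
#' @param x Descriptor vector, matrix (one row per descriptor) or tibble.
#' @return Numeric vector of log-densities.
#' @export
gmm_score <- function(model, x) {
  stopifnot(inherits(model, "usrml_gmm"))
  x <- as_descriptor_matrix(x, model$dim)
  comp_ll <- component_loglik(x, model$weights, model$means, model$covariances)
  as.double(row_logsumexp(comp_ll))
}

#' @export
print.usrml_gmm <- function(x, ...) {
  cat(sprintf("<usrml_gmm: M = %d, d = %d, n = %d, loglik = %.3f (%s in %d iters)>\n",
              x$n_components, x$dim, x$n, x$log_likelihood[x$n_iter],
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

# coerce descriptor input to a numeric matrix, optionally checking dimension
as_descriptor_matrix <- function(x, dim = NULL) {
  m <- if (is.data.frame(x)) descriptor_matrix(x)
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(as.double(x), nrow = 1L)
  else abort("Descriptors must be a numeric vector, matrix or descriptor tibble.")
  storage.mode(m) <- "double"
  if (!is.null(dim) && ncol(m) != dim) {
    abort(sprintf("Descriptor dimension %d does not match model dimension %d.", ncol(m), dim))
  }
  if (!all(is.finite(m))) abort("Descriptors must be finite.")
  m
}
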