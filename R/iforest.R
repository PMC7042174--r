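#' Fit an isolation forest
#'
#' One-class anomaly model: an ensemble of random binary trees, each grown
#' on a subsample of the data by recursively picking a random feature and a
#' random split point between that feature's minimum and maximum. Points
#' that are easy to isolate (short average path length) are anomalies;
#' points deep inside dense regions take longer to isolate. In screening,
#' the forest is trained on the descriptors of the *active* conformers
#' only, so descriptors far from every active cluster score as anomalies.
#'
#' @param x Numeric matrix (one descriptor per row) or descriptor tibble
#'   (n >= 2 rows).
#' @param n_trees Number of trees (default 100).
#' @param subsample_size Subsample size per tree (default 256, capped at n).
#' @param seed Integer seed.
#' @return An object of class `usrml_iforest`.
#' @export
fit_isolation_forest <- function(x, n_trees = 100, subsample_size = 256, seed = 1) {
  x <- as_descriptor_matrix(x)
  n <- nrow(x)
  if (n < 2L) abort("Isolation forest needs at least 2 rows.")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) abort("`n_trees` must be >= 1.")
  psi <- min(as.integer(subsample_size), n)
  hlim <- ceiling(log2(psi))
  trees <- withr::with_seed(seed, {
    purrr::map(seq_len(n_trees), function(t) {
      idx <- sample.int(n, psi)
      grow_itree(x[idx, , drop = FALSE], hlim)
    })
  })
  structure(
    list(trees = trees, n_trees = n_trees, subsample_size = psi,
         c_psi = avg_path_length(psi), dim = ncol(x), seed = seed),
    class = "usrml_iforest"
  )
}

# expected path length of an unsuccessful BST search (Liu et al. normalizer)
avg_path_length <- function(n) {
  if (n <= 1) return(0)
  if (n == 2) return(1)
  2 * (log(n - 1) + 0.5772156649) - 2 * (n - 1) / n
}

# grow one isolation tree as flat parallel arrays (feature NA == leaf);
# leaves store their size so scoring can add the subtree adjustment
grow_itree <- function(x, hlim) {
  feature <- integer(0); threshold <- double(0)
  left <- integer(0); right <- integer(0); size <- integer(0)
  new_node <- function() {
    feature[length(feature) + 1L] <<- NA_integer_
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    size[length(size) + 1L] <<- 0L
    length(feature)
  }
  build <- function(rows, depth) {
    id <- new_node()
    size[id] <<- length(rows)
    if (length(rows) <= 1L || depth >= hlim) return(id)
    sub <- x[rows, , drop = FALSE]
    rng <- apply(sub, 2L, range)
    splittable <- which(rng[2L, ] > rng[1L, ])
    if (length(splittable) == 0L) return(id)  # all duplicate points
    f <- if (length(splittable) == 1L) splittable else sample(splittable, 1L)
    s <- runif(1L, rng[1L, f], rng[2L, f])
    go_left <- sub[, f] < s
    if (!any(go_left) || all(go_left)) return(id)
    feature[id] <<- f
    threshold[id] <<- s
    left[id] <<- build(rows[go_left], depth + 1L)
    right[id] <<- build(rows[!go_left], depth + 1L)
    id
  }
  build(seq_len(nrow(x)), 0L)
  list(feature = feature, threshold = threshold, left = left,
       right = right, size = size)
}

# path lengths of the rows of x down one tree, vectorized by frontier
tree_path_length <- function(tree, x) {
  n <- nrow(x)
  depth <- numeric(n)
  node <- rep(1L, n)
  active <- !is.na(tree$feature[node])
  while (any(active)) {
    idx <- which(active)
    nd <- node[idx]
    f <- tree$feature[nd]
    goes_left <- x[cbind(idx, f)] < tree$threshold[nd]
    node[idx] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
    depth[idx] <- depth[idx] + 1
    active[idx] <- !is.na(tree$feature[node[idx]])
  }
  depth + vapply(tree$size[node], avg_path_length, numeric(1))
}

#' Normality score of descriptors under an isolation forest
#'
#' Returns the negated anomaly score `-2^(-E[h(x)] / c(psi))`, where
#' `E[h(x)]` is the mean path length over the trees, so that higher values
#' mean more active-like, matching the ranking convention of all model
#' families.
#'
#' @param model A fitted [fit_isolation_forest()] object.
#' @param x Descriptor vector, matrix or tibble.
#' @return Numeric vector of scores in `[-1, 0)`.
#' @export
if_score <- function(model, x) {
  stopifnot(inherits(model, "usrml_iforest"))
  x <- as_descriptor_matrix(x, model$dim)
  paths <- vapply(model$trees, tree_path_length, numeric(nrow(x)), x = x)
  if (is.null(dim(paths))) paths <- matrix(paths, nrow = nrow(x))
  h <- rowMeans(paths)
  -2^(-h / model$c_psi)
}

#' @export
print.usrml_iforest <- function(x, ...) {
  cat(sprintf("<usrml_iforest: %d trees, subsample %d, d = %d>\n",
              x$n_trees, x$subsample_size, x$dim))
  invisible(x)
}
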