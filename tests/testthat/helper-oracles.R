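# Independent, deliberately naive reference implementations used as
# oracles. Everything here is explicit loops with no code shared with the
# package internals.

naive_dist <- function(p, q) {
  s <- 0
  for (j in seq_along(p)) s <- s + (p[j] - q[j])^2
  sqrt(s)
}

naive_moments <- function(dists) {
  n <- length(dists)
  m1 <- 0
  for (x in dists) m1 <- m1 + x
  m1 <- m1 / n
  s2 <- 0
  s3 <- 0
  for (x in dists) {
    s2 <- s2 + (x - m1)^2
    s3 <- s3 + (x - m1)^3
  }
  s2 <- s2 / n
  s3 <- s3 / n
  c(m1, sqrt(s2), sign(s3) * abs(s3)^(1 / 3))
}

naive_farthest <- function(points, p) {
  best <- -1
  best_i <- 1L
  for (i in seq_len(nrow(points))) {
    d <- naive_dist(points[i, ], p)
    if (d > best) {
      best <- d
      best_i <- i
    }
  }
  best_i
}

naive_usr_values <- function(points) {
  n <- nrow(points)
  ctd <- numeric(3)
  for (i in seq_len(n)) for (j in 1:3) ctd[j] <- ctd[j] + points[i, j]
  ctd <- ctd / n
  best <- Inf
  cst_i <- 1L
  for (i in seq_len(n)) {
    d <- naive_dist(points[i, ], ctd)
    if (d < best) {
      best <- d
      cst_i <- i
    }
  }
  fct_i <- naive_farthest(points, ctd)
  ftf_i <- naive_farthest(points, points[fct_i, ])
  refs <- list(ctd, points[cst_i, ], points[fct_i, ], points[ftf_i, ])
  out <- numeric(0)
  for (r in refs) {
    dd <- numeric(n)
    for (i in seq_len(n)) dd[i] <- naive_dist(points[i, ], r)
    out <- c(out, naive_moments(dd))
  }
  out
}

naive_es_values <- function(points) {
  n <- nrow(points)
  d <- ncol(points)
  c1 <- numeric(d)
  for (i in seq_len(n)) for (j in seq_len(d)) c1[j] <- c1[j] + points[i, j]
  c1 <- c1 / n
  c2 <- points[naive_farthest(points, c1), ]
  c3 <- points[naive_farthest(points, c2), ]
  a <- c2 - c1
  b <- c3 - c1
  s <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s_norm <- sqrt(s[1]^2 + s[2]^2 + s[3]^2)
  if (s_norm < 1e-12) {
    c4 <- c1
    c5 <- c1
  } else {
    a3_norm <- sqrt(a[1]^2 + a[2]^2 + a[3]^2)
    spatial <- c1[1:3] + a3_norm / (2 * s_norm) * s
    c4 <- c1
    c5 <- c1
    c4[1:3] <- spatial
    c5[1:3] <- spatial
    q_max <- -Inf
    q_min <- Inf
    for (i in seq_len(n)) {
      if (points[i, 4] > q_max) q_max <- points[i, 4]
      if (points[i, 4] < q_min) q_min <- points[i, 4]
    }
    c4[4] <- q_max
    c5[4] <- q_min
  }
  out <- numeric(0)
  for (r in list(c1, c2, c3, c4, c5)) {
    dd <- numeric(n)
    for (i in seq_len(n)) dd[i] <- naive_dist(points[i, ], r)
    out <- c(out, naive_moments(dd))
  }
  out
}

# oracle for a whole conformer under a scheme (builds the augmented cloud
# itself, loop by loop)
naive_descriptor <- function(conformer, method, q_scale = 25, logp_scale = 25) {
  n <- nrow(conformer$coords)
  if (method == "usr") return(naive_usr_values(conformer$coords))
  d <- if (method == "es4d") 4L else 5L
  pts <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (j in 1:3) pts[i, j] <- conformer$coords[i, j]
    pts[i, 4] <- q_scale * conformer$charges[i]
    if (d == 5L) pts[i, 5] <- logp_scale * conformer$logp_contribs[i]
  }
  naive_es_values(pts)
}

# brute-force pair-counting AUC with half credit for ties
naive_auc <- function(scores, labels) {
  act <- scores[labels == "active"]
  dec <- scores[labels == "decoy"]
  total <- 0
  for (a in act) {
    for (b in dec) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(act) * length(dec))
}

# exhaustive two-sided rank-sum p-value via bitmask enumeration of all
# assignments of the pooled observations to group A
enum_wilcoxon_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# shorthand: descriptor value vector of a conformer under the package path
pkg_descriptor <- function(conformer, scheme) {
  as.numeric(usrml:::descriptor_matrix(compute_descriptor(conformer, scheme)))
}
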