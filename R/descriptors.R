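#' Descriptor scheme configuration
#'
#' Fixes the descriptor family and its scaling constants. `usr` encodes pure
#' shape: distances of every atom to four reference points (the molecular
#' centroid `ctd`, the atom closest to it `cst`, the atom furthest from it
#' `fct`, and the atom furthest from `fct`, `ftf`), each distance
#' distribution condensed to three moments, giving 12 values. `es4d` appends
#' a fourth coordinate `charge_scale * charge` to every atom and uses five
#' reference points (15 values); `es5d` additionally appends
#' `logp_scale * logp_contrib` as a fifth coordinate.
#'
#' The scales put the non-spatial dimensions on a magnitude comparable to
#' the spatial ones; 25 angstrom per elementary charge is the published
#' ElectroShape choice and is kept as the default for both scales.
#'
#' @param method One of `"usr"`, `"es4d"`, `"es5d"`.
#' @param charge_scale Angstrom per elementary charge (default 25).
#' @param logp_scale Angstrom per ALogP unit (default 25).
#' @param include_hydrogens Keep hydrogen atoms in the point cloud (default
#'   `TRUE`; only has an effect on records that carry element symbols).
#'
#' @return An object of class `descriptor_scheme`.
#' @examples
#' descriptor_scheme("usr")
#' descriptor_scheme("es5d", charge_scale = 25, logp_scale = 25)
#' @export
descriptor_scheme <- function(method = c("usr", "es4d", "es5d"),
                              charge_scale = 25, logp_scale = 25,
                              include_hydrogens = TRUE) {
  method <- match.arg(method)
  assert_number(charge_scale, "charge_scale", 0, strict = TRUE)
  assert_number(logp_scale, "logp_scale", 0, strict = TRUE)
  structure(
    list(method = method, charge_scale = charge_scale,
         logp_scale = logp_scale,
         include_hydrogens = isTRUE(include_hydrogens)),
    class = "descriptor_scheme"
  )
}

#' @export
print.descriptor_scheme <- function(x, ...) {
  cat(sprintf("<descriptor_scheme %s: dim %d, %d values%s>\n", x$method,
              scheme_dim(x$method), scheme_length(x$method),
              if (x$include_hydrogens) "" else ", hydrogens excluded"))
  invisible(x)
}

scheme_dim <- function(method) c(usr = 3L, es4d = 4L, es5d = 5L)[[method]]
scheme_refs <- function(method) c(usr = 4L, es4d = 5L, es5d = 5L)[[method]]
scheme_length <- function(method) 3L * scheme_refs(method)

# names of the value columns of a descriptor table for a given method
descriptor_cols <- function(method) sprintf("m%02d", seq_len(scheme_length(method)))

as_scheme <- function(scheme) {
  if (inherits(scheme, "descriptor_scheme")) return(scheme)
  if (is_string(scheme)) return(descriptor_scheme(scheme))
  abort("`scheme` must be a descriptor_scheme or a method name.")
}

#' Build the augmented point cloud for a conformer
#'
#' Returns the n x d matrix a descriptor scheme operates on: the Cartesian
#' coordinates for `usr` (d = 3), with the scaled partial charge appended as
#' a fourth column for `es4d`, and the scaled atomic logP contribution as a
#' fifth column for `es5d`.
#'
#' @param conformer A [conformer_record()].
#' @param scheme A [descriptor_scheme()] or method name.
#' @return Numeric n x d matrix.
#' @examples
#' cr <- conformer_record("m", 0, matrix(rnorm(9), 3, 3), charges = c(0.2, 0, -0.2))
#' augment_points(cr, "es4d")[, 4]
#' @export
augment_points <- function(conformer, scheme) {
  scheme <- as_scheme(scheme)
  if (!is_conformer_record(conformer)) abort("`conformer` must be a conformer_record.")
  d <- scheme_dim(scheme$method)
  pts <- conformer$coords
  keep <- rep(TRUE, nrow(pts))
  if (!scheme$include_hydrogens && !is.null(conformer$elements)) {
    keep <- toupper(conformer$elements) != "H"
    if (!any(keep)) abort("Excluding hydrogens leaves no atoms in the cloud.")
  }
  pts <- pts[keep, , drop = FALSE]
  if (d >= 4L) {
    if (is.null(conformer$charges)) {
      abort(sprintf("Scheme '%s' requires per-atom charges.", scheme$method))
    }
    pts <- cbind(pts, scheme$charge_scale * conformer$charges[keep])
  }
  if (d == 5L) {
    if (is.null(conformer$logp_contribs)) {
      abort("Scheme 'es5d' requires per-atom logP contributions.")
    }
    pts <- cbind(pts, scheme$logp_scale * conformer$logp_contribs[keep])
  }
  dimnames(pts) <- NULL
  pts
}

#' USR reference points of a 3D point cloud
#'
#' Computes the four USR reference points: `ctd`, the arithmetic centroid;
#' `cst`, the point closest to `ctd`; `fct`, the point furthest from `ctd`;
#' and `ftf`, the point furthest from `fct`. Ties are broken by lowest point
#' index so the selection is deterministic and order-stable.
#'
#' @param points Numeric n x 3 matrix.
#' @return A 4 x 3 matrix with rows `ctd`, `cst`, `fct`, `ftf`.
#' @examples
#' usr_reference_points(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
#' @export
usr_reference_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L) abort("`points` must be n x 3 with n >= 1.")
  ctd <- colMeans(points)
  d_ctd <- dist_to_point(points, ctd)
  cst <- points[which.min(d_ctd), ]
  fct <- points[which.max(d_ctd), ]
  ftf <- points[which.max(dist_to_point(points, fct)), ]
  out <- rbind(ctd = ctd, cst = cst, fct = fct, ftf = ftf)
  colnames(out) <- NULL
  out
}

#' ElectroShape reference points of an augmented point cloud
#'
#' Computes the five ElectroShape reference points in the augmented
#' (4- or 5-dimensional) space: `c1`, the centroid of the augmented cloud;
#' `c2`, the cloud point furthest from `c1`; `c3`, the cloud point furthest
#' from `c2`; and `c4`/`c5`, a chirality-sensitive pair displaced from `c1`
#' along the spatial cross product of `(c2 - c1)` and `(c3 - c1)` by half
#' the spatial length of `(c2 - c1)`, carrying the maximum and minimum
#' scaled charge of the cloud as their fourth coordinate (and `c1`'s fifth
#' coordinate in 5D). If the spatial parts are collinear the cross product
#' degenerates and `c4 = c5 = c1` (with a message).
#'
#' @param points Numeric n x d matrix with d of 4 or 5 (see [augment_points()]).
#' @return A 5 x d matrix with rows `c1` to `c5`.
#' @export
electroshape_reference_points <- function(points) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (!(d %in% c(4L, 5L)) || nrow(points) < 1L) {
    abort("`points` must be n x 4 or n x 5 with n >= 1.")
  }
  c1 <- colMeans(points)
  c2 <- points[which.max(dist_to_point(points, c1)), ]
  c3 <- points[which.max(dist_to_point(points, c2)), ]
  a <- c2 - c1
  b <- c3 - c1
  s <- cross3(a[1:3], b[1:3])
  s_norm <- sqrt(sum(s^2))
  if (s_norm < 1e-12) {
    inform("Collinear spatial parts in ElectroShape reference construction; using c4 = c5 = c1.")
    c4 <- c1
    c5 <- c1
  } else {
    spatial <- c1[1:3] + (sqrt(sum(a[1:3]^2)) / (2 * s_norm)) * s
    c4 <- c1
    c5 <- c1
    c4[1:3] <- spatial
    c5[1:3] <- spatial
    c4[4] <- max(points[, 4])
    c5[4] <- min(points[, 4])
  }
  out <- rbind(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  colnames(out) <- NULL
  out
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

dist_to_point <- function(points, p) {
  sqrt(colSums((t(points) - p)^2))
}

#' First three (normalized) moments of a distance distribution
#'
#' Condenses a distance distribution into the triple the descriptor uses:
#' the mean, the square root of the population second central moment, and
#' the signed cube root of the population third central moment. The root
#' normalizations bring all three onto the scale of the first moment; the
#' signed cube root preserves the direction of the asymmetry. A single
#' distance yields `(d, 0, 0)`.
#'
#' @param distances Numeric vector of non-negative distances (n >= 1).
#' @return Numeric vector `c(m1, m2, m3)`.
#' @examples
#' moment_triple(c(0, 2))     # (1, 1, 0)
#' moment_triple(c(0, 0, 3))  # (1, sqrt(2), 2^(1/3))
#' @export
moment_triple <- function(distances) {
  if (length(distances) < 1L) abort("`distances` must be non-empty.")
  if (!all(is.finite(distances)) || any(distances < 0)) {
    abort("`distances` must be finite and non-negative.")
  }
  m1 <- mean(distances)
  dev <- distances - m1
  m2 <- sqrt(mean(dev^2))
  t3 <- mean(dev^3)
  m3 <- sign(t3) * abs(t3)^(1 / 3)
  c(m1, m2, m3)
}

# descriptor values for an augmented cloud: moments of the distances from
# every point to each reference point, reference points in fixed order
descriptor_values <- function(points) {
  refs <- if (ncol(points) == 3L) usr_reference_points(points) else electroshape_reference_points(points)
  as.vector(apply(refs, 1L, function(r) moment_triple(dist_to_point(points, r))))
}

#' Compute the shape descriptor of one conformer
#'
#' Builds the augmented point cloud for the scheme, computes the Euclidean
#' distance (in the full augmented space) of every point to each reference
#' point, and condenses each distance distribution into its moment triple.
#' The result is 12 values for `usr` (4 reference points) and 15 for
#' `es4d`/`es5d` (5 reference points), invariant under rigid rotation and
#' translation of the coordinates.
#'
#' @inheritParams augment_points
#' @return A one-row tibble with columns `mol_id`, `conf_id`, `method` and
#'   the descriptor values `m01`, `m02`, ...
#' @examples
#' cr <- conformer_record("m", 0, matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
#' compute_descriptor(cr, "usr")
#' @export
compute_descriptor <- function(conformer, scheme) {
  scheme <- as_scheme(scheme)
  pts <- augment_points(conformer, scheme)
  vals <- descriptor_values(pts)
  out <- tibble::tibble(mol_id = conformer$mol_id,
                        conf_id = conformer$conf_id,
                        method = scheme$method)
  out[descriptor_cols(scheme$method)] <- as.list(vals)
  out
}

#' Compute descriptors for a batch of conformers
#'
#' Order-preserving map of [compute_descriptor()]. Conformers the scheme
#' cannot handle (e.g. missing charges under `es5d`) are skipped with a
#' warning; the number skipped is attached as attribute `n_skipped`.
#'
#' @param conformers A list of [conformer_record()]s (or a single record).
#' @inheritParams augment_points
#' @return A descriptor tibble with one row per successful conformer.
#' @export
compute_descriptors <- function(conformers, scheme) {
  scheme <- as_scheme(scheme)
  conformers <- as_conformer_list(conformers)
  if (length(conformers) == 0L) {
    out <- empty_descriptor_table(scheme$method)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  rows <- purrr::map(conformers, function(cr) {
    tryCatch(compute_descriptor(cr, scheme), error = function(e) NULL)
  })
  failed <- vapply(rows, is.null, logical(1))
  if (all(failed)) abort("All conformers failed descriptor computation.")
  if (any(failed)) {
    warn(sprintf("Skipped %d of %d conformers during descriptor computation.",
                 sum(failed), length(failed)))
  }
  out <- dplyr::bind_rows(rows[!failed])
  attr(out, "n_skipped") <- sum(failed)
  out
}

empty_descriptor_table <- function(method) {
  out <- tibble::tibble(mol_id = character(), conf_id = integer(),
                        method = character())
  out[descriptor_cols(method)] <- purrr::map(descriptor_cols(method), ~ double())
  out
}

# numeric matrix of the value columns of a descriptor tibble
descriptor_matrix <- function(descriptors, method = NULL) {
  method <- method %||% unique(descriptors$method)
  if (length(method) != 1L) abort("Descriptor table mixes methods.")
  as.matrix(descriptors[descriptor_cols(method)])
}
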