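#' Random point-cloud "molecule"
#'
#' Draws a synthetic conformer for descriptor testing: atom coordinates
#' uniform in a 10-angstrom box, partial charges and logP contributions
#' uniform in `[-0.5, 0.5]`, energy 0. Deterministic per seed.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param seed Integer seed.
#' @param mol_id,conf_id Identifiers for the record.
#' @return A [conformer_record()].
#' @export
random_point_cloud <- function(n_atoms, seed, mol_id = "cloud", conf_id = 0L) {
  if (n_atoms < 1L) abort("`n_atoms` must be >= 1.")
  withr::with_seed(seed, {
    conformer_record(
      mol_id, conf_id,
      coords = matrix(runif(n_atoms * 3L, 0, 10), ncol = 3L),
      charges = runif(n_atoms, -0.5, 0.5),
      logp_contribs = runif(n_atoms, -0.5, 0.5),
      energy = 0
    )
  })
}

#' Mirror image of a conformer
#'
#' Negates the x coordinate of every atom, producing the enantiomeric point
#' cloud; charges and logP contributions are untouched. Applying it twice
#' restores the original record.
#'
#' @param conformer A [conformer_record()].
#' @return The mirrored [conformer_record()].
#' @export
mirror_conformer <- function(conformer) {
  stopifnot(is_conformer_record(conformer))
  conformer$coords[, 1L] <- -conformer$coords[, 1L]
  conformer
}

#' Random rigid transform of a conformer
#'
#' Applies a uniformly random proper rotation and a random translation
#' (components uniform in `[-5, 5]` angstrom) to the coordinates; charges
#' and logP contributions are untouched. All interatomic distances are
#' preserved.
#'
#' @inheritParams mirror_conformer
#' @param seed Integer seed.
#' @return The transformed [conformer_record()].
#' @export
rigid_transform <- function(conformer, seed) {
  stopifnot(is_conformer_record(conformer))
  withr::with_seed(seed, {
    R <- random_rotation3()
    t <- runif(3L, -5, 5)
    conformer$coords <- sweep(conformer$coords %*% t(R), 2L, t, "+")
  })
  conformer
}

# Haar-uniform proper rotation via QR of a Gaussian matrix
random_rotation3 <- function() {
  qrd <- qr(matrix(rnorm(9L), 3L, 3L))
  R <- qr.Q(qrd)
  d <- diag(qr.R(qrd))
  R <- R %*% diag(sign(d))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Sample a descriptor population from a Gaussian mixture
#'
#' Draws i.i.d. descriptor vectors from a known mixture, tagged with
#' synthetic molecule/conformer identifiers. Used for parameter-recovery
#' and density tests of the descriptor-space models.
#'
#' @param weights Mixture weights (sum to 1).
#' @param means List (or matrix with one row per component) of component
#'   means, all the same dimension.
#' @param covariances List of positive-definite covariance matrices.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param method Method tag for the resulting table (defaults to `"usr"`
#'   for dimension 12, `"es5d"` for 15, `"synthetic"` otherwise).
#' @return A descriptor tibble with a `component` column carrying the
#'   ground-truth component of each draw.
#' @export
sample_descriptor_population <- function(weights, means, covariances, n, seed,
                                         method = NULL) {
  if (is.matrix(means)) means <- asplit(means, 1L)
  means <- purrr::map(means, as.double)
  M <- length(weights)
  if (length(means) != M || length(covariances) != M) {
    abort("`weights`, `means` and `covariances` must have one entry per component.")
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    abort("`weights` must be non-negative and sum to 1.")
  }
  d <- length(means[[1L]])
  chols <- purrr::map(covariances, function(S) {
    S <- as.matrix(S)
    if (!isTRUE(all.equal(S, t(S))) || nrow(S) != d) {
      abort("Covariances must be symmetric and match the mean dimension.")
    }
    tryCatch(chol(S), error = function(e) abort("Covariances must be positive-definite."))
  })
  method <- method %||% switch(as.character(d), "12" = "usr", "15" = "es5d", "synthetic")
  withr::with_seed(seed, {
    comp <- sample.int(M, n, replace = TRUE, prob = weights)
    z <- matrix(rnorm(n * d), n, d)
    x <- matrix(0, n, d)
    for (k in seq_len(M)) {
      idx <- comp == k
      if (any(idx)) {
        x[idx, ] <- sweep(z[idx, , drop = FALSE] %*% chols[[k]], 2L, means[[k]], "+")
      }
    }
    out <- tibble::tibble(mol_id = sprintf("synth%05d", seq_len(n)),
                          conf_id = 0L, method = method, component = comp)
    out[sprintf("m%02d", seq_len(d))] <- as.data.frame(x)
    out
  })
}

#' Configuration of a synthetic screening scenario
#'
#' Defines a descriptor-space retrospective-screening scenario with
#' controllable difficulty. Active conformer descriptors are drawn from
#' `active_modes` Gaussian clusters (one per hypothetical binding mode)
#' whose centers sit `separation` descriptor units from the origin along
#' mutually orthogonal axes; decoy descriptors come from a broad background
#' Gaussian (sd `3 * noise_sd`) centered at the origin, rejected when
#' closer than `separation` to any active center. With `separation = 0`
#' the scenario degenerates to the null case: decoys are drawn from the
#' same distribution as actives, so labels carry no information.
#'
#' @param n_actives,n_decoys Number of active / decoy molecules.
#' @param n_conformers_per_mol Descriptor draws per molecule.
#' @param active_modes Number of active clusters (binding modes, >= 1).
#' @param separation Distance between active-cluster centers and the decoy
#'   population, in descriptor units.
#' @param noise_sd Within-cluster spread.
#' @param descriptor_dim 12 (USR-shaped) or 15 (ElectroShape-shaped).
#' @param seed Integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_actives = 20, n_decoys = 1000,
                            n_conformers_per_mol = 5, active_modes = 2,
                            separation = 8, noise_sd = 1,
                            descriptor_dim = 12, seed = 1) {
  stopifnot(n_actives >= 1, n_decoys >= 1, n_conformers_per_mol >= 1,
            active_modes >= 1, separation >= 0, noise_sd > 0,
            descriptor_dim %in% c(12L, 15L))
  structure(
    list(n_actives = as.integer(n_actives), n_decoys = as.integer(n_decoys),
         n_conformers_per_mol = as.integer(n_conformers_per_mol),
         active_modes = as.integer(active_modes),
         separation = as.double(separation), noise_sd = as.double(noise_sd),
         descriptor_dim = as.integer(descriptor_dim), seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Generate a labeled synthetic screening scenario
#'
#' Produces the descriptor table of a full active/decoy screening scenario
#' per [scenario_config()]: every molecule receives
#' `n_conformers_per_mol` descriptor draws with synthetic conformer
#' energies (so lowest-energy-conformer reduction is well defined) and a
#' ground-truth label.
#'
#' @param config A [scenario_config()].
#' @return An object of class `usrml_scenario`: a list with `descriptors`
#'   (tibble with `mol_id`, `conf_id`, `method`, `label`, `energy` and the
#'   descriptor values), `centers` (active cluster centers) and `config`.
#' @export
make_screening_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  d <- config$descriptor_dim
  if (config$active_modes > d) {
    abort(sprintf("Cannot place %d mutually separated modes in %d dimensions.",
                  config$active_modes, d))
  }
  centers <- matrix(0, config$active_modes, d)
  for (k in seq_len(config$active_modes)) centers[k, k] <- config$separation
  method <- if (d == 12L) "usr" else "es5d"
  k_conf <- config$n_conformers_per_mol
  null_case <- config$separation == 0

  withr::with_seed(config$seed, {
    draw_active_like <- function(n_rows) {
      modes <- sample.int(config$active_modes, n_rows, replace = TRUE)
      centers[modes, , drop = FALSE] +
        matrix(rnorm(n_rows * d, sd = config$noise_sd), n_rows, d)
    }
    # actives: molecule -> mode round-robin, conformers i.i.d. around the center
    a_mode <- rep_len(seq_len(config$active_modes), config$n_actives)
    a_rows <- config$n_actives * k_conf
    a_x <- centers[rep(a_mode, each = k_conf), , drop = FALSE] +
      matrix(rnorm(a_rows * d, sd = config$noise_sd), a_rows, d)
    # decoys: broad background, kept at >= separation from every center
    d_rows <- config$n_decoys * k_conf
    if (null_case) {
      d_x <- draw_active_like(d_rows)
    } else {
      d_x <- matrix(0, 0, d)
      tries <- 0L
      while (nrow(d_x) < d_rows) {
        tries <- tries + 1L
        if (tries > 50L) abort("Scenario geometry infeasible: decoy rejection rate too high.")
        cand <- matrix(rnorm(d_rows * d, sd = 3 * config$noise_sd), d_rows, d)
        min_dist <- apply(cand, 1L, function(x) {
          min(sqrt(colSums((t(centers) - x)^2)))
        })
        d_x <- rbind(d_x, cand[min_dist >= config$separation, , drop = FALSE])
      }
      d_x <- d_x[seq_len(d_rows), , drop = FALSE]
    }
    x <- rbind(a_x, d_x)
    out <- tibble::tibble(
      mol_id = c(rep(sprintf("act%04d", seq_len(config$n_actives)), each = k_conf),
                 rep(sprintf("dec%04d", seq_len(config$n_decoys)), each = k_conf)),
      conf_id = rep(seq_len(k_conf) - 1L, config$n_actives + config$n_decoys),
      method = method,
      label = c(rep("active", a_rows), rep("decoy", d_rows)),
      energy = runif(a_rows + d_rows, 0, 10)
    )
    out[sprintf("m%02d", seq_len(d))] <- as.data.frame(x)
    structure(list(descriptors = out, centers = centers, config = config),
              class = "usrml_scenario")
  })
}

#' @export
print.usrml_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<usrml_scenario: %d actives (%d modes) / %d decoys, ",
                     "%d confs/mol, dim %d, separation %.3g, noise %.3g>\n"),
              cfg$n_actives, cfg$active_modes, cfg$n_decoys,
              cfg$n_conformers_per_mol, cfg$descriptor_dim,
              cfg$separation, cfg$noise_sd))
  invisible(x)
}
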