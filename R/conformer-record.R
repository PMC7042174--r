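#' Create a conformer record
#'
#' A conformer record holds one 3D geometry of a molecule together with the
#' per-atom quantities the descriptor schemes consume: Cartesian coordinates
#' (angstrom), partial charges (elementary charge), per-atom lipophilicity
#' contributions (ALogP-type, dimensionless) and the force-field energy
#' (kcal/mol). Records are the unit handed to [compute_descriptor()] and the
#' unit produced by [generate_conformers()] and [read_sdf()].
#'
#' @param mol_id Molecule identifier (non-empty string).
#' @param conf_id Non-negative integer conformer index within the molecule.
#' @param coords Numeric n x 3 matrix of atom coordinates in angstrom.
#' @param charges Optional numeric vector of per-atom partial charges
#'   (length n). Required by the `es4d` and `es5d` descriptor schemes.
#' @param logp_contribs Optional numeric vector of per-atom logP
#'   contributions (length n). Required by the `es5d` scheme.
#' @param energy Force-field energy in kcal/mol (single number).
#' @param elements Optional character vector of element symbols (length n);
#'   used only when a descriptor scheme excludes hydrogens.
#'
#' @return An object of class `conformer_record`.
#' @examples
#' conformer_record("mol1", 0, matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE))
#' @export
conformer_record <- function(mol_id, conf_id, coords, charges = NULL,
                             logp_contribs = NULL, energy = 0,
                             elements = NULL) {
  if (!is_string(mol_id)) abort("`mol_id` must be a non-empty string.")
  conf_id <- as.integer(conf_id)
  if (length(conf_id) != 1L || is.na(conf_id) || conf_id < 0L) {
    abort("`conf_id` must be a single non-negative integer.")
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) < 1L) {
    abort("`coords` must be an n x 3 matrix with n >= 1.")
  }
  if (!all(is.finite(coords))) abort("`coords` must be finite.")
  n <- nrow(coords)
  check_peratom <- function(x, name) {
    if (is.null(x)) return(NULL)
    x <- as.double(x)
    if (length(x) != n || !all(is.finite(x))) {
      abort(sprintf("`%s` must be a finite numeric vector of length n = %d.", name, n))
    }
    x
  }
  charges <- check_peratom(charges, "charges")
  logp_contribs <- check_peratom(logp_contribs, "logp_contribs")
  if (!is.null(elements) && length(elements) != n) {
    abort("`elements` must have one symbol per atom.")
  }
  assert_number(energy, "energy")
  structure(
    list(mol_id = mol_id, conf_id = conf_id, coords = coords,
         charges = charges, logp_contribs = logp_contribs,
         energy = as.double(energy), elements = elements),
    class = "conformer_record"
  )
}

#' @export
print.conformer_record <- function(x, ...) {
  cat(sprintf("<conformer_record %s/%d: %d atoms, E = %.3f kcal/mol%s%s>\n",
              x$mol_id, x$conf_id, nrow(x$coords), x$energy,
              if (is.null(x$charges)) "" else ", charges",
              if (is.null(x$logp_contribs)) "" else ", logP"))
  invisible(x)
}

is_conformer_record <- function(x) inherits(x, "conformer_record")

as_conformer_list <- function(x, arg = "conformers") {
  if (is_conformer_record(x)) return(list(x))
  if (is.list(x) && all(vapply(x, is_conformer_record, logical(1)))) return(x)
  abort(sprintf("`%s` must be a conformer_record or a list of them.", arg))
}
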