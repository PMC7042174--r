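# Conformer generation and selection. The chemistry itself (SMILES
# parsing, MolVS-style standardization, ETKDG embedding, MMFF94 energies
# and charges, Crippen atomic logP) is delegated to RDKit through the
# bundled python helper; this file owns the R surface and the energy-window
# and LEC rules.

the_backend <- new.env(parent = emptyenv())

#' Is the RDKit chemistry backend available?
#'
#' The conformer engine and SMILES validation shell out to a bundled
#' python helper that requires RDKit. This checks (once per session) that
#' a python interpreter with RDKit can be found; set
#' `options(usrml.python = "/path/to/python")` to point at a specific
#' interpreter.
#'
#' @return `TRUE` or `FALSE`.
#' @export
chem_backend_available <- function() {
  if (!is.null(the_backend$available)) return(the_backend$available)
  py <- getOption("usrml.python", Sys.which("python"))
  ok <- nzchar(py) &&
    identical(tryCatch(system2(py, c("-c", shQuote("import rdkit")),
                               stdout = FALSE, stderr = FALSE),
                       error = function(e) 1L), 0L)
  the_backend$python <- py
  the_backend$available <- ok
  ok
}

chem_backend_json <- function(command, smiles_lines, args = character(0)) {
  if (!chem_backend_available()) {
    abort(paste("The chemistry backend (python with RDKit) is not available;",
                "see ?chem_backend_available."))
  }
  script <- system.file("python", "chem_backend.py", package = "usrml")
  if (!nzchar(script)) abort("Bundled chem_backend.py not found; reinstall the package.")
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(smiles_lines, infile)
  out <- suppressWarnings(
    system2(the_backend$python, c(script, command, "--in", infile, args),
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L) abort(sprintf("Chemistry backend failed (command '%s').", command))
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

#' Standardize molecules
#'
#' Validates and standardizes SMILES through the RDKit standardizer:
#' functional-group normalization, largest-fragment selection and
#' neutralization. The operation is idempotent - standardizing an already
#' standardized structure returns it unchanged. Records that fail are
#' dropped with a warning (their count is in the `n_failed` attribute).
#'
#' @param molecules A molecule tibble (with `mol_id` and `smiles` columns,
#'   as from [read_smiles_file()]) or a character vector of SMILES.
#' @return The same shape with standardized SMILES; failed character
#'   entries are `NA`.
#' @export
standardize_molecule <- function(molecules) {
  if (is.character(molecules)) {
    res <- chem_backend_json("standardize", molecules)
    out <- vapply(res, function(r) {
      if (isTRUE(r$ok)) r$standardized else NA_character_
    }, character(1))
    if (anyNA(out)) warn(sprintf("Standardization failed for %d molecule(s).", sum(is.na(out))))
    return(out)
  }
  if (!is.data.frame(molecules) || !all(c("mol_id", "smiles") %in% names(molecules))) {
    abort("`molecules` must be a molecule tibble or a character vector of SMILES.")
  }
  std <- standardize_molecule(molecules$smiles)
  ok <- !is.na(std)
  out <- molecules[ok, ]
  out$smiles <- std[ok]
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Generate 3D conformers for molecules
#'
#' Embeds up to `max_conformers` conformers per molecule with ETKDG
#' (torsion-knowledge distance geometry, whose embedded experimental
#' knowledge yields geometries that are already effectively
#' energy-minimized, so no minimization step is applied), computes a
#' single-point MMFF94 energy per conformer, attaches MMFF94 (or
#' Gasteiger) partial charges and Crippen per-atom logP contributions, and
#' prunes each molecule's ensemble with [filter_by_energy_window()]. Fully
#' reproducible given `seed`. Molecules whose embedding fails are excluded
#' with a warning and counted in the `n_failed` attribute.
#'
#' @param molecules Molecule tibble (`mol_id`, `smiles`) or character
#'   vector of SMILES (auto-numbered ids).
#' @param max_conformers Conformer cap per molecule (default 200).
#' @param energy_window Energy-window width in kcal/mol (default 5).
#' @param seed Integer seed for the stochastic embedding.
#' @param charge_model `"mmff94"` (default) or `"gasteiger"`.
#' @return Flat list of [conformer_record()]s (grouped by molecule, in
#'   input order).
#' @export
generate_conformers <- function(molecules, max_conformers = 200,
                                energy_window = 5, seed = 42,
                                charge_model = c("mmff94", "gasteiger")) {
  charge_model <- match.arg(charge_model)
  if (max_conformers < 1L) abort("`max_conformers` must be >= 1.")
  assert_number(energy_window, "energy_window", 0, strict = TRUE)
  if (is.character(molecules)) {
    molecules <- tibble::tibble(mol_id = sprintf("mol%04d", seq_along(molecules)),
                                smiles = molecules)
  }
  lines <- paste(molecules$smiles, molecules$mol_id)
  res <- chem_backend_json(
    "conformers", lines,
    c("--max-confs", max_conformers, "--seed", seed, "--charge-model", charge_model)
  )
  n_failed <- 0L
  out <- list()
  for (entry in res) {
    if (!is.null(entry$error) || length(entry$conformers) == 0L) {
      n_failed <- n_failed + 1L
      next
    }
    charges <- as.double(unlist(entry$charges))
    logp <- as.double(unlist(entry$logp_contribs))
    elements <- as.character(unlist(entry$elements))
    confs <- purrr::map(entry$conformers, function(cf) {
      conformer_record(entry$mol_id, cf$conf_id,
                       coords = do.call(rbind, purrr::map(cf$coords, unlist)),
                       charges = charges, logp_contribs = logp,
                       energy = cf$energy, elements = elements)
    })
    out <- c(out, filter_by_energy_window(confs, energy_window))
  }
  if (n_failed > 0L) {
    warn(sprintf("Conformer embedding failed for %d molecule(s); excluded.", n_failed))
  }
  attr(out, "n_failed") <- n_failed
  out
}

#' Prune conformers by an energy window above the LEC
#'
#' Keeps a conformer exactly when its energy lies strictly less than
#' `window` kcal/mol above the molecule's lowest-energy conformer:
#' conformers higher by `window` *or more* are removed. Order is
#' preserved and the lowest-energy conformer itself always survives.
#'
#' @param conformers List of [conformer_record()]s sharing one `mol_id`.
#' @param window Window width in kcal/mol (default 5).
#' @return Filtered list (possibly empty when the input is empty).
#' @export
filter_by_energy_window <- function(conformers, window = 5) {
  assert_number(window, "window", 0, strict = TRUE)
  conformers <- as_conformer_list(conformers)
  if (length(conformers) == 0L) return(conformers)
  if (length(unique(purrr::map_chr(conformers, "mol_id"))) != 1L) {
    abort("All conformers must share one mol_id.")
  }
  energies <- purrr::map_dbl(conformers, "energy")
  conformers[energies - min(energies) < window]
}

#' Select the lowest-energy conformer
#'
#' Returns the conformer with minimum energy; ties are broken by the
#' lowest `conf_id`.
#'
#' @param conformers Non-empty list of [conformer_record()]s sharing one
#'   `mol_id`.
#' @return A single [conformer_record()].
#' @export
select_lec <- function(conformers) {
  conformers <- as_conformer_list(conformers)
  if (length(conformers) == 0L) abort("Cannot select the LEC of an empty conformer list.")
  if (length(unique(purrr::map_chr(conformers, "mol_id"))) != 1L) {
    abort("All conformers must share one mol_id.")
  }
  energies <- purrr::map_dbl(conformers, "energy")
  conf_ids <- purrr::map_int(conformers, "conf_id")
  conformers[[order(energies, conf_ids)[1L]]]
}
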