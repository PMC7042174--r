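#' Read a SMILES library file
#'
#' Parses a `.smi`-style file: one molecule per line, whitespace-separated
#' `SMILES identifier`, with `#` comment lines and blank lines ignored.
#' Each SMILES is validated with the RDKit backend; unparseable records are
#' skipped with a warning and counted in the `n_skipped` attribute.
#'
#' @param path Path to the SMILES file.
#' @param validate Check each SMILES with the chemistry backend (default
#'   `TRUE`; set `FALSE` for syntax-only splitting when RDKit is absent).
#' @return A molecule tibble with columns `mol_id`, `smiles`, `label`
#'   (initialized to `"unknown"`).
#' @export
read_smiles_file <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(sprintf("SMILES file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_skipped <- 0L
  records <- purrr::map(lines, function(ln) {
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (length(tok) < 2L) return(NULL)
    tibble::tibble(mol_id = tok[[2L]], smiles = tok[[1L]])
  })
  bad_shape <- vapply(records, is.null, logical(1))
  if (any(bad_shape)) {
    warn(sprintf("Skipped %d line(s) without 'SMILES identifier' shape.", sum(bad_shape)))
    n_skipped <- n_skipped + sum(bad_shape)
  }
  out <- dplyr::bind_rows(records[!bad_shape])
  if (validate && nrow(out) > 0L) {
    res <- chem_backend_json("validate", out$smiles)
    ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
    if (any(!ok)) {
      warn(sprintf("Skipped %d unparseable SMILES record(s): %s",
                   sum(!ok), paste(out$mol_id[!ok], collapse = ", ")))
      n_skipped <- n_skipped + sum(!ok)
      out <- out[ok, ]
    }
  }
  if (nrow(out) == 0L) abort(sprintf("No parseable SMILES records in %s.", path))
  if (anyDuplicated(out$mol_id)) abort("Duplicate mol_id values in SMILES file.")
  out$label <- "unknown"
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read conformers from an SDF file
#'
#' Reads a V2000 (or, via OpenBabel conversion, V3000) SDF with 3D
#' coordinates into conformer records. The molecule title supplies
#' `mol_id` unless `id_property` names an SDF data field to use instead;
#' `conf_id` is assigned sequentially per molecule starting at 0, in file
#' order. Per-atom charges and logP contributions are taken from the
#' space-separated `CHARGES` and `LOGP_CONTRIBS` data fields when present
#' and the energy from `ENERGY_KCAL_MOL`. Entries whose z coordinates are
#' all zero are emitted with a "2D suspect" warning; corrupt entries are
#' skipped with a warning.
#'
#' @param path Path to the SDF file.
#' @param id_property Optional SDF data-field name overriding the title as
#'   the source of `mol_id`.
#' @return List of [conformer_record()]s.
#' @export
read_sdf <- function(path, id_property = NULL) {
  if (!file.exists(path)) abort(sprintf("SDF file not found: %s", path))
  head_lines <- readLines(path, n = 200L, warn = FALSE)
  if (any(grepl("V3000", head_lines, fixed = TRUE))) {
    path <- convert_v3000(path)
  }
  all_lines <- readLines(path, warn = FALSE)
  breaks <- which(trimws(all_lines) == "$$$$")
  starts <- c(1L, head(breaks, -1L) + 1L)
  ends <- if (length(breaks) > 0L) breaks - 1L else length(all_lines)
  records <- list()
  conf_counter <- integer(0)
  n_skipped <- 0L
  suspect <- character(0)
  for (e in seq_along(starts)) {
    lines <- all_lines[starts[e]:ends[e]]
    if (all(!nzchar(trimws(lines)))) next
    entry <- tryCatch(parse_v2000_entry(lines), error = function(err) NULL)
    rec <- tryCatch({
      db <- entry$db
      mol_id <- if (!is.null(id_property) && id_property %in% names(db)) {
        db[[id_property]]
      } else if (is_string(entry$title)) entry$title else sprintf("mol%04d", e)
      parse_field <- function(name) {
        if (name %in% names(db)) as.double(strsplit(trimws(db[[name]]), "\\s+")[[1L]]) else NULL
      }
      energy <- if ("ENERGY_KCAL_MOL" %in% names(db)) as.double(db[["ENERGY_KCAL_MOL"]]) else 0
      conf_counter[mol_id] <- if (mol_id %in% names(conf_counter)) conf_counter[[mol_id]] + 1L else 0L
      conformer_record(mol_id, conf_counter[[mol_id]], entry$coords,
                       charges = parse_field("CHARGES"),
                       logp_contribs = parse_field("LOGP_CONTRIBS"),
                       energy = energy, elements = entry$elements)
    }, error = function(err) NULL)
    if (is.null(rec)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (all(rec$coords[, 3L] == 0)) suspect <- c(suspect, rec$mol_id)
    records[[length(records) + 1L]] <- rec
  }
  if (n_skipped > 0L) warn(sprintf("Skipped %d corrupt SDF entr(ies).", n_skipped))
  if (length(suspect) > 0L) {
    warn(sprintf("2D suspect (all z = 0): %s", paste(unique(suspect), collapse = ", ")))
  }
  attr(records, "n_skipped") <- n_skipped
  records
}

# fixed-width V2000 field extraction for one entry (lines up to its $$$$).
# Done in-package because the established SDF reader collapses the atom
# block of single-atom / bond-less entries, which this pipeline must accept.
parse_v2000_entry <- function(lines) {
  if (length(lines) < 5L) abort("Truncated SDF entry.")
  n_atoms <- as.integer(substr(lines[4L], 1L, 3L))
  if (is.na(n_atoms) || n_atoms < 1L || length(lines) < 4L + n_atoms) {
    abort("Malformed counts line in SDF entry.")
  }
  atom_lines <- lines[5L:(4L + n_atoms)]
  coords <- cbind(as.numeric(substr(atom_lines, 1L, 10L)),
                  as.numeric(substr(atom_lines, 11L, 20L)),
                  as.numeric(substr(atom_lines, 21L, 30L)))
  if (any(is.na(coords))) abort("Malformed atom block in SDF entry.")
  elements <- trimws(substr(atom_lines, 31L, 34L))
  db <- list()
  i <- 5L + n_atoms
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      name <- sub("^>.*<([^>]+)>.*$", "\\1", lines[i])
      vals <- character(0)
      i <- i + 1L
      while (i <= length(lines) && nzchar(trimws(lines[i])) && !startsWith(lines[i], ">")) {
        vals <- c(vals, lines[i])
        i <- i + 1L
      }
      db[[name]] <- paste(vals, collapse = " ")
    } else {
      i <- i + 1L
    }
  }
  list(title = trimws(lines[1L]), coords = coords, elements = elements, db = db)
}

convert_v3000 <- function(path) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) abort("V3000 SDF support requires the OpenBabel CLI (obabel).")
  out <- tempfile(fileext = ".sdf")
  status <- system2(obabel, c(shQuote(path), "-osdf", "-O", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out)) abort("OpenBabel V3000 conversion failed.")
  out
}

#' Write conformer records to an SDF file
#'
#' Emits one V2000 entry per conformer: the molecule title carries
#' `mol_id`, the atom block the coordinates (element symbols default to
#' `C` when the record has none, and no bond block is written - point
#' clouds carry no bond graph), and the data fields `ENERGY_KCAL_MOL`,
#' `CHARGES` and `LOGP_CONTRIBS` the per-record quantities.
#'
#' @param conformers A [conformer_record()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(conformers, path) {
  conformers <- as_conformer_list(conformers)
  entries <- purrr::map_chr(conformers, function(cr) {
    n <- nrow(cr$coords)
    elements <- cr$elements %||% rep("C", n)
    atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     cr$coords[, 1L], cr$coords[, 2L], cr$coords[, 3L], elements)
    props <- c(sprintf(">  <ENERGY_KCAL_MOL>\n%.8g\n", cr$energy))
    if (!is.null(cr$charges)) {
      props <- c(props, sprintf(">  <CHARGES>\n%s\n", paste(format(cr$charges, digits = 10), collapse = " ")))
    }
    if (!is.null(cr$logp_contribs)) {
      props <- c(props, sprintf(">  <LOGP_CONTRIBS>\n%s\n", paste(format(cr$logp_contribs, digits = 10), collapse = " ")))
    }
    paste(c(cr$mol_id, "  usrml", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
            atoms, "M  END", props, "$$$$"), collapse = "\n")
  })
  writeLines(paste(entries, collapse = "\n"), path)
  invisible(path)
}

descriptor_table_header <- c("mol_id", "conf_id", "method", sprintf("m%02d", 1:15))

#' Write / read a descriptor table
#'
#' Descriptor tables are plain CSV with the fixed header `mol_id, conf_id,
#' method, m01...m15`; USR tables leave `m13`-`m15` empty. Values are
#' written at full precision, so a write/read round trip reproduces the
#' descriptors to at least 12 significant digits. A table must be
#' homogeneous in its method tag; mixed tags or a USR row carrying
#' 15 values are format errors.
#'
#' @param descriptors Descriptor tibble (single method).
#' @param path CSV path.
#' @return `write_descriptor_table()` returns `path` invisibly;
#'   `read_descriptor_table()` returns the descriptor tibble.
#' @export
write_descriptor_table <- function(descriptors, path) {
  method <- unique(descriptors$method)
  if (nrow(descriptors) > 0L && length(method) != 1L) {
    abort("Descriptor table must hold a single method tag.")
  }
  out <- descriptors
  for (col in setdiff(sprintf("m%02d", 1:15), names(out))) out[[col]] <- NA_real_
  out <- out[descriptor_table_header]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Descriptor table not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  if (!identical(header, descriptor_table_header)) {
    abort("Descriptor table header mismatch.")
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(
    mol_id = readr::col_character(), conf_id = readr::col_integer(),
    method = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (nrow(tbl) == 0L) return(empty_descriptor_table("usr"))
  method <- unique(tbl$method)
  if (length(method) != 1L || !(method %in% c("usr", "es4d", "es5d"))) {
    abort("Descriptor table must hold a single valid method tag.")
  }
  if (method == "usr") {
    if (any(!is.na(as.matrix(tbl[sprintf("m%02d", 13:15)])))) {
      abort("USR descriptor table carries values beyond m12.")
    }
    tbl <- tbl[c("mol_id", "conf_id", "method", sprintf("m%02d", 1:12))]
  }
  if (any(!stats::complete.cases(tbl))) abort("Descriptor table has missing values.")
  tbl
}

#' Assemble a per-target active/decoy dataset
#'
#' Reads active and decoy SMILES files, labels the molecules by file
#' membership, and attaches conformers (from SDF files) by `mol_id`.
#' Molecules without conformers are retained and counted. Overlapping
#' identifiers between the two files are a consistency error.
#'
#' @param actives_path,decoys_path SMILES files of actives and decoys.
#' @param conformer_paths Optional character vector of SDF files.
#' @param target_id Identifier for the target (default: actives file stem).
#' @param validate Passed to [read_smiles_file()].
#' @return An object of class `target_dataset`: list with `target_id`,
#'   `molecules` (tibble `mol_id`, `smiles`, `label`), `conformers` (named
#'   list of conformer-record lists) and `n_missing_conformers`.
#' @export
assemble_target_dataset <- function(actives_path, decoys_path,
                                    conformer_paths = NULL, target_id = NULL,
                                    validate = TRUE) {
  actives <- read_smiles_file(actives_path, validate = validate)
  decoys <- read_smiles_file(decoys_path, validate = validate)
  overlap <- intersect(actives$mol_id, decoys$mol_id)
  if (length(overlap) > 0L) {
    abort(sprintf("mol_id present in both actives and decoys: %s",
                  paste(overlap, collapse = ", ")))
  }
  actives$label <- "active"
  decoys$label <- "decoy"
  molecules <- dplyr::bind_rows(actives, decoys)
  conformers <- list()
  for (p in conformer_paths %||% character(0)) {
    for (cr in read_sdf(p)) {
      conformers[[cr$mol_id]] <- c(conformers[[cr$mol_id]], list(cr))
    }
  }
  unknown <- setdiff(names(conformers), molecules$mol_id)
  if (length(unknown) > 0L) {
    warn(sprintf("Dropping conformers for %d unknown molecule(s).", length(unknown)))
    conformers <- conformers[setdiff(names(conformers), unknown)]
  }
  missing <- setdiff(molecules$mol_id, names(conformers))
  structure(
    list(target_id = target_id %||% sub("\\.[^.]*$", "", basename(actives_path)),
         molecules = molecules, conformers = conformers,
         n_missing_conformers = length(missing)),
    class = "target_dataset"
  )
}

#' @export
print.target_dataset <- function(x, ...) {
  cat(sprintf("<target_dataset %s: %d actives / %d decoys, conformers for %d molecules%s>\n",
              x$target_id, sum(x$molecules$label == "active"),
              sum(x$molecules$label == "decoy"), length(x$conformers),
              if (x$n_missing_conformers > 0)
                sprintf(" (%d without)", x$n_missing_conformers) else ""))
  invisible(x)
}

#' Write / read a dataset manifest
#'
#' A manifest is a small JSON document `{target_id, actives, decoys}`
#' recording the label partition of a target dataset.
#'
#' @param dataset A `target_dataset` (or a labeled molecule tibble plus
#'   `target_id`).
#' @param path JSON path.
#' @return `write_dataset_manifest()` returns `path` invisibly;
#'   `read_dataset_manifest()` returns a list with `target_id`, `actives`,
#'   `decoys`.
#' @export
write_dataset_manifest <- function(dataset, path) {
  stopifnot(inherits(dataset, "target_dataset"))
  jsonlite::write_json(
    list(target_id = dataset$target_id,
         actives = dataset$molecules$mol_id[dataset$molecules$label == "active"],
         decoys = dataset$molecules$mol_id[dataset$molecules$label == "decoy"]),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_dataset_manifest
#' @export
read_dataset_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(intersect(m$actives, m$decoys)) > 0L) {
    abort("Manifest lists molecules as both active and decoy.")
  }
  m
}
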