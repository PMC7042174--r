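#' Inverse-Manhattan similarity between two descriptors
#'
#' The classical USR similarity: `S = 1 / (1 + mean(|q - i|))`, i.e. the
#' reciprocal of one plus the Manhattan distance normalized by the number of
#' descriptor elements (12 for `usr`, 15 for `es4d`/`es5d`). The score is
#' symmetric, lies in `(0, 1]`, and equals 1 exactly when the descriptors
#' are identical.
#'
#' @param q,i Descriptor value vectors of equal length (12 or 15), or
#'   one-row descriptor tibbles with matching `method`.
#' @return A single similarity value in `(0, 1]`.
#' @examples
#' usr_similarity(rep(0, 12), rep(1, 12))  # 0.5
#' @export
usr_similarity <- function(q, i) {
  q <- descriptor_vector(q)
  i <- descriptor_vector(i)
  if (length(q) != length(i)) abort("Descriptors differ in length.")
  if (!(length(q) %in% c(12L, 15L))) abort("Descriptors must have 12 or 15 elements.")
  1 / (1 + mean(abs(q - i)))
}

descriptor_vector <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort("Expected a single descriptor (one row).")
    return(as.double(descriptor_matrix(x)[1L, ]))
  }
  abort("Descriptors must be numeric vectors or one-row descriptor tibbles.")
}

#' Maximum-similarity score between two conformer ensembles
#'
#' Compares every conformer descriptor of one molecule to every conformer
#' descriptor of another and takes the maximum similarity as the similarity
#' between the two molecules.
#'
#' @param query_confs,lib_confs Descriptor tibbles (or numeric matrices with
#'   one descriptor per row) for the conformers of the two molecules; both
#'   non-empty and of the same method.
#' @return A single similarity value in `(0, 1]`.
#' @export
molecule_similarity <- function(query_confs, lib_confs) {
  qm <- descriptor_rows(query_confs, "query_confs")
  lm <- descriptor_rows(lib_confs, "lib_confs")
  if (ncol(qm) != ncol(lm)) abort("Descriptor methods/lengths differ.")
  1 / (1 + min_pairwise_l1(qm, lm))
}

descriptor_rows <- function(x, arg) {
  m <- if (is.matrix(x)) x else if (is.data.frame(x)) descriptor_matrix(x) else
    abort(sprintf("`%s` must be a descriptor tibble or matrix.", arg))
  if (nrow(m) == 0L) abort(sprintf("`%s` is empty.", arg))
  if (!(ncol(m) %in% c(12L, 15L))) abort("Descriptors must have 12 or 15 elements.")
  m
}

# minimum over all row pairs of the normalized L1 distance between the rows
# of a and the rows of b (maximizing similarity == minimizing this distance)
min_pairwise_l1 <- function(a, b) {
  L <- ncol(a)
  best <- Inf
  for (r in seq_len(nrow(a))) {
    d <- rowSums(abs(sweep(b, 2L, a[r, ], "-"))) / L
    best <- min(best, min(d))
  }
  best
}

#' Classical template-based screening
#'
#' Ranks a compound library against a set of active templates with the
#' inverse-Manhattan similarity. Each library molecule is scored against
#' each template with the max-over-conformer-pairs rule and the best
#' template score is kept. In `"lec"` mode the templates are first reduced
#' to their lowest-energy conformer (an `energy` column is required unless
#' every template molecule already carries a single descriptor); the library
#' side always uses all available conformers.
#'
#' @param templates Descriptor tibble of the template (active) molecules.
#' @param library Descriptor tibble of the library to rank; an optional
#'   `label` column (`"active"`/`"decoy"`/`"unknown"`) is carried through.
#' @param mode `"full"` (all template conformers) or `"lec"`.
#' @return A tibble with columns `rank`, `mol_id`, `score`, `label`, sorted
#'   by decreasing score with ties broken by `mol_id`.
#' @export
screen_baseline <- function(templates, library, mode = c("full", "lec")) {
  mode <- match.arg(mode)
  if (!is.data.frame(templates) || nrow(templates) == 0L) abort("`templates` is empty.")
  if (!is.data.frame(library) || nrow(library) == 0L) abort("`library` is empty.")
  method <- unique(c(templates$method, library$method))
  if (length(method) != 1L) abort("Templates and library must share one descriptor method.")
  if (mode == "lec") templates <- reduce_to_lec(templates)
  tmat <- descriptor_matrix(templates, method)
  lib_labels <- if ("label" %in% names(library)) library$label else rep("unknown", nrow(library))
  scored <- library |>
    dplyr::mutate(.label = lib_labels) |>
    dplyr::group_by(.data$mol_id) |>
    dplyr::group_map(function(rows, key) {
      m <- as.matrix(rows[descriptor_cols(method)])
      tibble::tibble(mol_id = key$mol_id[[1L]],
                     score = 1 / (1 + min_pairwise_l1(m, tmat)),
                     label = rows$.label[[1L]])
    }) |>
    dplyr::bind_rows()
  rank_scored(scored)
}

# deterministic ranking: descending score, ties broken lexicographically
rank_scored <- function(scored) {
  scored |>
    dplyr::arrange(dplyr::desc(.data$score), .data$mol_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
}

#' Reduce a descriptor tibble to one lowest-energy conformer per molecule
#'
#' Keeps, for every molecule, the descriptor of the conformer with minimum
#' `energy` (ties broken by lowest `conf_id`). When no `energy` column is
#' present the table must already hold exactly one conformer per molecule.
#'
#' @param descriptors Descriptor tibble.
#' @return Descriptor tibble with one row per molecule.
#' @export
reduce_to_lec <- function(descriptors) {
  if (!"energy" %in% names(descriptors)) {
    n_per <- dplyr::count(descriptors, .data$mol_id)
    if (any(n_per$n > 1L)) {
      abort("LEC reduction needs an `energy` column when molecules have several conformers.")
    }
    return(descriptors)
  }
  descriptors |>
    dplyr::group_by(.data$mol_id) |>
    dplyr::arrange(.data$energy, .data$conf_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}
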