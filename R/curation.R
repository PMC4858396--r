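# ---------------------------------------------------------------------------
# Structure curation: neutralize, desalt, strip stereochemistry, reject
# metalorganics and very large molecules, canonicalize, deduplicate.
# ---------------------------------------------------------------------------

# proton-transfer neutralization: -1 on O/N/S gains a proton, +1 on N/P
# with a proton loses one; other charges (quaternary N, metals) are left
.neutralize <- function(mol) {
  h <- mol$atoms$hcount
  for (i in seq_len(n_atoms(mol))) {
    chg <- mol$atoms$charge[i]; el <- mol$atoms$element[i]
    if (chg == -1L && el %in% c("O", "N", "S")) {
      mol$atoms$charge[i] <- 0L
      mol$atoms$hcount[i] <- NA_integer_      # revert to implicit fill
    } else if (chg == 1L && el %in% c("N", "P")) {
      hh <- if (is.na(h[i])) 0L else h[i]
      if (hh >= 1L) {
        mol$atoms$charge[i] <- 0L
        mol$atoms$hcount[i] <- NA_integer_
      }
    }
  }
  .normalize_hcounts(mol)
}

#' Curate one structure record
#'
#' Applies the standardization rules: parse; keep the largest covalent
#' component of a mixture (counter-ions drop out here); neutralize charges
#' where a proton transfer suffices; strip stereochemistry (inherent to
#' parsing); reject metalorganics (carbon-metal bond) and molecules heavier
#' than `mw_limit`; canonicalize. Never raises on bad input.
#'
#' @param structure a SMILES string
#' @param id identifier carried into the result
#' @param mw_limit molecular-weight cutoff in g/mol (default 2000)
#' @return a list of class `curated_compound` (fields `id`,
#'   `canonical_structure`, `identity_key`, `mw`, `was_mixture`) or of class
#'   `rejection` (fields `id`, `reason` in \{"no_structure", "mw_gt_2000",
#'   "metalorganic", "unparseable"\})
#' @export
curate <- function(structure, id = NA_character_, mw_limit = 2000) {
  # NB: the `structure` argument shadows base::structure in this scope
  reject <- function(reason)
    base::structure(list(id = id, reason = reason), class = "rejection")
  if (is.null(structure) || is.na(structure) || !nzchar(trimws(structure)))
    return(reject("no_structure"))
  mol <- parse_smiles_safe(structure)
  if (is.null(mol)) return(reject("unparseable"))
  comps <- mol_components(mol)
  was_mixture <- length(comps) > 1L
  main <- comps[[1]]                        # most heavy atoms, then MW
  if (is_metalorganic(main)) return(reject("metalorganic"))
  main <- .neutralize(main)
  mw <- mol_weight(main)
  if (mw > mw_limit) return(reject("mw_gt_2000"))
  key <- canonical_smiles(main)
  base::structure(list(id = id, canonical_structure = key,
                       identity_key = key, mw = mw,
                       was_mixture = was_mixture),
                  class = "curated_compound")
}

#' Curate a vector of structures
#'
#' @param structures character vector of SMILES
#' @param ids identifiers (defaults to names or index)
#' @param mw_limit passed to [curate()]
#' @param verbose log one message per mixture resolved automatically
#' @return list with `curated` (data.frame `id`, `canonical_structure`,
#'   `identity_key`, `mw`, `was_mixture`) and `rejected` (data.frame `id`,
#'   `reason`); every input lands in exactly one of the two
#' @export
curate_library <- function(structures, ids = NULL, mw_limit = 2000,
                           verbose = FALSE) {
  if (is.null(ids)) {
    ids <- names(structures)
    if (is.null(ids)) ids <- as.character(seq_along(structures))
  }
  stopifnot(length(ids) == length(structures))
  cur <- list(); rej <- list()
  for (i in seq_along(structures)) {
    r <- curate(structures[[i]], ids[[i]], mw_limit)
    if (inherits(r, "rejection")) {
      rej[[length(rej) + 1L]] <- data.frame(id = r$id, reason = r$reason,
                                           stringsAsFactors = FALSE)
    } else {
      if (verbose && r$was_mixture)
        message("mixture resolved to largest component: ", r$id)
      cur[[length(cur) + 1L]] <- data.frame(
        id = r$id, canonical_structure = r$canonical_structure,
        identity_key = r$identity_key, mw = r$mw,
        was_mixture = r$was_mixture, stringsAsFactors = FALSE)
    }
  }
  list(curated = if (length(cur)) do.call(rbind, cur) else
         data.frame(id = character(0), canonical_structure = character(0),
                    identity_key = character(0), mw = numeric(0),
                    was_mixture = logical(0)),
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(id = character(0), reason = character(0)))
}

#' Deduplicate curated compounds, resolving label conflicts by majority
#'
#' Groups records by identity key; a group's label is the categorical
#' majority, with ties resolved to `"inconclusive"`.
#'
#' @param curated data.frame with `identity_key` (and optionally `id`)
#' @param labels categorical label vector aligned with `curated` rows
#' @return data.frame with one row per identity key: `identity_key`,
#'   `label`, `n_records`, `ids` (collapsed provenance), `had_conflict`
#' @export
deduplicate <- function(curated, labels) {
  stopifnot(nrow(curated) == length(labels))
  ids <- if ("id" %in% names(curated)) curated$id else
    as.character(seq_len(nrow(curated)))
  groups <- split(seq_len(nrow(curated)), curated$identity_key)
  rows <- lapply(names(groups), function(key) {
    idx <- groups[[key]]
    tab <- sort(table(as.character(labels[idx])), decreasing = TRUE)
    label <- if (length(tab) > 1L && tab[1] == tab[2]) "inconclusive"
             else names(tab)[1]
    data.frame(identity_key = key, label = label,
               n_records = length(idx),
               ids = paste(ids[idx], collapse = ";"),
               had_conflict = length(unique(labels[idx])) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
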