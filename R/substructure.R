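# ---------------------------------------------------------------------------
# Substructure search (subgraph isomorphism) and circular fragments.
#
# Patterns are plain SMILES interpreted as substructure queries: atoms match
# on element + aromaticity + formal charge, bonds on order class (aromatic
# matches aromatic, fixed orders match exactly).  This is the semantics a
# SMARTS query written with the same characters would have, restricted to
# the dialect the synthetic library uses.
# ---------------------------------------------------------------------------

.bond_label <- function(order, aromatic) ifelse(aromatic, "a", as.character(order))

# per-atom match key and per-bond lookup for a mol
.match_env <- function(mol) {
  akey <- paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
                mol$atoms$charge, sep = "|")
  ab <- .adj_with_bonds(mol)
  list(akey = akey, adj = ab$adj, blab = ab$border)
}

#' Test whether a query substructure occurs in a molecule
#'
#' Backtracking subgraph-isomorphism (VF2-style candidate ordering) over the
#' molecular graph. Hydrogens are implicit and never constrain the match.
#'
#' @param pattern a SMILES string or `mol` used as the query
#' @param mol a SMILES string or `mol` to search in
#' @return `TRUE` if an embedding exists
#' @export
has_substructure <- function(pattern, mol) {
  if (is.character(pattern)) pattern <- parse_smiles(pattern)
  if (is.character(mol)) mol <- parse_smiles(mol)
  np <- n_atoms(pattern); nt <- n_atoms(mol)
  if (np > nt) return(FALSE)
  pe <- .match_env(pattern); te <- .match_env(mol)

  # order pattern atoms so each one (after the first) touches a mapped atom
  ordp <- integer(0); left <- seq_len(np)
  while (length(left)) {
    nxt <- NA_integer_
    if (length(ordp)) {
      for (cand in left) if (any(pe$adj[[cand]] %in% ordp)) { nxt <- cand; break }
    }
    if (is.na(nxt)) nxt <- left[1]
    ordp <- c(ordp, nxt); left <- setdiff(left, nxt)
  }

  used <- logical(nt)
  mapv <- integer(np)   # pattern idx -> target idx (0 = unmapped)

  try_atom <- function(d) {
    if (d > np) return(TRUE)
    p <- ordp[d]
    prevs <- pe$adj[[p]][pe$adj[[p]] %in% ordp[seq_len(d - 1L)]]
    cands <- if (length(prevs)) {
      anchor <- prevs[1]
      te$adj[[mapv[anchor]]]
    } else seq_len(nt)
    for (t in cands) {
      if (used[t]) next
      if (te$akey[t] != pe$akey[p]) next
      ok <- TRUE
      for (q in pe$adj[[p]]) {
        if (!mapv[q]) next
        pos <- which(te$adj[[t]] == mapv[q])
        if (!length(pos)) { ok <- FALSE; break }
        plab <- pe$blab[[p]][which(pe$adj[[p]] == q)[1]]
        if (!any(te$blab[[t]][pos] == plab)) { ok <- FALSE; break }
      }
      if (!ok) next
      mapv[p] <<- t; used[t] <<- TRUE
      if (try_atom(d + 1L)) return(TRUE)
      mapv[p] <<- 0L; used[t] <<- FALSE
    }
    FALSE
  }
  try_atom(1L)
}

#' Match a fragment pattern against a compound set
#'
#' @param pattern substructure query (SMILES string)
#' @param compounds character vector of SMILES, or list of `mol` objects;
#'   names (or a parallel `ids` argument) identify compounds
#' @param ids optional compound identifiers; defaults to names or index
#' @return character vector of matched compound ids, in input order
#' @export
match_fragment <- function(pattern, compounds, ids = NULL) {
  pm <- if (is.character(pattern)) parse_smiles_safe(pattern) else pattern
  if (is.null(pm)) stop("invalid fragment pattern: ", pattern)
  if (is.null(ids)) {
    ids <- names(compounds)
    if (is.null(ids)) ids <- as.character(seq_along(compounds))
  }
  stopifnot(length(ids) == length(compounds))
  hit <- vapply(seq_along(compounds), function(i) {
    m <- compounds[[i]]
    if (is.character(m)) m <- parse_smiles_safe(m)
    if (is.null(m)) return(FALSE)
    has_substructure(pm, m)
  }, TRUE)
  ids[hit]
}

#' Circular fragments (atom environments) of a molecule
#'
#' For every atom, extracts the induced subgraph of atoms within graph
#' distance `0..radius` and canonicalizes it. The resulting strings act as
#' Morgan-style environment keys: two compounds share a fragment iff they
#' share a key.
#'
#' @param mol a `mol` or SMILES string
#' @param radius maximum environment radius (default 2)
#' @return character vector of unique canonical environment strings
#' @export
circular_fragments <- function(mol, radius = 2L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  na <- n_atoms(mol)
  adj <- .adjacency(mol)
  out <- character(0)
  for (a in seq_len(na)) {
    shell <- a
    for (r in 0:radius) {
      if (r > 0L) {
        nxt <- unique(c(shell, unlist(adj[shell])))
        if (length(nxt) == length(shell)) break
        shell <- sort(nxt)
      }
      sub <- .subgraph(mol, shell)
      out <- c(out, paste0("r", r, ":", .canonical_smiles_cached(sub)))
    }
  }
  unique(out)
}

# environment subgraphs repeat across a scaffold-templated library; cache
# their canonical form keyed by an input-order serialization (orderings that
# differ simply miss the cache -- never wrong, just slower)
.canon_cache <- new.env(parent = emptyenv())

.canonical_smiles_cached <- function(mol) {
  key <- paste(
    paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
          mol$atoms$charge, mol$atoms$hcount, collapse = ","),
    paste(mol$bonds$a1, mol$bonds$a2, mol$bonds$order,
          as.integer(mol$bonds$aromatic), collapse = ","),
    sep = ";")
  hit <- .canon_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- canonical_smiles(mol)
  assign(key, res, envir = .canon_cache)
  res
}

# deterministic polynomial string hash into 1..nbins
.hash_string <- function(s, nbins) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 1048573
  as.integer(h %% nbins) + 1L
}

# package-local memo for per-structure fragment sets (canonicalization of
# atom environments dominates descriptor cost; libraries repeat structures)
.frag_cache <- new.env(parent = emptyenv())

#' @rdname circular_fragments
#' @param smiles a SMILES string (memoized entry point)
#' @export
circular_fragments_memo <- function(smiles, radius = 2L) {
  key <- paste0(radius, "|", smiles)
  hit <- .frag_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- parse_smiles_safe(smiles)
  res <- if (is.null(m)) character(0) else circular_fragments(m, radius)
  assign(key, res, envir = .frag_cache)
  res
}

#' Hashed binary circular fingerprint
#'
#' @param mol a `mol` or SMILES string
#' @param nbits fingerprint length (default 256)
#' @param radius environment radius (default 2)
#' @return logical vector of length `nbits`
#' @export
circular_fingerprint <- function(mol, nbits = 256L, radius = 2L) {
  fr <- if (is.character(mol)) circular_fragments_memo(mol, radius)
        else circular_fragments(mol, radius)
  fp <- logical(nbits)
  fp[vapply(fr, .hash_string, 1L, nbins = nbits)] <- TRUE
  fp
}

#' Tanimoto similarity between fingerprint matrices
#'
#' @param A,B logical matrices, one fingerprint per row; `B` defaults to `A`
#' @return numeric matrix of pairwise Tanimoto coefficients; similarity of
#'   two all-zero fingerprints is defined as 0
#' @export
tanimoto <- function(A, B = A) {
  A <- A * 1; B <- B * 1
  common <- A %*% t(B)
  ca <- rowSums(A); cb <- rowSums(B)
  denom <- outer(ca, cb, "+") - common
  out <- ifelse(denom > 0, common / denom, 0)
  out
}
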