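# ---------------------------------------------------------------------------
# Two disjoint open 2-D descriptor families. They stand in for the
# commercial generators the original workflow used; absolute descriptor
# counts are deliberately not reproduced.
#   setA ("const"): constitutional / topological scalars
#   setB ("circ") : hashed circular-fragment counts (radius <= 2)
# ---------------------------------------------------------------------------

# pairwise topological distance matrix (BFS per atom; molecules are small)
.topo_dist <- function(mol) {
  na <- n_atoms(mol); adj <- .adjacency(mol)
  D <- matrix(Inf, na, na); diag(D) <- 0
  for (s in seq_len(na)) {
    q <- s; d <- 0
    seen <- logical(na); seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!seen[nxt]]
      d <- d + 1
      if (!length(nxt)) break
      D[s, nxt] <- d; seen[nxt] <- TRUE
      frontier <- nxt
    }
  }
  D
}

#' Constitutional descriptor set ("const", descriptor family A)
#'
#' @param mol a `mol` or SMILES string
#' @return named numeric vector of 18 descriptors
#' @export
descriptors_const <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  el <- mol$atoms$element
  na <- n_atoms(mol); nb <- n_bonds(mol)
  deg <- integer(na)
  if (nb) for (k in seq_len(nb)) {
    deg[mol$bonds$a1[k]] <- deg[mol$bonds$a1[k]] + 1L
    deg[mol$bonds$a2[k]] <- deg[mol$bonds$a2[k]] + 1L
  }
  D <- .topo_dist(mol)
  finiteD <- D[is.finite(D) & upper.tri(D)]
  ncomp <- length(mol_components(mol))
  c(n_heavy = na,
    mw = mol_weight(mol),
    n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
    n_S = sum(el == "S"),
    n_halogen = sum(el %in% c("F", "Cl", "Br", "I")),
    n_hetero = sum(!el %in% c("C", "H")),
    n_aromatic = sum(mol$atoms$aromatic),
    n_rings = nb - na + ncomp,
    n_double = sum(mol$bonds$order == 2L & !mol$bonds$aromatic),
    n_triple = sum(mol$bonds$order == 3L),
    n_H = sum(hydrogen_counts(mol)),
    mean_degree = if (na) mean(deg) else 0,
    max_degree = if (na) max(deg) else 0,
    n_terminal = sum(deg == 1L),
    wiener = if (length(finiteD)) sum(finiteD) else 0,
    diameter = if (length(finiteD)) max(finiteD) else 0)
}

#' Hashed circular-fragment count descriptors ("circ", descriptor family B)
#'
#' @param mol a `mol` or SMILES string
#' @param nbins number of hash bins (default 64)
#' @return named numeric vector of fragment counts per bin
#' @export
descriptors_circ <- function(mol, nbins = 64L) {
  fr <- if (is.character(mol)) circular_fragments_memo(mol, 2L)
        else circular_fragments(mol, radius = 2L)
  v <- numeric(nbins)
  if (length(fr)) {
    idx <- vapply(fr, .hash_string, 1L, nbins = nbins)
    tb <- table(idx)
    v[as.integer(names(tb))] <- as.numeric(tb)
  }
  names(v) <- sprintf("circ_%03d", seq_len(nbins))
  v
}

#' Descriptor matrix for a compound set
#'
#' @param smiles character vector of SMILES
#' @param set `"const"` or `"circ"`
#' @param ids row identifiers (defaults to names or index)
#' @return numeric matrix, one row per compound
#' @export
descriptor_matrix <- function(smiles, set = c("const", "circ"), ids = NULL) {
  set <- match.arg(set)
  if (is.null(ids)) {
    ids <- names(smiles)
    if (is.null(ids)) ids <- as.character(seq_along(smiles))
  }
  f <- if (set == "const") descriptors_const else descriptors_circ
  rows <- lapply(smiles, function(s) f(s))
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

#' Fit a [0,1] range scaler on training descriptors
#'
#' Constant descriptors are dropped and recorded; applying the scaler to new
#' data clips to [0,1] so distance computations stay bounded.
#'
#' @param X numeric training matrix
#' @return object of class `range_scaler` with `min`, `max`, `keep`, `dropped`
#' @export
fit_range_scaler <- function(X) {
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  keep <- maxs > mins
  structure(list(min = mins[keep], max = maxs[keep],
                 keep = colnames(X)[keep],
                 dropped = colnames(X)[!keep]),
            class = "range_scaler")
}

#' Apply a fitted range scaler
#' @param scaler a `range_scaler`
#' @param X numeric matrix with at least the scaler's columns
#' @param clip clip transformed values into [0,1] (default TRUE); training
#'   data reproduce themselves bit-identically either way
#' @return scaled matrix restricted to the scaler's kept columns
#' @export
apply_range_scaler <- function(scaler, X, clip = TRUE) {
  stopifnot(inherits(scaler, "range_scaler"))
  miss <- setdiff(scaler$keep, colnames(X))
  if (length(miss)) stop("descriptor columns missing: ", paste(miss, collapse = ", "))
  Z <- X[, scaler$keep, drop = FALSE]
  Z <- sweep(Z, 2, scaler$min, "-")
  Z <- sweep(Z, 2, scaler$max - scaler$min, "/")
  if (clip) Z <- pmin(pmax(Z, 0), 1)
  Z
}
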