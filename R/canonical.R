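# ---------------------------------------------------------------------------
# Canonical line notation.
#
# Morgan-style iterative invariant refinement assigns each atom a canonical
# rank; remaining ties are broken by promoting, in turn, every member of the
# lowest tied class and keeping the lexicographically smallest emitted
# string (tied classes after full refinement are almost always graph
# automorphisms, so the candidates usually coincide).  The writer emits a
# SMILES string that re-parses to the same graph; stereochemistry never
# survives parsing, so stereoisomers share one canonical string by
# construction.
# ---------------------------------------------------------------------------

# initial invariant per atom: element, aromatic, charge, degree, H count
.atom_invariant <- function(mol) {
  h <- hydrogen_counts(mol)
  deg <- integer(n_atoms(mol))
  if (n_bonds(mol)) {
    t1 <- table(factor(mol$bonds$a1, levels = seq_len(n_atoms(mol))))
    t2 <- table(factor(mol$bonds$a2, levels = seq_len(n_atoms(mol))))
    deg <- as.integer(t1 + t2)
  }
  paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
        mol$atoms$charge, deg, h, sep = "|")
}

# refine ranks until stable; returns integer ranks (1-based, dense)
.refine_ranks <- function(mol, ranks, adj, border) {
  na <- n_atoms(mol)
  repeat {
    sig <- vapply(seq_len(na), function(i) {
      nb <- adj[[i]]
      if (!length(nb)) return(sprintf("%04d|", ranks[i]))
      key <- sort(paste0(border[[i]], ":", sprintf("%04d", ranks[nb])))
      paste0(sprintf("%04d", ranks[i]), "|", paste(key, collapse = ","))
    }, "")
    new <- match(sig, sort(unique(sig)))
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

# adjacency + per-neighbour bond label, aligned lists
.adj_with_bonds <- function(mol) {
  na <- n_atoms(mol)
  adj <- vector("list", na); border <- vector("list", na)
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      lab <- if (mol$bonds$aromatic[k]) "a" else as.character(mol$bonds$order[k])
      adj[[i]] <- c(adj[[i]], j); border[[i]] <- c(border[[i]], lab)
      adj[[j]] <- c(adj[[j]], i); border[[j]] <- c(border[[j]], lab)
    }
  }
  list(adj = adj, border = border)
}

#' Canonical ranks for the atoms of a molecular graph
#' @param mol a `mol` object (single component preferred)
#' @return integer vector of distinct ranks, length `n_atoms(mol)`
#' @keywords internal
canonical_ranks <- function(mol) {
  ab <- .adj_with_bonds(mol)
  ranks <- match(.atom_invariant(mol), sort(unique(.atom_invariant(mol))))
  ranks <- .refine_ranks(mol, ranks, ab$adj, ab$border)
  .break_ties(mol, ranks, ab)$ranks
}

# returns list(ranks=..., smiles=...) with all ties broken; recursion depth
# equals the number of symmetry classes that need promotion (small).
.break_ties <- function(mol, ranks, ab, depth = 0L) {
  na <- n_atoms(mol)
  if (length(unique(ranks)) == na || depth > 8L) {
    ord <- order(ranks)
    final <- integer(na); final[ord] <- seq_len(na)
    return(list(ranks = final, smiles = .emit_smiles(mol, final, ab)))
  }
  tied <- ranks[duplicated(ranks)]
  cls <- min(tied)
  members <- which(ranks == cls)
  best <- NULL
  for (m in members) {
    r2 <- ifelse(seq_len(na) == m, ranks * 2L - 1L, ranks * 2L)
    r2 <- match(r2, sort(unique(r2)))
    r2 <- .refine_ranks(mol, r2, ab$adj, ab$border)
    cand <- .break_ties(mol, r2, ab, depth + 1L)
    if (is.null(best) || cand$smiles < best$smiles) best <- cand
  }
  best
}

# write one atom token
.atom_token <- function(mol, i, h) {
  el <- mol$atoms$element[i]
  sym <- if (mol$atoms$aromatic[i]) tolower(el) else el
  plain_ok <- el %in% .ORGANIC_SUBSET && mol$atoms$charge[i] == 0L &&
    is.na(mol$atoms$hcount[i])
  if (plain_ok) return(sym)
  chg <- mol$atoms$charge[i]
  chs <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
         else sprintf("%+d", chg)
  hs <- if (h[i] == 0L) "" else if (h[i] == 1L) "H" else paste0("H", h[i])
  paste0("[", sym, hs, chs, "]")
}

.bond_token <- function(order, aromatic, from_arom, to_arom) {
  if (aromatic) return("")                       # implicit between aromatics
  if (order == 2L) return("=")
  if (order == 3L) return("#")
  if (from_arom && to_arom) return("-")          # e.g. biphenyl linker
  ""
}

# DFS emit using canonical ranks for all orderings
.emit_smiles <- function(mol, ranks, ab = NULL) {
  if (is.null(ab)) ab <- .adj_with_bonds(mol)
  na <- n_atoms(mol)
  h <- integer(na)
  expl <- !is.na(mol$atoms$hcount)
  if (any(expl)) h[expl] <- mol$atoms$hcount[expl]
  bonds <- mol$bonds
  bkey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  bmap <- new.env(parent = emptyenv())
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds)))
      assign(bkey(bonds$a1[k], bonds$a2[k]),
             list(order = bonds$order[k], aromatic = bonds$aromatic[k]), bmap)
  }

  # pre-pass: classify bonds into tree vs ring along the canonical DFS
  # order, assigning ring digits at the earlier-visited endpoint
  ring_pre <- new.env(parent = emptyenv())
  vis <- logical(na); order_visit <- integer(0)
  tree <- new.env(parent = emptyenv())
  dfs <- function(i, parent) {
    vis[i] <<- TRUE
    order_visit <<- c(order_visit, i)
    nb <- ab$adj[[i]]; nb <- nb[order(ranks[nb])]
    for (j in nb) {
      if (!is.na(parent) && j == parent) next
      key <- bkey(i, j)
      if (!is.null(tree[[key]])) next
      if (vis[j]) tree[[key]] <- "ring"
      else { tree[[key]] <- "tree"; dfs(j, i) }
    }
  }
  roots <- integer(0)
  for (s in order(ranks)) if (!vis[s]) { roots <- c(roots, s); dfs(s, NA_integer_) }
  pos <- integer(na); pos[order_visit] <- seq_along(order_visit)
  if (nrow(bonds)) {
    ring_bonds <- list()
    for (k in seq_len(nrow(bonds))) {
      key <- bkey(bonds$a1[k], bonds$a2[k])
      if (identical(tree[[key]], "ring")) {
        i0 <- bonds$a1[k]; j0 <- bonds$a2[k]
        first <- if (pos[i0] < pos[j0]) i0 else j0
        second <- if (pos[i0] < pos[j0]) j0 else i0
        ring_bonds[[length(ring_bonds) + 1L]] <-
          list(key = key, first = first, second = second, ford = pos[first])
      }
    }
    if (length(ring_bonds)) {
      ord <- order(vapply(ring_bonds, function(x) x$ford, 1L))
      d <- 0L
      for (rb in ring_bonds[ord]) {
        d <- d + 1L
        slot <- as.character(rb$first)
        ring_pre[[slot]] <- c(ring_pre[[slot]],
                              list(list(key = rb$key, digit = d,
                                        i = rb$first, j = rb$second)))
      }
    }
  }

  visited <- logical(na)
  ring_open <- new.env(parent = emptyenv())   # bond key -> digit

  emit <- function(i, parent) {
    visited[i] <<- TRUE
    nb <- ab$adj[[i]]
    ordnb <- nb[order(ranks[nb])]
    token <- .atom_token(mol, i, h)
    ring_here <- character(0)
    # closures first: neighbours already emitted that opened a digit here
    for (j in ordnb) {
      if (!is.na(parent) && j == parent) next
      key <- bkey(i, j)
      if (visited[j] && !is.null(ring_open[[key]])) {
        d <- ring_open[[key]]$digit
        b <- get(key, bmap)
        sym <- .bond_token(b$order, b$aromatic,
                           mol$atoms$aromatic[i], mol$atoms$aromatic[j])
        ring_here <- c(ring_here, paste0(sym, .digit_token(d)))
        rm(list = key, envir = ring_open)
      }
    }
    # openings assigned to this atom by the pre-pass
    opens <- ring_pre[[as.character(i)]]
    if (!is.null(opens)) {
      for (op in opens) {
        b <- get(op$key, bmap)
        sym <- .bond_token(b$order, b$aromatic,
                           mol$atoms$aromatic[op$i], mol$atoms$aromatic[op$j])
        ring_here <- c(ring_here, paste0(sym, .digit_token(op$digit)))
        ring_open[[op$key]] <- list(digit = op$digit)
      }
    }
    pieces <- paste0(token, paste0(ring_here, collapse = ""))
    kk <- ordnb[if (is.na(parent)) TRUE else ordnb != parent]
    kk <- kk[!visited[kk]]
    while (length(kk)) {
      j <- kk[1]
      key <- bkey(i, j)
      b <- get(key, bmap)
      sym <- .bond_token(b$order, b$aromatic,
                         mol$atoms$aromatic[i], mol$atoms$aromatic[j])
      sub <- emit(j, i)
      rest <- kk[-1]; rest <- rest[!visited[rest]]
      pieces <- if (length(rest)) paste0(pieces, "(", sym, sub, ")")
                else paste0(pieces, sym, sub)
      kk <- rest
    }
    pieces
  }

  parts <- character(0)
  for (s in roots) if (!visited[s]) parts <- c(parts, emit(s, NA_integer_))
  paste(parts, collapse = ".")
}

.digit_token <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

#' Canonical SMILES of a molecular graph
#'
#' @param mol a `mol` object or a SMILES string
#' @return a single canonical SMILES string; components are canonicalized
#'   independently and joined with `.` in sorted order
#' @export
canonical_smiles <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  comps <- mol_components(mol)
  strs <- vapply(comps, function(m) {
    ab <- .adj_with_bonds(m)
    ranks <- match(.atom_invariant(m), sort(unique(.atom_invariant(m))))
    ranks <- .refine_ranks(m, ranks, ab$adj, ab$border)
    .break_ties(m, ranks, ab)$smiles
  }, "")
  paste(sort(strs, method = "radix"), collapse = ".")
}
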