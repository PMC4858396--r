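#' @useDynLib toxprofiler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal molecular graph toolkit.
#
# No open cheminformatics toolkit ships with this R installation, so the
# package carries its own small SMILES layer.  It supports the dialect the
# rest of the package needs: the organic subset (B C N O P S F Cl Br I plus
# aromatic b c n o p s), bracket atoms with charge / explicit H / any
# element symbol, branches, ring closures (including %nn), dot-separated
# components, and bond symbols - = # :.  Stereo marks (/ \ @) and isotope
# numbers are parsed and dropped: the whole pipeline is constitution-only.
# ---------------------------------------------------------------------------

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK    <- c("b", "c", "n", "o", "p", "s", "se")

.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, Se = 2, Si = 4, H = 1)

# monoisotopic-free average atomic masses, enough elements for curation
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Cr = 51.996,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, Mo = 95.95,
  Ag = 107.87, Cd = 112.41, Sn = 118.71, Sb = 121.76, I = 126.904,
  Ba = 137.33, Pt = 195.08, Au = 196.97, Hg = 200.59, Pb = 207.2,
  Li = 6.94, Ti = 47.867, V = 50.942, Gd = 157.25, Bi = 208.98)

# elements treated as non-metals for the metalorganic rule
.NONMETALS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
                "Se", "Br", "I")

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string. Stereochemistry and isotope labels
#'   are discarded; the returned graph is constitution-only.
#' @return an object of class `mol`: a list with `atoms` (data.frame with
#'   columns `element`, `aromatic`, `charge`, `hcount` where `hcount` is
#'   `NA` for implicit-H atoms) and `bonds` (data.frame with `a1`, `a2`,
#'   `order` in \{1, 2, 3\} and logical `aromatic`), or `NULL` with a
#'   warning suppressed -- callers that must not fail use
#'   [parse_smiles_safe()].
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  el <- character(0); arom <- logical(0); chg <- integer(0); hct <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- integer(0); barom <- logical(0)

  prev <- NA_integer_          # atom the next bond attaches to
  stack <- integer(0)          # branch stack
  pend_bond <- NA_character_   # explicit bond symbol waiting for next atom
  ring <- list()               # open ring closures: digit -> c(atom, bond)

  add_atom <- function(element, aromatic, charge = 0L, hcount = NA_integer_) {
    el <<- c(el, element); arom <<- c(arom, aromatic)
    chg <<- c(chg, as.integer(charge)); hct <<- c(hct, as.integer(hcount))
    length(el)
  }
  add_bond <- function(i, j, sym) {
    if (is.na(i)) return(invisible())
    if (is.na(sym)) {
      if (arom[i] && arom[j]) { o <- 1L; ar <- TRUE } else { o <- 1L; ar <- FALSE }
    } else if (sym == "-") { o <- 1L; ar <- FALSE
    } else if (sym == "=") { o <- 2L; ar <- FALSE
    } else if (sym == "#") { o <- 3L; ar <- FALSE
    } else if (sym == ":") { o <- 1L; ar <- TRUE
    } else stop("bad bond symbol")
    b1 <<- c(b1, i); b2 <<- c(b2, j); bord <<- c(bord, o); barom <<- c(barom, ar)
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced parenthesis in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":")) { pend_bond <- ch; i <- i + 1L; next }
    if (ch %in% c("/", "\\")) { i <- i + 1L; next }  # stereo bond -> single
    if (ch == ".") { prev <- NA_integer_; pend_bond <- NA_character_; i <- i + 1L; next }

    if (ch == "%" || grepl("[0-9]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure: ", smiles)
        digit <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { digit <- ch; i <- i + 1L }
      if (is.na(prev)) stop("ring closure with no open atom: ", smiles)
      key <- digit
      if (!is.null(ring[[key]])) {
        op <- ring[[key]]
        sym <- pend_bond
        if (is.na(sym) && !is.na(op$sym)) sym <- op$sym
        add_bond(op$atom, prev, sym)
        ring[[key]] <- NULL
      } else {
        ring[[key]] <- list(atom = prev, sym = pend_bond)
      }
      pend_bond <- NA_character_
      next
    }

    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom: ", smiles)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket(body, smiles)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$hcount)
      add_bond(prev, idx, pend_bond); pend_bond <- NA_character_
      prev <- idx; i <- j + 1L; next
    }

    # organic subset, possibly two characters (Cl, Br)
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE); i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      idx <- add_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE); i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
    add_bond(prev, idx, pend_bond); pend_bond <- NA_character_
    prev <- idx
  }
  if (length(ring)) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(stack)) stop("unbalanced parenthesis in SMILES: ", smiles)
  if (!length(el)) stop("empty SMILES")

  mol <- structure(list(
    atoms = data.frame(element = el, aromatic = arom, charge = chg,
                       hcount = hct, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord, aromatic = barom)),
    class = "mol")
  .normalize_hcounts(mol)
}

# bracket atoms like [C@@H] whose explicit H count equals the implicit
# default collapse to plain atoms, so stereo-stripped forms share one key
.normalize_hcounts <- function(mol) {
  expl <- which(!is.na(mol$atoms$hcount) & mol$atoms$charge == 0L &
                  mol$atoms$element %in% .ORGANIC_SUBSET)
  if (!length(expl)) return(mol)
  probe <- mol
  probe$atoms$hcount[expl] <- NA_integer_
  imp <- hydrogen_counts(probe)
  same <- expl[mol$atoms$hcount[expl] == imp[expl]]
  mol$atoms$hcount[same] <- NA_integer_
  mol
}

# bracket atom body, e.g. "O-", "nH", "NH3+", "13CH2", "Na+", "Fe+2"
.parse_bracket <- function(body, smiles) {
  s <- sub("^[0-9]+", "", body)                 # isotope dropped
  m <- regmatches(s, regexpr("^([A-Z][a-z]?|[a-z]{1,2})", s))
  if (!length(m)) stop("bad bracket atom [", body, "] in ", smiles)
  sym <- m
  s <- substring(s, nchar(sym) + 1L)
  aromatic <- sym %in% .AROMATIC_OK
  element <- if (aromatic) {
    paste0(toupper(substring(sym, 1, 1)), substring(sym, 2))
  } else sym
  s <- gsub("@", "", s, fixed = TRUE)           # stereo dropped
  hcount <- 0L
  hm <- regmatches(s, regexpr("H[0-9]*", s))
  if (length(hm)) {
    hcount <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2))
    s <- sub("H[0-9]*", "", s)
  }
  charge <- 0L
  cm <- regmatches(s, regexpr("[+-][0-9]*|[+]{2,}|[-]{2,}", s))
  if (length(cm)) {
    if (grepl("^[+]+$", cm)) charge <- nchar(cm)
    else if (grepl("^[-]+$", cm)) charge <- -nchar(cm)
    else charge <- as.integer(paste0(substring(cm, 1, 1),
                                     ifelse(nchar(cm) > 1, substring(cm, 2), "1")))
  }
  list(element = element, aromatic = aromatic,
       charge = as.integer(charge), hcount = hcount)
}

#' Parse a SMILES string, returning NULL instead of raising
#' @param smiles a single SMILES string
#' @return a `mol` or `NULL` when unparseable
#' @export
parse_smiles_safe <- function(smiles) {
  tryCatch(parse_smiles(smiles), error = function(e) NULL)
}

#' Number of atoms / bonds of a molecular graph
#' @param mol a `mol` object
#' @return integer count
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

# per-atom sum of bond orders, aromatic bonds count 1 plus one shared pi
.bond_order_sum <- function(mol) {
  s <- numeric(n_atoms(mol))
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      o <- mol$bonds$order[k]
      s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + o
      s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + o
    }
  }
  s + ifelse(mol$atoms$aromatic, 1, 0)
}

#' Implicit plus explicit hydrogen count per atom
#'
#' Bracket atoms carry their explicit H count; organic-subset atoms get the
#' standard default-valence fill (N+ gains one valence unit, O-/S-/N- lose
#' one per negative charge when written without brackets -- which cannot
#' happen, so the charge adjustment only applies to bracket atoms, where H
#' is explicit anyway and returned as-is).
#' @param mol a `mol` object
#' @return integer vector, one entry per atom
#' @export
hydrogen_counts <- function(mol) {
  h <- mol$atoms$hcount
  implicit <- is.na(h)
  if (any(implicit)) {
    val <- .DEFAULT_VALENCE[mol$atoms$element[implicit]]
    val[is.na(val)] <- 0
    bos <- .bond_order_sum(mol)[implicit]
    h[implicit] <- pmax(0, round(val - bos))
  }
  as.integer(h)
}

#' Molecular weight (g/mol) including implicit hydrogens
#' @param mol a `mol` object
#' @return numeric scalar; unknown elements contribute 0 with a warning
#' @export
mol_weight <- function(mol) {
  m <- .ATOMIC_MASS[mol$atoms$element]
  if (anyNA(m)) {
    warning("unknown atomic mass for: ",
            paste(unique(mol$atoms$element[is.na(m)]), collapse = ", "))
    m[is.na(m)] <- 0
  }
  sum(m) + sum(hydrogen_counts(mol)) * .ATOMIC_MASS[["H"]]
}

# adjacency list (atom index -> integer vector of neighbours)
.adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  if (n_bonds(mol)) {
    for (k in seq_len(n_bonds(mol))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Split a molecular graph into connected components
#' @param mol a `mol` object
#' @return list of `mol` objects, largest (most heavy atoms) first; ties
#'   broken by molecular weight then original order
#' @export
mol_components <- function(mol) {
  na <- n_atoms(mol)
  comp <- integer(na); adj <- .adjacency(mol); cid <- 0L
  for (s in seq_len(na)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (comp[v] > 0L) next
      comp[v] <- cid
      q <- c(q, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  out <- lapply(seq_len(cid), function(k) .subgraph(mol, which(comp == k)))
  sizes <- vapply(out, n_atoms, 1L)
  mws <- vapply(out, mol_weight, 1.0)
  out[order(-sizes, -mws)]
}

# induced subgraph on atom index vector `keep` (re-indexed 1..length(keep))
.subgraph <- function(mol, keep) {
  map <- integer(n_atoms(mol)); map[keep] <- seq_along(keep)
  bsel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  b <- mol$bonds[bsel, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  rownames(b) <- NULL
  structure(list(atoms = mol$atoms[keep, , drop = FALSE],
                 bonds = b), class = "mol") -> out
  rownames(out$atoms) <- NULL
  out
}

#' Does the molecule contain a carbon-metal bond?
#'
#' A metalorganic is defined as any molecule with a covalent bond between a
#' carbon atom and an element outside the non-metal set
#' \{H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I\}. Disconnected metal
#' counter-ions (e.g. the sodium in sodium acetate) are not metalorganics.
#' @param mol a `mol` object
#' @return logical scalar
#' @export
is_metalorganic <- function(mol) {
  if (!n_bonds(mol)) return(FALSE)
  e1 <- mol$atoms$element[mol$bonds$a1]
  e2 <- mol$atoms$element[mol$bonds$a2]
  any((e1 == "C" & !(e2 %in% .NONMETALS)) |
      (e2 == "C" & !(e1 %in% .NONMETALS)))
}

#' @export
print.mol <- function(x, ...) {
  cat(sprintf("<mol: %d atoms, %d bonds, formula-ish %s>\n",
              n_atoms(x), n_bonds(x),
              paste0(names(table(x$atoms$element)),
                     table(x$atoms$element), collapse = "")))
  invisible(x)
}
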