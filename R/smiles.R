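# Minimal SMILES layer: parser, implicit-hydrogen resolution, elemental
# composition, and canonicalization for the non-aromatic organic subset that
# gas-phase kinetics corpora use. Radicals and ions are first-class citizens;
# "valid" means parseable + consistent valence, not "stable molecule".

# standard valences used to resolve implicit hydrogens on bare (organic
# subset) atoms; multi-valent elements list allowed valences in ascending order
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

# atomic numbers for the elements this package expects to meet; used by the
# dipole layer's center-of-nuclear-charge origin
.ATOMIC_NUMBER <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
  Cl = 17L, Br = 35L, I = 53L
)

stop_rxnvae <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "rxnvae_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_smiles <- function(msg) stop_rxnvae(msg, "rxnvae_smiles_error")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the non-aromatic organic subset: bare atoms `B C N O P S F Cl Br I`,
#' bracket atoms with isotope, hydrogen count and charge (`[CH3]`, `[O-]`,
#' `[NH4+]`, `[13C]`), single/double/triple bonds, branches, ring closures
#' (including `%nn`), and dot-separated fragments. Aromatic (lowercase) atoms
#' are rejected: gas-phase kinetics species do not need them and silent
#' mis-handling would corrupt balance verdicts.
#'
#' @param s a single SMILES string.
#' @return an object of class `rxnvae_mol`: a list with `atoms` (data.frame of
#'   `element`, `charge`, `hcount`, `bracket`, `isotope`) and `bonds`
#'   (data.frame of `a1`, `a2`, `order`).
#' @export
smiles_parse <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop_smiles("SMILES must be a single character string")
  }
  if (nchar(s) == 0L) stop_smiles("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]

  atoms <- list()       # each: list(element, charge, hcount, bracket, isotope)
  bonds <- list()       # each: c(a1, a2, order)
  prev <- NA_integer_   # previous atom index, NA after '.' or at start
  pend_bond <- 1L       # bond order pending for the next atom/ring closure
  pend_explicit <- FALSE  # an explicit bond symbol awaits its partner
  stack <- integer(0)   # branch stack of atom indices
  rings <- list()       # open ring closures: key -> list(atom, order)

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, pend_bond)
    }
    prev <<- idx
    pend_bond <<- 1L
    pend_explicit <<- FALSE
    idx
  }

  close_ring <- function(key) {
    if (is.na(prev)) stop_smiles(sprintf("ring closure '%s' before any atom", key))
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      ord <- max(op$order, pend_bond)
      if (op$order != 1L && pend_bond != 1L && op$order != pend_bond) {
        stop_smiles(sprintf("conflicting bond orders on ring closure '%s'", key))
      }
      if (op$atom == prev) stop_smiles("ring closure bonds an atom to itself")
      bonds[[length(bonds) + 1L]] <<- c(op$atom, prev, ord)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, order = pend_bond)
    }
    pend_bond <<- 1L
    pend_explicit <<- FALSE
  }

  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop_smiles(sprintf("unclosed bracket atom in '%s'", s))
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      add_atom(.parse_bracket_atom(body, s))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, charge = 0L, hcount = NA_integer_,
                      bracket = FALSE, isotope = NA_integer_))
        i <- i + 2L
      } else {
        stop_smiles(sprintf("unknown atom symbol at '%s' in '%s'", two, s))
      }
    } else if (ch %in% .ORGANIC_SUBSET) {
      add_atom(list(element = ch, charge = 0L, hcount = NA_integer_,
                    bracket = FALSE, isotope = NA_integer_))
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      stop_smiles(sprintf("aromatic SMILES atom '%s' not supported", ch))
    } else if (ch == "=") {
      pend_bond <- 2L; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch == "#") {
      pend_bond <- 3L; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pend_bond <- 1L; pend_explicit <- TRUE; i <- i + 1L
    } else if (ch == ":") {
      stop_smiles("aromatic bond ':' not supported")
    } else if (ch == "(") {
      if (is.na(prev)) stop_smiles("branch open before any atom")
      if (pend_explicit) stop_smiles(sprintf("dangling bond before '(' in '%s'", s))
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop_smiles("unmatched ')'")
      if (pend_explicit) stop_smiles(sprintf("dangling bond before ')' in '%s'", s))
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L]))) {
        stop_smiles("'%' ring closure needs two digits")
      }
      close_ring(paste0("%", chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ".") {
      if (pend_explicit) stop_smiles(sprintf("dangling bond before '.' in '%s'", s))
      prev <- NA_integer_; pend_bond <- 1L; i <- i + 1L
    } else {
      stop_smiles(sprintf("unexpected character '%s' in SMILES '%s'", ch, s))
    }
  }
  if (pend_explicit) stop_smiles(sprintf("dangling bond at end of '%s'", s))
  if (length(stack) > 0L) stop_smiles(sprintf("unclosed branch in '%s'", s))
  if (length(rings) > 0L) stop_smiles(sprintf("unclosed ring bond in '%s'", s))
  if (length(atoms) == 0L) stop_smiles(sprintf("no atoms in SMILES '%s'", s))

  at <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    hcount = vapply(atoms, `[[`, 0L, "hcount"),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    isotope = vapply(atoms, `[[`, 0L, "isotope"),
    stringsAsFactors = FALSE
  )
  bd <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    data.frame(a1 = m[, 1], a2 = m[, 2], order = m[, 3])
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }

  mol <- structure(list(atoms = at, bonds = bd, source = s), class = "rxnvae_mol")
  .resolve_implicit_h(mol)
}

.parse_bracket_atom <- function(body, s) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Z][a-z]?)(@{1,2})?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
    body
  ))[[1]]
  if (length(m) == 0L) {
    stop_smiles(sprintf("cannot parse bracket atom '[%s]' in '%s'", body, s))
  }
  element <- m[3]
  if (!(element %in% c(names(.ATOMIC_NUMBER), .ORGANIC_SUBSET))) {
    stop_smiles(sprintf("unsupported element '%s' in '%s'", element, s))
  }
  hpart <- m[5]
  hcount <- if (hpart == "") 0L else if (hpart == "H") 1L else as.integer(sub("H", "", hpart))
  cpart <- m[6]
  charge <- 0L
  if (cpart != "") {
    if (grepl("^\\++$", cpart)) charge <- nchar(cpart)
    else if (grepl("^-+$", cpart)) charge <- -nchar(cpart)
    else if (grepl("^\\+[0-9]+$", cpart)) charge <- as.integer(sub("\\+", "", cpart))
    else charge <- -as.integer(sub("-", "", cpart))
  }
  isotope <- if (m[2] == "") NA_integer_ else as.integer(m[2])
  list(element = element, charge = as.integer(charge), hcount = hcount,
       bracket = TRUE, isotope = isotope)
}

# fill hcount for bare atoms from standard valences; error when explicit bonds
# already exceed every allowed valence (invalid species, e.g. 5-bonded bare C)
.resolve_implicit_h <- function(mol) {
  bsum <- .bond_order_sums(mol)
  at <- mol$atoms
  for (k in seq_len(nrow(at))) {
    if (!at$bracket[k]) {
      v <- .VALENCES[[at$element[k]]]
      fit <- v[v >= bsum[k]]
      if (length(fit) == 0L) {
        stop_smiles(sprintf(
          "valence violation: bare %s with %d explicit bonds in '%s'",
          at$element[k], bsum[k], mol$source
        ))
      }
      at$hcount[k] <- fit[1] - bsum[k]
    }
  }
  mol$atoms <- at
  mol
}

.bond_order_sums <- function(mol) {
  bsum <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      bsum[mol$bonds$a1[r]] <- bsum[mol$bonds$a1[r]] + mol$bonds$order[r]
      bsum[mol$bonds$a2[r]] <- bsum[mol$bonds$a2[r]] + mol$bonds$order[r]
    }
  }
  bsum
}

#' Elemental composition and net charge of a SMILES species
#'
#' Implicit hydrogens are resolved by standard valence rules, so the implicit
#' (`C`) and explicit (`[H][C]([H])([H])[H]`) dialects of the same molecule
#' yield identical compositions.
#'
#' @param s a SMILES string or a parsed `rxnvae_mol`.
#' @return named integer vector of element counts (alphabetical), with the net
#'   formal charge in attribute `charge`.
#' @export
smiles_composition <- function(s) {
  mol <- if (inherits(s, "rxnvae_mol")) s else smiles_parse(s)
  at <- mol$atoms
  counts <- tapply(rep(1L, nrow(at)), at$element, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h_implicit <- sum(at$hcount)
  if (h_implicit > 0L) {
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + h_implicit
  }
  counts <- counts[counts > 0L]
  counts <- counts[order(names(counts))]
  attr(counts, "charge") <- sum(at$charge)
  counts
}

# -- canonicalization ---------------------------------------------------------

# fold terminal explicit [H] atoms (single bond to one heavier neighbor, no
# charge/isotope) into the neighbor's hydrogen count, so explicit-H and
# implicit-H spellings of a molecule canonicalize identically
.fold_hydrogens <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  deg <- integer(nrow(at))
  for (r in seq_len(nrow(bd))) {
    deg[bd$a1[r]] <- deg[bd$a1[r]] + 1L
    deg[bd$a2[r]] <- deg[bd$a2[r]] + 1L
  }
  fold <- rep(FALSE, nrow(at))
  add_h <- integer(nrow(at))
  for (r in seq_len(nrow(bd))) {
    if (bd$order[r] != 1L) next
    for (side in 1:2) {
      h <- if (side == 1) bd$a1[r] else bd$a2[r]
      nb <- if (side == 1) bd$a2[r] else bd$a1[r]
      if (at$element[h] == "H" && at$element[nb] != "H" &&
          at$charge[h] == 0L && at$hcount[h] == 0L &&
          is.na(at$isotope[h]) && deg[h] == 1L && !fold[h]) {
        fold[h] <- TRUE
        add_h[nb] <- add_h[nb] + 1L
      }
    }
  }
  if (!any(fold)) return(mol)
  at$hcount <- at$hcount + add_h
  keep <- which(!fold)
  remap <- match(seq_len(nrow(at)), keep)
  bd <- bd[!(fold[bd$a1] | fold[bd$a2]), , drop = FALSE]
  bd$a1 <- remap[bd$a1]
  bd$a2 <- remap[bd$a2]
  mol$atoms <- at[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol$bonds <- bd
  mol
}

# Weisfeiler-Lehman style iterative refinement of atom ranks with deterministic
# tie-breaking; exact for the small (near-)tree molecules of this domain
.canonical_ranks <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  n <- nrow(at)
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(bd))) {
    nbrs[[bd$a1[r]]] <- rbind(nbrs[[bd$a1[r]]], c(bd$a2[r], bd$order[r]))
    nbrs[[bd$a2[r]]] <- rbind(nbrs[[bd$a2[r]]], c(bd$a1[r], bd$order[r]))
  }
  bsum <- .bond_order_sums(mol)
  inv <- sprintf("%s|%d|%d|%d|%d|%d",
                 at$element, vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), 0L),
                 bsum, at$charge, at$hcount,
                 ifelse(is.na(at$isotope), 0L, at$isotope))
  ranks <- match(inv, sort(unique(inv)))

  refine <- function(ranks) {
    repeat {
      sig <- vapply(seq_len(n), function(k) {
        nb <- nbrs[[k]]
        part <- if (is.null(nb)) "" else
          paste(sort(sprintf("%02d:%06d", nb[, 2], ranks[nb[, 1]])), collapse = ",")
        sprintf("%06d|%s", ranks[k], part)
      }, "")
      new_ranks <- match(sig, sort(unique(sig)))
      # the partition only ever refines; stable once the class count stops growing
      if (length(unique(new_ranks)) == length(unique(ranks))) return(new_ranks)
      ranks <- new_ranks
    }
  }
  ranks <- refine(ranks)
  # break remaining ties (symmetric or WL-equivalent atoms) one at a time
  while (length(unique(ranks)) < n) {
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1])
    cls <- min(tied)
    pick <- which(ranks == cls)[1]
    ranks <- ranks * 2L
    ranks[pick] <- ranks[pick] - 1L
    ranks <- match(ranks, sort(unique(ranks)))
    ranks <- refine(ranks)
  }
  ranks
}

.atom_token <- function(el, charge, hcount, isotope, bsum) {
  plain_ok <- el %in% .ORGANIC_SUBSET && charge == 0L && is.na(isotope)
  if (plain_ok) {
    v <- .VALENCES[[el]]
    fit <- v[v >= bsum]
    default_h <- if (length(fit)) fit[1] - bsum else -1L
    if (default_h == hcount) return(el)
  }
  hpart <- if (hcount == 0L) "" else if (hcount == 1L) "H" else paste0("H", hcount)
  cpart <- if (charge == 0L) {
    ""
  } else if (charge == 1L) {
    "+"
  } else if (charge == -1L) {
    "-"
  } else if (charge > 1L) {
    paste0("+", charge)
  } else {
    paste0("-", -charge)
  }
  ipart <- if (is.na(isotope)) "" else as.character(isotope)
  paste0("[", ipart, el, hpart, cpart, "]")
}

.write_component <- function(mol, comp_atoms, ranks) {
  at <- mol$atoms
  bd <- mol$bonds
  bsum <- .bond_order_sums(mol)
  nbrs <- vector("list", nrow(at))
  for (r in seq_len(nrow(bd))) {
    nbrs[[bd$a1[r]]] <- rbind(nbrs[[bd$a1[r]]], c(bd$a2[r], bd$order[r]))
    nbrs[[bd$a2[r]]] <- rbind(nbrs[[bd$a2[r]]], c(bd$a1[r], bd$order[r]))
  }
  root <- comp_atoms[which.min(ranks[comp_atoms])]

  visited <- rep(FALSE, nrow(at))
  ring_ids <- list()      # per-atom character vector of "<bond><digit>" tokens
  ring_next <- 0L
  # first pass: find back edges via iterative DFS in canonical order
  order_children <- function(k, parent) {
    nb <- nbrs[[k]]
    if (is.null(nb)) return(NULL)
    nb <- nb[order(ranks[nb[, 1]], nb[, 1]), , drop = FALSE]
    nb[nb[, 1] != parent, , drop = FALSE]
  }
  ring_marks <- new.env(parent = emptyenv())
  add_ring <- function(k, tok) {
    key <- as.character(k)
    ring_marks[[key]] <- c(
      if (is.null(ring_marks[[key]])) character(0) else ring_marks[[key]], tok
    )
  }
  used_edge <- new.env(parent = emptyenv())
  edge_key <- function(a, b) paste(min(a, b), max(a, b))

  dfs_rings <- function(k, parent) {
    visited[k] <<- TRUE
    nb <- order_children(k, parent)
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      j <- nb[r, 1]; ord <- nb[r, 2]
      ek <- edge_key(k, j)
      if (!is.null(used_edge[[ek]])) next
      if (visited[j]) {
        used_edge[[ek]] <- TRUE
        ring_next <<- ring_next + 1L
        dig <- if (ring_next < 10L) as.character(ring_next) else sprintf("%%%02d", ring_next)
        bsym <- c("", "", "=", "#")[ord + 1L]
        add_ring(k, paste0(bsym, dig))
        add_ring(j, paste0(bsym, dig))
      } else {
        used_edge[[ek]] <- TRUE
        dfs_rings(j, k)
      }
    }
  }
  dfs_rings(root, 0L)

  # second pass: emit text along the same spanning tree
  visited2 <- rep(FALSE, nrow(at))
  emit <- function(k, parent, inbond) {
    visited2[k] <<- TRUE
    bsym <- c("", "", "=", "#")[inbond + 1L]
    tok <- .atom_token(at$element[k], at$charge[k], at$hcount[k], at$isotope[k], bsum[k])
    rng <- ring_marks[[as.character(k)]]
    out <- paste0(bsym, tok, if (is.null(rng)) "" else paste(rng, collapse = ""))
    nb <- order_children(k, parent)
    subs <- character(0)
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]
        if (!visited2[j]) subs <- c(subs, emit(j, k, nb[r, 2]))
      }
    }
    if (length(subs)) {
      out <- paste0(
        out,
        paste0(vapply(utils::head(subs, -1), function(x) paste0("(", x, ")"), ""),
               collapse = ""),
        subs[length(subs)]
      )
    }
    out
  }
  emit(root, 0L, 1L)
}

#' Canonical SMILES
#'
#' Deterministic canonical form: explicit terminal hydrogens are folded into
#' hydrogen counts, atoms are ranked by iterative neighborhood refinement, and
#' the molecule is rewritten from the lowest-ranked root with neighbors in rank
#' order. Dot-separated fragments are canonicalized independently and joined in
#' sorted order. Canonicalization is idempotent, which is what deduplication by
#' [reaction_key()] relies on.
#'
#' @param s SMILES string.
#' @return canonical SMILES string.
#' @export
smiles_canonical <- function(s) {
  mol <- if (inherits(s, "rxnvae_mol")) s else smiles_parse(s)
  mol <- .fold_hydrogens(mol)
  n <- nrow(mol$atoms)
  # connected components
  comp <- seq_len(n)
  if (nrow(mol$bonds)) {
    repeat {
      ch <- FALSE
      for (r in seq_len(nrow(mol$bonds))) {
        a <- mol$bonds$a1[r]; b <- mol$bonds$a2[r]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) { comp[a] <- m; comp[b] <- m; ch <- TRUE }
      }
      if (!ch) break
    }
  }
  ranks <- .canonical_ranks(mol)
  parts <- vapply(sort(unique(comp)), function(cc) {
    .write_component(mol, which(comp == cc), ranks)
  }, "")
  paste(sort(parts), collapse = ".")
}

#' Construct a Species record
#'
#' @param smiles species SMILES in either the implicit- or explicit-hydrogen
#'   dialect.
#' @return object of class `rxnvae_species`: input SMILES, canonical SMILES,
#'   elemental composition, and net formal charge.
#' @export
species <- function(smiles) {
  mol <- smiles_parse(smiles)
  comp <- smiles_composition(mol)
  structure(list(
    smiles = smiles,
    canonical_smiles = smiles_canonical(mol),
    composition = comp,
    net_charge = attr(comp, "charge")
  ), class = "rxnvae_species")
}

#' @export
print.rxnvae_species <- function(x, ...) {
  cat(sprintf("<species> %s  (canonical %s)  %s  charge %+d\n",
              x$smiles, x$canonical_smiles,
              paste0(names(x$composition), x$composition, collapse = ""),
              x$net_charge))
  invisible(x)
}

#' Is a SMILES string a valid species?
#'
#' Valid means: parseable under the supported grammar with consistent valences.
#' Open-shell radicals and ions are valid; chemical stability is not assessed.
#'
#' @param smiles SMILES string.
#' @return `TRUE` or `FALSE`.
#' @export
smiles_is_valid <- function(smiles) {
  !inherits(tryCatch(smiles_parse(smiles), rxnvae_smiles_error = function(e) e),
            "rxnvae_smiles_error")
}
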