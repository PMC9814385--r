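# Reaction-equation dialect: "coefSMILES + coefSMILES ... >> ..." with an
# optional unicode arrow accepted on input. Coefficients are integer prefixes
# glued to the species SMILES ("2[H][H]"); coefficient 1 is implicit on output.

stop_reaction <- function(msg) stop_rxnvae(msg, "rxnvae_reaction_error")

.SEPARATORS <- c("→", ">>")

#' Parse a reaction-equation string
#'
#' @param text one equation, e.g. `"O=C=O + 2[H][H] >> C=O + O"`. Both `">>"`
#'   and the unicode arrow are accepted as the side separator; species terms
#'   are separated by `" + "`; a leading integer is the stoichiometric
#'   coefficient (default 1).
#' @param parse_species if `TRUE` (default) each species SMILES is parsed and
#'   canonicalized eagerly; with `FALSE` only the dialect structure is checked,
#'   which the generation cascade uses to separate "unparseable string" from
#'   "invalid species".
#' @return object of class `rxnvae_reaction` with `reactants` and `products`
#'   (lists of `list(coefficient, smiles, species)`) and `source_string`.
#' @export
parse_reaction_string <- function(text, parse_species = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop_reaction("reaction text must be a single string")
  }
  seps_found <- vapply(.SEPARATORS, function(sp) {
    lengths(regmatches(text, gregexpr(sp, text, fixed = TRUE)))
  }, 0L)
  if (sum(seps_found) != 1L) {
    stop_reaction(sprintf(
      "expected exactly one side separator ('>>' or unicode arrow) in '%s'", text
    ))
  }
  sep <- .SEPARATORS[seps_found == 1L]
  sides <- strsplit(text, sep, fixed = TRUE)[[1]]
  if (length(sides) != 2L || !nzchar(trimws(sides[1])) || !nzchar(trimws(sides[2]))) {
    stop_reaction(sprintf("empty reaction side in '%s'", text))
  }

  parse_side <- function(side_text, side_name) {
    side_text <- trimws(side_text)
    if (grepl("^\\+", side_text) || grepl("\\+$", side_text) ||
        grepl("\\s\\+\\s*\\+\\s", side_text)) {
      stop_reaction(sprintf("empty species term on %s side of '%s'", side_name, text))
    }
    terms <- strsplit(side_text, "\\s\\+\\s")[[1]]
    terms <- trimws(terms)
    if (length(terms) == 0L || any(!nzchar(terms))) {
      stop_reaction(sprintf("empty species term on %s side of '%s'", side_name, text))
    }
    lapply(terms, function(tm) {
      m <- regmatches(tm, regexec("^([0-9]+)?(.+)$", tm))[[1]]
      coef <- if (m[2] == "") 1L else as.integer(m[2])
      if (coef == 0L) {
        stop_reaction(sprintf("zero coefficient in term '%s' of '%s'", tm, text))
      }
      smi <- m[3]
      sp <- NULL
      if (parse_species) {
        sp <- tryCatch(species(smi), rxnvae_smiles_error = function(e) {
          stop_reaction(sprintf("invalid species term '%s' in '%s': %s",
                                tm, text, conditionMessage(e)))
        })
      }
      list(coefficient = coef, smiles = smi, species = sp)
    })
  }

  structure(list(
    reactants = parse_side(sides[1], "reactant"),
    products = parse_side(sides[2], "product"),
    source_string = text
  ), class = "rxnvae_reaction")
}

#' Serialize a reaction to the canonical output dialect
#'
#' Emits `">>"` as separator (ASCII-safe) and omits unit coefficients; a
#' parse/serialize/parse round trip is a fixed point of the dialect.
#'
#' @param eq `rxnvae_reaction`.
#' @return single string.
#' @export
format_reaction <- function(eq) {
  fmt_side <- function(side) {
    paste(vapply(side, function(tm) {
      paste0(if (tm$coefficient == 1L) "" else tm$coefficient, tm$smiles)
    }, ""), collapse = " + ")
  }
  paste(fmt_side(eq$reactants), ">>", fmt_side(eq$products))
}

#' @export
print.rxnvae_reaction <- function(x, ...) {
  cat("<reaction>", format_reaction(x), "\n")
  invisible(x)
}

#' Elemental composition vector of a reaction side or species
#'
#' @param x a `rxnvae_species`, or a list of `(coefficient, species)` terms.
#' @return named integer vector of element totals with `charge` attribute.
#' @export
elemental_composition <- function(x) {
  if (inherits(x, "rxnvae_species")) return(x$composition)
  .side_composition(x)
}

.side_composition <- function(side) {
  total <- integer(0)
  charge <- 0L
  for (tm in side) {
    sp <- tm$species
    if (is.null(sp)) sp <- species(tm$smiles)
    comp <- sp$composition
    for (el in names(comp)) {
      total[el] <- (if (el %in% names(total)) total[[el]] else 0L) +
        tm$coefficient * comp[[el]]
    }
    charge <- charge + tm$coefficient * sp$net_charge
  }
  total <- total[order(names(total))]
  attr(total, "charge") <- charge
  total
}

#' Stoichiometric balance check
#'
#' A reaction is balanced iff the coefficient-weighted per-element atom totals
#' (implicit hydrogens included) and, by default, the net formal charge agree
#' between the two sides. Charge checking exists because kinetics corpora
#' contain ions; disable with `check_charge = FALSE`.
#'
#' @param eq `rxnvae_reaction` or a reaction string.
#' @param check_charge also require equal net charge (default `TRUE`).
#' @return `TRUE` or `FALSE`.
#' @export
is_balanced <- function(eq, check_charge = TRUE) {
  if (is.character(eq)) eq <- parse_reaction_string(eq)
  lhs <- .side_composition(eq$reactants)
  rhs <- .side_composition(eq$products)
  els <- sort(union(names(lhs), names(rhs)))
  get <- function(v, el) if (el %in% names(v)) v[[el]] else 0L
  for (el in els) {
    if (get(lhs, el) != get(rhs, el)) return(FALSE)
  }
  if (check_charge && attr(lhs, "charge") != attr(rhs, "charge")) return(FALSE)
  TRUE
}

#' Direction-preserving canonical key of a reaction
#'
#' Each side is expanded into a multiset of canonical species SMILES
#' (coefficient copies of each species), sorted lexicographically, and the two
#' sides are joined with `">>"`. Two equations are duplicates iff their keys
#' are equal; `A >> B` and `B >> A` get different keys (kinetics reactions are
#' directional; pass `directional = FALSE` to relax).
#'
#' @param eq `rxnvae_reaction` or reaction string.
#' @param directional keep the two sides ordered (default `TRUE`).
#' @return single string key.
#' @export
reaction_key <- function(eq, directional = TRUE) {
  if (is.character(eq)) eq <- parse_reaction_string(eq)
  side_key <- function(side) {
    expanded <- unlist(lapply(side, function(tm) {
      sp <- tm$species
      canon <- if (is.null(sp)) smiles_canonical(tm$smiles) else sp$canonical_smiles
      rep(canon, tm$coefficient)
    }))
    paste(sort(expanded), collapse = "+")
  }
  keys <- c(side_key(eq$reactants), side_key(eq$products))
  if (!directional) keys <- sort(keys)
  paste(keys, collapse = ">>")
}

#' Number of distinct species on each reaction side
#'
#' @param eq `rxnvae_reaction`.
#' @return integer vector `c(reactants, products)` of distinct-species counts.
#' @export
species_per_side <- function(eq) {
  c(
    reactants = length(unique(vapply(eq$reactants, `[[`, "", "smiles"))),
    products = length(unique(vapply(eq$products, `[[`, "", "smiles")))
  )
}

#' Read a reaction text file
#'
#' UTF-8, one equation per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of equation strings.
#' @export
read_reaction_file <- function(path) {
  if (!file.exists(path)) stop_rxnvae(paste0("no such file: ", path), "rxnvae_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a reaction text file
#'
#' @param equations character vector of equation strings or list of
#'   `rxnvae_reaction` objects.
#' @param path output path.
#' @export
write_reaction_file <- function(equations, path) {
  if (is.list(equations)) {
    equations <- vapply(equations, function(e) {
      if (inherits(e, "rxnvae_reaction")) format_reaction(e) else as.character(e)
    }, "")
  }
  writeLines(equations, path, useBytes = TRUE)
  invisible(path)
}

#' Export species compositions as CSV
#'
#' One row per unique canonical species: `canonical_smiles`, Hill-ordered
#' `formula`, `charge`.
#'
#' @param smiles_vec character vector of species SMILES.
#' @param path output CSV path.
#' @export
write_composition_csv <- function(smiles_vec, path) {
  sps <- lapply(unique(smiles_vec), species)
  canon <- vapply(sps, `[[`, "", "canonical_smiles")
  keep <- !duplicated(canon)
  sps <- sps[keep]
  formula <- vapply(sps, function(sp) {
    comp <- sp$composition
    # Hill order: C, H, then alphabetical
    els <- names(comp)
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
    paste0(ord, ifelse(comp[ord] > 1L, comp[ord], ""), collapse = "")
  }, "")
  df <- data.frame(
    canonical_smiles = canon[keep],
    formula = formula,
    charge = vapply(sps, `[[`, 0L, "net_charge")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
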