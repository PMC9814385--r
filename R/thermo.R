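# Reaction thermochemistry combination layer. Per-species standard-state
# properties (enthalpy in eV, entropy in eV/K, dipole magnitude in debye) come
# from a pluggable table keyed by canonical SMILES — any adapter that can map
# canonical SMILES to such rows (e.g. a semi-empirical code) can be swapped in.
# Reaction-level quantities are coefficient-weighted product-minus-reactant
# sums; a |dG| <= 5 eV stability filter separates plausibly stable reactions.

stop_thermo <- function(msg) stop_rxnvae(msg, "rxnvae_thermo_error")

.THERMO_COLUMNS <- c("canonical_smiles", "H_eV", "S_eV_per_K", "dipole_debye")

#' Read / write a species property table
#'
#' CSV with unit-bearing column names `canonical_smiles, H_eV, S_eV_per_K,
#' dipole_debye`; the names are checked on read so silently mis-scaled tables
#' are rejected rather than converted.
#'
#' @param path CSV path.
#' @return data.frame property table.
#' @export
read_thermo_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.THERMO_COLUMNS %in% names(tab))) {
    stop_thermo(paste0(
      "property table must have unit-labelled columns: ",
      paste(.THERMO_COLUMNS, collapse = ", ")
    ))
  }
  if (any(tab$dipole_debye < 0, na.rm = TRUE)) {
    stop_thermo("dipole magnitudes must be >= 0")
  }
  tab
}

#' @rdname read_thermo_table
#' @param tab property table data.frame.
#' @export
write_thermo_table <- function(tab, path) {
  utils::write.csv(tab[, .THERMO_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.thermo_lookup <- function(tab, canon_smiles) {
  hit <- match(canon_smiles, tab$canonical_smiles)
  if (is.na(hit)) {
    stop_thermo(sprintf("species '%s' missing from the property table", canon_smiles))
  }
  tab[hit, ]
}

#' Standard-state Gibbs energy of one species
#'
#' The default (`sign_mode = "standard"`) uses the textbook relation
#' `G = H - T*S`. `sign_mode = "published"` reproduces the `H + T*S` form printed
#' in the source this package reimplements (most likely a typo there; both are
#' provided rather than guessing).
#'
#' @param H_eV standard-state enthalpy, eV.
#' @param S_eV_per_K standard-state entropy, eV/K.
#' @param T_K temperature in kelvin (default 298.15, room temperature).
#' @param sign_mode `"standard"` or `"published"`.
#' @return Gibbs energy in eV.
#' @export
gibbs_of_species <- function(H_eV, S_eV_per_K, T_K = 298.15,
                             sign_mode = c("standard", "published")) {
  sign_mode <- match.arg(sign_mode)
  if (any(T_K <= 0)) stop_thermo("temperature must be > 0 K")
  if (sign_mode == "standard") H_eV - T_K * S_eV_per_K else H_eV + T_K * S_eV_per_K
}

# coefficient-weighted sum of a per-species quantity over one reaction side
.side_sum <- function(side, tab, f) {
  s <- 0
  for (tm in side) {
    canon <- if (!is.null(tm$species)) tm$species$canonical_smiles else
      smiles_canonical(tm$smiles)
    s <- s + tm$coefficient * f(.thermo_lookup(tab, canon))
  }
  s
}

#' Reaction Gibbs energy
#'
#' Coefficient-weighted `sum(G products) - sum(G reactants)` in eV. Every
#' species must be present in the table (error names the missing one).
#'
#' @param eq `rxnvae_reaction` or reaction string.
#' @param tab property table (see [read_thermo_table()]).
#' @param T_K temperature, K.
#' @param sign_mode see [gibbs_of_species()].
#' @return dG in eV.
#' @export
reaction_gibbs <- function(eq, tab, T_K = 298.15,
                           sign_mode = c("standard", "published")) {
  sign_mode <- match.arg(sign_mode)
  if (is.character(eq)) eq <- parse_reaction_string(eq)
  g <- function(row) gibbs_of_species(row$H_eV, row$S_eV_per_K, T_K, sign_mode)
  .side_sum(eq$products, tab, g) - .side_sum(eq$reactants, tab, g)
}

#' Reaction entropy difference
#'
#' Coefficient-weighted `sum(S products) - sum(S reactants)` in the table's
#' entropy units (eV/K).
#'
#' @inheritParams reaction_gibbs
#' @return dS in eV/K.
#' @export
reaction_entropy_diff <- function(eq, tab) {
  if (is.character(eq)) eq <- parse_reaction_string(eq)
  .side_sum(eq$products, tab, function(r) r$S_eV_per_K) -
    .side_sum(eq$reactants, tab, function(r) r$S_eV_per_K)
}

#' Reaction dipole-moment difference
#'
#' Coefficient-weighted difference of per-species dipole *magnitudes* (the
#' property table carries magnitudes only, so vector differencing is not
#' possible at this layer), in debye.
#'
#' @inheritParams reaction_gibbs
#' @return d(mu) in debye.
#' @export
reaction_dipole_diff <- function(eq, tab) {
  if (is.character(eq)) eq <- parse_reaction_string(eq)
  .side_sum(eq$products, tab, function(r) r$dipole_debye) -
    .side_sum(eq$reactants, tab, function(r) r$dipole_debye)
}

#' Molecular dipole moment from partial charges and positions
#'
#' `mu = sum_a q_a * (r_a - origin)`. The default origin is the center of
#' nuclear charge; `"centroid"` uses the geometric centroid and `"none"` the
#' coordinate origin as given. The vector is origin-independent exactly when
#' the total partial charge is zero.
#'
#' @param atoms data.frame with columns `element`, `q` (partial charge,
#'   elementary charge units) and `x`, `y`, `z` (angstrom).
#' @param origin `"charge_center"`, `"centroid"` or `"none"`.
#' @return list `vector` (length-3, debye-scaled charge*angstrom units as
#'   supplied) and `magnitude`.
#' @export
dipole_moment <- function(atoms, origin = c("charge_center", "centroid", "none")) {
  origin <- match.arg(origin)
  stopifnot(all(c("element", "q", "x", "y", "z") %in% names(atoms)),
            nrow(atoms) > 0)
  R <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(R))) stop_thermo("non-finite atom coordinates")
  o <- switch(origin,
    none = c(0, 0, 0),
    centroid = colMeans(R),
    charge_center = {
      zn <- .ATOMIC_NUMBER[atoms$element]
      if (anyNA(zn)) {
        stop_thermo(sprintf("unknown element '%s' for nuclear charge center",
                            atoms$element[which(is.na(zn))[1]]))
      }
      colSums(R * zn) / sum(zn)
    }
  )
  v <- colSums((R - matrix(o, nrow(R), 3, byrow = TRUE)) * atoms$q)
  list(vector = unname(v), magnitude = sqrt(sum(v^2)))
}

#' Thermodynamic stability filter
#'
#' Keeps reactions whose |dG| does not exceed the bound ("exceeded" read
#' strictly: the boundary value itself is kept).
#'
#' @param delta_G numeric vector of reaction Gibbs energies, eV.
#' @param bound symmetric bound in eV (default 5).
#' @return logical vector, `TRUE` = kept.
#' @export
stability_filter <- function(delta_G, bound = 5.0) {
  stopifnot(bound >= 0)
  abs(delta_G) <= bound
}

#' Tabulate reaction thermodynamics for a set of equations
#'
#' Computes dG, dS and d(mu) for each equation and applies the stability
#' filter. Equations with species missing from the table are reported, not
#' errored, so a generated set containing novel species degrades gracefully.
#'
#' @param equations character vector of reaction strings.
#' @param tab property table.
#' @param T_K temperature, K.
#' @param sign_mode see [gibbs_of_species()].
#' @param bound stability bound, eV.
#' @return data.frame `equation, delta_G_eV, delta_S_eV_per_K,
#'   delta_mu_debye, kept, note`.
#' @export
reaction_thermo_table <- function(equations, tab, T_K = 298.15,
                                  sign_mode = c("standard", "published"),
                                  bound = 5.0) {
  sign_mode <- match.arg(sign_mode)
  if (length(equations) == 0L) {
    return(data.frame(equation = character(0), delta_G_eV = numeric(0),
                      delta_S_eV_per_K = numeric(0),
                      delta_mu_debye = numeric(0), kept = logical(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(equations, function(line) {
    r <- tryCatch({
      eq <- parse_reaction_string(line)
      data.frame(
        equation = line,
        delta_G_eV = reaction_gibbs(eq, tab, T_K, sign_mode),
        delta_S_eV_per_K = reaction_entropy_diff(eq, tab),
        delta_mu_debye = reaction_dipole_diff(eq, tab),
        kept = NA, note = "", stringsAsFactors = FALSE
      )
    }, rxnvae_error = function(e) {
      data.frame(equation = line, delta_G_eV = NA_real_,
                 delta_S_eV_per_K = NA_real_, delta_mu_debye = NA_real_,
                 kept = FALSE, note = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    r
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$delta_G_eV)
  out$kept[ok] <- stability_filter(out$delta_G_eV[ok], bound)
  out
}
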