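# Seeded synthetic corpus generator. Emulates a cleaned gas-phase kinetics
# corpus at toy scale: small H/C/O/N molecules (radicals included), 1-3
# distinct species per side, integer coefficients, balanced by construction,
# with controllable fractions of corrupted lines for negative-path testing.

#' Default gas-phase molecule library
#'
#' About two dozen small H/C/O/N species mirroring what a gas-phase kinetics
#' corpus contains, radicals included. Compositions are computed from the
#' SMILES at construction, so the library is consistent by definition.
#'
#' @return data.frame with `name`, `smiles`, `canonical_smiles`.
#' @export
rxn_library <- function() {
  spec <- c(
    H2 = "[H][H]", O2 = "O=O", H2O = "O", H2O2 = "OO", CH4 = "C",
    CO2 = "O=C=O", CH2O = "C=O", CH3OH = "CO", C2H6 = "CC", C2H4 = "C=C",
    C2H2 = "C#C", N2 = "N#N", NH3 = "N", HCN = "C#N", CH3CHO = "CC=O",
    HCOOH = "OC=O", N2H4 = "NN", DME = "COC", C2H5OH = "CCO",
    H = "[H]", O = "[O]", OH = "[OH]", CH3 = "[CH3]", HO2 = "[O]O",
    NO = "[N]=O", NH2 = "[NH2]", HCO = "[CH]=O"
  )
  data.frame(
    name = names(spec),
    smiles = unname(spec),
    canonical_smiles = vapply(unname(spec), smiles_canonical, ""),
    stringsAsFactors = FALSE
  )
}

#' Synthetic corpus generator configuration
#'
#' @param library molecule library data.frame (see [rxn_library()]); needs a
#'   `smiles` column.
#' @param n_equations number of output lines (clean + corrupted).
#' @param max_species_per_side distinct-species cap per side (default 3).
#' @param max_coefficient stoichiometric coefficient bound for the balancing
#'   search (default 4).
#' @param max_length reject clean equations longer than this many characters
#'   (keeps the training sequences of comparable length; default 64).
#' @param side_size_weights sampling weights for the number of distinct
#'   reactant species (length `max_species_per_side`); the default favours
#'   uni/bimolecular sides the way elementary gas-phase reactions do.
#' @param coef_weights sampling weights for each stoichiometric coefficient
#'   `1..max_coefficient`; the default makes unit coefficients dominant.
#' @param corruption named fractions `c(unbalanced=, invalid=, duplicate=)`
#'   in \[0,1\], summing to at most 1; counts are `floor(fraction * n)`.
#' @param seed integer seed; everything the generator emits is a deterministic
#'   function of the config.
#' @return `rxnvae_generator_config` list.
#' @export
generator_config <- function(library = rxn_library(), n_equations = 500L,
                             max_species_per_side = 3L, max_coefficient = 4L,
                             max_length = 64L,
                             side_size_weights = c(0.25, 0.55, 0.20),
                             coef_weights = c(0.60, 0.25, 0.10, 0.05),
                             corruption = c(unbalanced = 0, invalid = 0, duplicate = 0),
                             seed = 1L) {
  corr <- c(unbalanced = 0, invalid = 0, duplicate = 0)
  corr[names(corruption)] <- corruption
  if (any(corr < 0) || sum(corr) > 1) {
    stop_config("corruption fractions must be in [0,1] and sum to at most 1")
  }
  if (!"smiles" %in% names(library) || nrow(library) == 0L) {
    stop_config("library must be a non-empty data.frame with a 'smiles' column")
  }
  side_size_weights <- rep_len(side_size_weights, max_species_per_side)
  coef_weights <- rep_len(coef_weights, max_coefficient)
  structure(list(
    library = library, n_equations = as.integer(n_equations),
    max_species_per_side = as.integer(max_species_per_side),
    max_coefficient = as.integer(max_coefficient),
    max_length = as.integer(max_length),
    side_size_weights = side_size_weights / sum(side_size_weights),
    coef_weights = coef_weights / sum(coef_weights),
    corruption = corr, seed = as.integer(seed)
  ), class = "rxnvae_generator_config")
}

# composition matrix (species x elements, last column = charge) for a library
.library_matrix <- function(library) {
  comps <- lapply(library$smiles, smiles_composition)
  els <- sort(unique(unlist(lapply(comps, names))))
  M <- matrix(0L, nrow(library), length(els) + 1L,
              dimnames = list(library$smiles, c(els, ".charge")))
  for (i in seq_along(comps)) {
    M[i, names(comps[[i]])] <- comps[[i]]
    M[i, ".charge"] <- attr(comps[[i]], "charge")
  }
  M
}

# enumerate every side (multiset of <= max_species distinct species with
# coefficients 1..max_coef) and index them by elemental-composition key;
# memoised because enumeration is the expensive part
.side_index_cache <- new.env(parent = emptyenv())

.side_index <- function(library, max_species, max_coef) {
  key <- paste0("k", digest_key(
    paste(c(library$smiles, max_species, max_coef), collapse = "\r")
  ))
  hit <- .side_index_cache[[key]]
  if (!is.null(hit)) return(hit)

  M <- .library_matrix(library)
  n <- nrow(library)
  coefs <- seq_len(max_coef)
  sides <- list()  # rows: species indices (0 = unused) and coefficients

  add <- function(df) sides[[length(sides) + 1L]] <<- df
  add(cbind(expand.grid(i = seq_len(n), ci = coefs), j = 0L, cj = 0L, k = 0L, ck = 0L))
  if (max_species >= 2L && n >= 2L) {
    pr <- t(utils::combn(n, 2))
    g <- expand.grid(p = seq_len(nrow(pr)), ci = coefs, cj = coefs)
    add(cbind(i = pr[g$p, 1], ci = g$ci, j = pr[g$p, 2], cj = g$cj, k = 0L, ck = 0L))
  }
  if (max_species >= 3L && n >= 3L) {
    tr <- t(utils::combn(n, 3))
    g <- expand.grid(p = seq_len(nrow(tr)), ci = coefs, cj = coefs, ck = coefs)
    add(cbind(i = tr[g$p, 1], ci = g$ci, j = tr[g$p, 2], cj = g$cj,
              k = tr[g$p, 3], ck = g$ck))
  }
  S <- do.call(rbind, lapply(sides, as.matrix))
  colnames(S) <- c("i", "ci", "j", "cj", "k", "ck")

  comp <- S[, "ci"] * M[S[, "i"], , drop = FALSE]
  hasj <- S[, "j"] > 0L
  comp[hasj, ] <- comp[hasj, ] +
    S[hasj, "cj"] * M[S[hasj, "j"], , drop = FALSE]
  hask <- S[, "k"] > 0L
  comp[hask, ] <- comp[hask, ] +
    S[hask, "ck"] * M[S[hask, "k"], , drop = FALSE]
  keys <- do.call(paste, c(as.data.frame(comp), sep = ","))

  idx <- list(S = S, keys = keys, by_key = split(seq_along(keys), keys),
              M = M)
  .side_index_cache[[key]] <- idx
  idx
}

# small deterministic string hash for the cache key (no digest dependency)
digest_key <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  as.character(h)
}

.side_terms <- function(S_row, library) {
  out <- list()
  for (slot in c("i", "j", "k")) {
    sp <- S_row[[slot]]
    if (sp > 0L) {
      out[[length(out) + 1L]] <-
        list(coefficient = S_row[[paste0("c", slot)]], smiles = library$smiles[sp])
    }
  }
  out
}

.side_string <- function(terms) {
  paste(vapply(terms, function(tm) {
    paste0(if (tm$coefficient == 1L) "" else tm$coefficient, tm$smiles)
  }, ""), collapse = " + ")
}

# expanded-multiset signature of a side, used to exclude identity reactions
.side_multiset <- function(S_row) {
  parts <- character(0)
  for (slot in c("i", "j", "k")) {
    if (S_row[[slot]] > 0L) {
      parts <- c(parts, rep(S_row[[slot]], S_row[[paste0("c", slot)]]))
    }
  }
  paste(sort(as.integer(parts)), collapse = ",")
}

#' Generate a labeled synthetic reaction corpus
#'
#' Clean equations are balanced by construction: a random reactant side is
#' drawn from the library and a product side with the identical elemental
#' composition (and different species multiset) is found by bounded integer
#' search over enumerated sides. Corrupted lines are derived from clean ones:
#' a perturbed coefficient (`unbalanced`), a mangled species token
#' (`invalid`), or a verbatim copy of an earlier line (`duplicate`). Every
#' line carries a ground-truth label.
#'
#' @param config `rxnvae_generator_config`.
#' @return list with `lines` (character vector in the reaction dialect) and
#'   `labels` (data.frame `line`, `text`, `label`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "rxnvae_generator_config"))
  lib <- config$library
  idx <- .side_index(lib, config$max_species_per_side, config$max_coefficient)
  set.seed(config$seed)

  n <- config$n_equations
  n_unbal <- floor(config$corruption[["unbalanced"]] * n)
  n_inval <- floor(config$corruption[["invalid"]] * n)
  n_dup <- floor(config$corruption[["duplicate"]] * n)
  n_clean <- n - n_unbal - n_inval - n_dup
  if (n_clean < 1L) stop_config("corruption fractions leave no clean equations")

  S <- idx$S
  nlib <- nrow(lib)
  seen_keys <- new.env(parent = emptyenv())
  clean <- character(n_clean)
  clean_terms <- vector("list", n_clean)
  made <- 0L
  attempts <- 0L
  max_attempts <- 200L * n_clean
  # draw a reactant side with realistic shape: side size and coefficients
  # follow the configured weights instead of the uniform-over-enumeration
  # measure (which would be dominated by 3-species high-coefficient sides)
  draw_side <- function() {
    k <- sample.int(config$max_species_per_side, 1L,
                    prob = config$side_size_weights)
    k <- min(k, nlib)
    sp <- sort(sample.int(nlib, k))
    cf <- sample.int(config$max_coefficient, k, replace = TRUE,
                     prob = config$coef_weights)
    row <- list(i = sp[1], ci = cf[1], j = 0L, cj = 0L, k = 0L, ck = 0L)
    if (k >= 2L) { row$j <- sp[2]; row$cj <- cf[2] }
    if (k >= 3L) { row$k <- sp[3]; row$ck <- cf[3] }
    row
  }
  side_comp_key <- function(row) {
    M <- idx$M
    comp <- row$ci * M[row$i, ]
    if (row$j > 0L) comp <- comp + row$cj * M[row$j, ]
    if (row$k > 0L) comp <- comp + row$ck * M[row$k, ]
    paste(comp, collapse = ",")
  }
  while (made < n_clean) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_config("library cannot balance enough distinct equations; relax the config")
    }
    lhs_row <- draw_side()
    cand <- idx$by_key[[side_comp_key(lhs_row)]]
    if (is.null(cand)) next
    ms_r <- .side_multiset(lhs_row)
    cand <- cand[vapply(cand, function(cc) {
      .side_multiset(as.list(S[cc, ])) != ms_r
    }, TRUE)]
    if (length(cand) == 0L) next
    pr <- cand[sample.int(length(cand), 1L)]
    lhs <- .side_terms(lhs_row, lib)
    rhs <- .side_terms(as.list(S[pr, ]), lib)
    line <- paste(.side_string(lhs), ">>", .side_string(rhs))
    if (nchar(line) > config$max_length) next
    key <- reaction_key(parse_reaction_string(line))
    if (!is.null(seen_keys[[key]])) next
    seen_keys[[key]] <- TRUE
    made <- made + 1L
    clean[made] <- line
    clean_terms[[made]] <- list(lhs = lhs, rhs = rhs)
  }

  corrupt_lines <- character(0)
  corrupt_label <- character(0)

  if (n_unbal > 0L) {
    for (q in seq_len(n_unbal)) {
      repeat {
        src <- sample.int(n_clean, 1L)
        tm <- clean_terms[[src]]
        side <- if (stats::runif(1) < 0.5) "lhs" else "rhs"
        pos <- sample.int(length(tm[[side]]), 1L)
        tm[[side]][[pos]]$coefficient <-
          tm[[side]][[pos]]$coefficient + sample.int(2L, 1L)
        line <- paste(.side_string(tm$lhs), ">>", .side_string(tm$rhs))
        if (!is_balanced(line)) { corrupt_lines <- c(corrupt_lines, line); break }
      }
      corrupt_label <- c(corrupt_label, "unbalanced")
    }
  }
  if (n_inval > 0L) {
    for (q in seq_len(n_inval)) {
      src <- sample.int(n_clean, 1L)
      tm <- clean_terms[[src]]
      side <- if (stats::runif(1) < 0.5) "lhs" else "rhs"
      pos <- sample.int(length(tm[[side]]), 1L)
      smi <- tm[[side]][[pos]]$smiles
      at <- sample.int(nchar(smi) + 1L, 1L) - 1L
      tm[[side]][[pos]]$smiles <-
        paste0(substr(smi, 1, at), "Q", substr(smi, at + 1L, nchar(smi)))
      corrupt_lines <- c(corrupt_lines,
                         paste(.side_string(tm$lhs), ">>", .side_string(tm$rhs)))
      corrupt_label <- c(corrupt_label, "invalid")
    }
  }
  if (n_dup > 0L) {
    for (q in seq_len(n_dup)) {
      corrupt_lines <- c(corrupt_lines, clean[sample.int(n_clean, 1L)])
      corrupt_label <- c(corrupt_label, "duplicate")
    }
  }

  # clean block first (duplicates must follow their originals), corrupted
  # block shuffled so rejection reasons are interleaved
  ord <- sample.int(length(corrupt_lines))
  lines <- c(clean, corrupt_lines[ord])
  labels <- data.frame(
    line = seq_along(lines),
    text = lines,
    label = c(rep("clean", n_clean), corrupt_label[ord]),
    stringsAsFactors = FALSE
  )
  list(lines = lines, labels = labels)
}

#' Generate a per-species standard-state property table
#'
#' Seeded plausible values (enthalpy in eV, entropy in eV/K, dipole magnitude
#' in debye) for every library species, with exactly planted values for
#' H2 / O2 / H2O so reaction-level answers have closed-form expectations:
#' H2 (0 eV, 1e-3 eV/K, 0 D), O2 (0, 2e-3, 0), H2O (-2.5, 1.5e-3, 1.85).
#'
#' @param library molecule library data.frame.
#' @param seed integer seed.
#' @param h_range,s_range,mu_range uniform sampling ranges.
#' @return data.frame `canonical_smiles`, `H_eV`, `S_eV_per_K`,
#'   `dipole_debye`.
#' @export
generate_thermo_table <- function(library = rxn_library(), seed = 1L,
                                  h_range = c(-3, 3), s_range = c(5e-4, 3e-3),
                                  mu_range = c(0, 3)) {
  set.seed(seed)
  canon <- vapply(library$smiles, smiles_canonical, "", USE.NAMES = FALSE)
  n <- length(canon)
  tab <- data.frame(
    canonical_smiles = canon,
    H_eV = stats::runif(n, h_range[1], h_range[2]),
    S_eV_per_K = stats::runif(n, s_range[1], s_range[2]),
    dipole_debye = stats::runif(n, mu_range[1], mu_range[2]),
    stringsAsFactors = FALSE
  )
  plant <- list(
    list(smiles_canonical("[H][H]"), 0, 1e-3, 0),
    list(smiles_canonical("O=O"), 0, 2e-3, 0),
    list(smiles_canonical("O"), -2.5, 1.5e-3, 1.85)
  )
  for (p in plant) {
    hit <- tab$canonical_smiles == p[[1]]
    if (any(hit)) {
      tab$H_eV[hit] <- p[[2]]
      tab$S_eV_per_K[hit] <- p[[3]]
      tab$dipole_debye[hit] <- p[[4]]
    }
  }
  tab[!duplicated(tab$canonical_smiles), ]
}
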