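# Independent oracles: these deliberately do NOT use the package's SMILES
# parser or reaction machinery, so they can arbitrate its verdicts.

# hand-written molecular formulas for the default library, keyed by the exact
# SMILES the generator emits
ORACLE_FORMULAS <- list(
  "[H][H]" = c(H = 2), "O=O" = c(O = 2), "O" = c(H = 2, O = 1),
  "OO" = c(H = 2, O = 2), "C" = c(C = 1, H = 4), "O=C=O" = c(C = 1, O = 2),
  "C=O" = c(C = 1, H = 2, O = 1), "CO" = c(C = 1, H = 4, O = 1),
  "CC" = c(C = 2, H = 6), "C=C" = c(C = 2, H = 4), "C#C" = c(C = 2, H = 2),
  "N#N" = c(N = 2), "N" = c(H = 3, N = 1), "C#N" = c(C = 1, H = 1, N = 1),
  "CC=O" = c(C = 2, H = 4, O = 1), "OC=O" = c(C = 1, H = 2, O = 2),
  "NN" = c(H = 4, N = 2), "COC" = c(C = 2, H = 6, O = 1),
  "CCO" = c(C = 2, H = 6, O = 1), "[H]" = c(H = 1), "[O]" = c(O = 1),
  "[OH]" = c(H = 1, O = 1), "[CH3]" = c(C = 1, H = 3),
  "[O]O" = c(H = 1, O = 2), "[N]=O" = c(N = 1, O = 1),
  "[NH2]" = c(H = 2, N = 1), "[CH]=O" = c(C = 1, H = 1, O = 1)
)

# brute-force per-element summation balance oracle over a formula dictionary;
# returns TRUE/FALSE, or NA if any species is not in the dictionary
oracle_balanced <- function(line, formulas = ORACLE_FORMULAS) {
  sides <- strsplit(line, " >> ", fixed = TRUE)[[1]]
  if (length(sides) != 2) return(NA)
  side_total <- function(side) {
    total <- c()
    for (term in strsplit(side, " + ", fixed = TRUE)[[1]]) {
      m <- regmatches(term, regexec("^([0-9]*)(.*)$", term))[[1]]
      coef <- if (m[2] == "") 1 else as.integer(m[2])
      f <- formulas[[m[3]]]
      if (is.null(f)) return(NULL)
      for (el in names(f)) total[el] <- (if (el %in% names(total)) total[[el]] else 0) + coef * f[[el]]
    }
    total[order(names(total))]
  }
  l <- side_total(sides[1]); r <- side_total(sides[2])
  if (is.null(l) || is.null(r)) return(NA)
  identical(l[l > 0], r[r > 0])
}

# python RDKit, used as an external reference implementation (never as the
# package's own computation path)
rdkit_formulas <- function(smiles_vec) {
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.rdMolDescriptors import CalcMolFormula",
    "for line in sys.stdin.read().splitlines():",
    "    m = Chem.MolFromSmiles(line, sanitize=True)",
    "    print(CalcMolFormula(m) if m is not None else 'PARSE_FAIL')",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  input = smiles_vec, stdout = TRUE))
  if (!is.null(attr(out, "status"))) return(NULL)
  out
}

# formula string from a package composition vector, in RDKit's Hill order
hill_formula <- function(comp) {
  els <- names(comp)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  f <- paste0(ord, ifelse(comp[ord] > 1, comp[ord], ""), collapse = "")
  ch <- attr(comp, "charge")
  if (!is.null(ch) && ch != 0) {
    f <- paste0(f, if (ch > 0) "+" else "-", if (abs(ch) > 1) abs(ch) else "")
  }
  f
}
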