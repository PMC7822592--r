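## Protein specifications: mature-chain residue string plus the modifiable
## site inventory (disulfide cysteines, carboxylation-eligible glutamates,
## candidate O-glycosylation serines/threonines). Positions are 1-based on
## the MATURE protein, the numbering used for S8 (mouse) and Y12 (human).

## Residue elemental compositions (residue = amino acid minus water).
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Define a protein for intact-mass analysis
#'
#' @param id short identifier string.
#' @param residues one-letter amino-acid string of the mature chain.
#' @param disulfide_bonds list of length-2 integer vectors of cysteine
#'   positions (1-based, mature numbering). Bonds are treated as formed by
#'   default in all mass arithmetic.
#' @param gla_sites integer positions of glutamate residues eligible for
#'   gamma-carboxylation (Gla).
#' @param glycosites integer positions of serine/threonine residues that can
#'   carry a mucin-type O-glycan.
#' @return An object of class `protein_spec`.
#' @examples
#' ocn_mouse()
#' @export
protein_spec <- function(id, residues, disulfide_bonds = list(),
                         gla_sites = integer(), glycosites = integer()) {
  residues <- toupper(gsub("\\s", "", residues))
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(letters, names(.RESIDUE_FORMULA))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- length(letters)
  check_pos <- function(pos, what, allowed) {
    pos <- as.integer(pos)
    if (any(pos < 1 | pos > n)) {
      stop(what, " position out of range [1, ", n, "]")
    }
    wrong <- pos[!letters[pos] %in% allowed]
    if (length(wrong) > 0L) {
      stop(what, " position(s) ", paste(wrong, collapse = ", "),
           " are not ", paste(allowed, collapse = "/"), " residues (found ",
           paste(letters[wrong], collapse = ", "), ")")
    }
    pos
  }
  disulfide_bonds <- lapply(disulfide_bonds, function(b) {
    if (length(b) != 2L) stop("each disulfide bond must pair two positions")
    check_pos(b, "disulfide", "C")
  })
  structure(
    list(
      id = id,
      residues = residues,
      disulfide_bonds = disulfide_bonds,
      gla_sites = check_pos(gla_sites, "gla_site", "E"),
      glycosites = check_pos(glycosites, "glycosite", c("S", "T"))
    ),
    class = "protein_spec"
  )
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("protein_spec '%s': %d aa, %d disulfide bond(s), %d Gla site(s), %d glycosite(s)\n",
              x$id, nchar(x$residues), length(x$disulfide_bonds),
              length(x$gla_sites), length(x$glycosites)))
  cat(" ", x$residues, "\n")
  invisible(x)
}

#' Elemental composition of a protein chain
#'
#' Sums residue compositions and adds one water per chain; optionally removes
#' two hydrogens per formed disulfide bond.
#'
#' @param protein a `protein_spec`.
#' @param disulfides logical; subtract 2 H per listed bond (default TRUE).
#' @return An `elemental` composition.
#' @export
protein_composition <- function(protein, disulfides = TRUE) {
  letters <- strsplit(protein$residues, "")[[1]]
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (aa in letters) {
    f <- .RESIDUE_FORMULA[[aa]]
    counts[names(f)] <- counts[names(f)] + f
  }
  counts[["H"]] <- counts[["H"]] + 2  # one water per chain
  counts[["O"]] <- counts[["O"]] + 1
  if (disulfides && length(protein$disulfide_bonds) > 0L) {
    counts[["H"]] <- counts[["H"]] - 2L * length(protein$disulfide_bonds)
  }
  elemental(counts[counts > 0])
}

#' Mature mouse osteocalcin (46 aa)
#'
#' The mature mouse OCN chain with its single intramolecular disulfide
#' (C19-C25), the three carboxylation-eligible glutamates (E13, E17, E20)
#' and the N-terminal serine/threonine cluster (S5, S8, T15) as candidate
#' O-glycosylation sites; S8 is the site identified by mutagenesis. The
#' theoretical monoisotopic mass of the fully carboxylated (3 Gla),
#' disulfide-formed chain is 5243.46 Da.
#'
#' @return A `protein_spec`.
#' @export
ocn_mouse <- function() {
  protein_spec(
    id = "OCN_mouse_mature",
    residues = "YLGASVPSPDPLEPTREQCELNPACDELSDQYGLKTAYKRIYGITI",
    disulfide_bonds = list(c(19L, 25L)),
    gla_sites = c(13L, 17L, 20L),
    glycosites = c(5L, 8L, 15L)
  )
}

#' Mature human osteocalcin (49 aa)
#'
#' The mature human OCN chain: disulfide C23-C29, Gla-eligible glutamates
#' E17, E21, E24, and no serine or threonine residues, hence an empty
#' glycosite inventory — human OCN cannot carry a mucin-type O-glycan
#' without mutation (the mouse glycosylation site S8 aligns to Y12 here).
#'
#' @return A `protein_spec`.
#' @export
ocn_human <- function() {
  protein_spec(
    id = "OCN_human_mature",
    residues = "YLYQWLGAPVPYPDPLEPRREVCELNPDCDELADHIGFQEAYRRFYGPV",
    disulfide_bonds = list(c(23L, 29L)),
    gla_sites = c(17L, 21L, 24L),
    glycosites = integer()
  )
}
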