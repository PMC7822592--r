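## Modification definitions and proteoform mass arithmetic.

#' Define a modification
#'
#' A modification is a named mass delta with an elemental composition, a
#' maximum count and a site class used for bound checking. The built-in
#' alphabet covers the deltas needed for intact osteocalcin:
#' gamma-carboxylation (Gla, +CO2), the core-1 O-glycan units
#' (HexNAc, Hex, NeuAc) and methionine/other oxidation (+O).
#'
#' @param name modification name.
#' @param composition an `elemental` composition of the delta, or NULL when
#'   only a bare mass applies.
#' @param mass delta mass in Da; defaults to the mass of `composition`.
#' @param max_count maximum number of copies per proteoform.
#' @param site_class one of `"gla_site"`, `"glycosite"`, `"any"`, `"none"`.
#' @return An object of class `modification_def`.
#' @export
modification_def <- function(name, composition = NULL, mass = NULL,
                             max_count = 1L, site_class = "any") {
  site_class <- match.arg(site_class, c("gla_site", "glycosite", "any", "none"))
  if (is.null(mass)) {
    if (is.null(composition)) stop("give a composition or a bare mass")
    mass <- mono_mass(composition)
  } else if (!is.null(composition)) {
    if (abs(mass - mono_mass(composition)) >= 1e-4) {
      stop(sprintf("mass %.5f not reproducible from composition (%.5f)",
                   mass, mono_mass(composition)))
    }
  }
  if (max_count < 0 || max_count != round(max_count)) {
    stop("max_count must be a non-negative integer")
  }
  structure(
    list(name = name, composition = composition, mass = mass,
         max_count = as.integer(max_count), site_class = site_class),
    class = "modification_def"
  )
}

#' Default modification alphabet for a protein
#'
#' Bounds are derived from the protein's site inventory: Gla up to the
#' number of carboxylation-eligible glutamates; glycan-unit bounds follow
#' the core-1 structure with at most `min(2, n_glycosites)` occupied sites
#' (purified OCN shows up to two glycan adducts); oxidation up to
#' `max_oxidation`.
#'
#' @param protein a `protein_spec`.
#' @param max_oxidation maximum oxidation count (default 2).
#' @return Named list of `modification_def` objects.
#' @export
default_alphabet <- function(protein, max_oxidation = 2L) {
  n_glyco <- min(2L, length(protein$glycosites))
  mods <- list(
    Gla = modification_def("Gla", elemental(C = 1, O = 2),
                           max_count = length(protein$gla_sites),
                           site_class = "gla_site"),
    HexNAc = modification_def("HexNAc", elemental(C = 8, H = 13, N = 1, O = 5),
                              max_count = n_glyco, site_class = "glycosite"),
    Hex = modification_def("Hex", elemental(C = 6, H = 10, O = 5),
                           max_count = n_glyco, site_class = "glycosite"),
    NeuAc = modification_def("NeuAc", elemental(C = 11, H = 17, N = 1, O = 8),
                             max_count = 2L * n_glyco, site_class = "glycosite"),
    Oxidation = modification_def("Oxidation", elemental(O = 1),
                                 max_count = as.integer(max_oxidation),
                                 site_class = "any")
  )
  mods[vapply(mods, function(m) m$max_count > 0L, logical(1))]
}

#' Construct a proteoform composition
#'
#' Counts per modification name plus an optional unexplained residual mass,
#' the unit produced by the assignment stage.
#'
#' @param counts named non-negative integer vector (names are modification
#'   names); may be empty for the unmodified proteoform.
#' @param residual_mass unexplained mass in Da (>= 0).
#' @return An object of class `proteoform_composition`.
#' @export
proteoform_composition <- function(counts = integer(), residual_mass = 0) {
  if (length(counts) > 0L) {
    if (is.null(names(counts))) stop("counts must be named by modification")
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be non-negative integers")
    }
    counts <- counts[counts > 0]
  }
  if (residual_mass < 0) stop("residual_mass must be non-negative")
  structure(
    list(counts = structure(as.integer(counts), names = names(counts)),
         residual_mass = residual_mass),
    class = "proteoform_composition"
  )
}

#' @export
print.proteoform_composition <- function(x, ...) {
  cat(format_composition(x))
  if (x$residual_mass > 0) cat(sprintf(" [+%.4f Da residual]", x$residual_mass))
  cat("\n")
  invisible(x)
}

.count_of <- function(composition, name) {
  cnt <- composition$counts
  if (name %in% names(cnt)) cnt[[name]] else 0L
}

#' Total modification delta mass of a proteoform composition
#'
#' @param composition a `proteoform_composition`.
#' @param alphabet named list of `modification_def` (defaults to the mouse
#'   OCN alphabet masses for the standard names).
#' @param include_residual add the residual mass (default TRUE).
#' @return Delta mass in Da relative to the unmodified chain.
#' @export
composition_delta <- function(composition, alphabet,
                              include_residual = TRUE) {
  cnt <- composition$counts
  delta <- 0
  for (nm in names(cnt)) {
    if (!nm %in% names(alphabet)) stop("unknown modification: ", nm)
    delta <- delta + cnt[[nm]] * alphabet[[nm]]$mass
  }
  if (include_residual) delta <- delta + composition$residual_mass
  delta
}

.check_bounds <- function(composition, alphabet) {
  cnt <- composition$counts
  for (nm in names(cnt)) {
    if (!nm %in% names(alphabet)) stop("unknown modification: ", nm)
    if (cnt[[nm]] > alphabet[[nm]]$max_count) {
      stop(sprintf("count %d of %s exceeds bound %d", cnt[[nm]], nm,
                   alphabet[[nm]]$max_count))
    }
  }
  invisible(TRUE)
}

#' Monoisotopic mass of a modified protein
#'
#' Sum of residue masses plus one water, minus two hydrogens per formed
#' disulfide bond, plus the mass of every modification carried, plus any
#' residual mass. Disulfide bonds listed on the protein are formed by
#' default; set `disulfides = FALSE` for the reduced chain.
#'
#' @param protein a `protein_spec`.
#' @param composition a `proteoform_composition` (default: unmodified).
#' @param alphabet modification alphabet used to resolve counts; defaults to
#'   [default_alphabet()] of the protein.
#' @param disulfides logical, bonds formed (default TRUE).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(ocn_mouse(), proteoform_composition(c(Gla = 3)))
#' @export
monoisotopic_mass <- function(protein, composition = proteoform_composition(),
                              alphabet = default_alphabet(protein),
                              disulfides = TRUE) {
  .check_bounds(composition, alphabet)
  mono_mass(protein_composition(protein, disulfides = disulfides)) +
    composition_delta(composition, alphabet)
}

#' Full elemental composition of a modified proteoform
#'
#' Needed for isotope-envelope computation. Only compositions whose
#' modifications all have elemental formulas and whose residual mass is zero
#' can be rendered as envelopes.
#'
#' @inheritParams monoisotopic_mass
#' @return An `elemental` composition.
#' @export
proteoform_elemental <- function(protein, composition = proteoform_composition(),
                                 alphabet = default_alphabet(protein),
                                 disulfides = TRUE) {
  .check_bounds(composition, alphabet)
  if (composition$residual_mass != 0) {
    stop("cannot form an elemental composition with a nonzero residual mass")
  }
  out <- protein_composition(protein, disulfides = disulfides)
  for (nm in names(composition$counts)) {
    def <- alphabet[[nm]]
    if (is.null(def$composition)) {
      stop("modification ", nm, " has no elemental composition")
    }
    out <- out + elemental_times(def$composition, composition$counts[[nm]])
  }
  out
}

#' Format a proteoform composition in the field's reporting notation
#'
#' Produces strings like `"Glycosylation + 2x Gla + oxidation"`: any
#' HexNAc-initiated glycan is summarized as "Glycosylation", Gla counts are
#' written with multipliers, oxidation is spelled out. The glycan itself is
#' rendered by [format_oligosaccharide()].
#'
#' @param composition a `proteoform_composition`.
#' @return A character string; `"Unmodified"` for the empty composition.
#' @export
format_composition <- function(composition) {
  cnt <- composition$counts
  parts <- character()
  if (.count_of(composition, "HexNAc") >= 1L) parts <- c(parts, "Glycosylation")
  gla <- .count_of(composition, "Gla")
  if (gla > 0L) parts <- c(parts, sprintf("%dx Gla", gla))
  ox <- .count_of(composition, "Oxidation")
  if (ox > 0L) parts <- c(parts, if (ox == 1L) "oxidation" else sprintf("%dx oxidation", ox))
  other <- setdiff(names(cnt), c("HexNAc", "Hex", "NeuAc", "Gla", "Oxidation"))
  for (nm in other) {
    k <- cnt[[nm]]
    parts <- c(parts, if (k == 1L) nm else sprintf("%dx %s", k, nm))
  }
  if (composition$residual_mass > 0) {
    parts <- c(parts, "additional unidentified modifications or adduct ions")
  }
  if (length(parts) == 0L) "Unmodified" else paste(parts, collapse = " + ")
}

#' Format the oligosaccharide portion of a composition
#'
#' @param composition a `proteoform_composition`.
#' @return Strings like `"HexNAc, Hex, 2x NANA"`, or `"NA"` when no glycan
#'   is present.
#' @export
format_oligosaccharide <- function(composition) {
  hexnac <- .count_of(composition, "HexNAc")
  if (hexnac == 0L) return("NA")
  unit <- function(n, nm) {
    if (n == 0L) NULL else if (n == 1L) nm else sprintf("%dx %s", n, nm)
  }
  paste(c(unit(hexnac, "HexNAc"),
          unit(.count_of(composition, "Hex"), "Hex"),
          unit(.count_of(composition, "NeuAc"), "NANA")),
        collapse = ", ")
}
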