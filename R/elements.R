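## Atomic constants (monoisotopic, Da) and per-element isotope tables.
## Monoisotopic (not average) masses are required throughout: intact-protein
## deconvolution reports the monoisotopic peak, and ppm-level agreement with
## observed neutral masses is only possible on that scale.

.MONO_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740,
  O = 15.9949146,
  S = 31.9720707
)

.PROTON_MASS <- 1.007276467
.WATER_MASS <- 2 * .MONO_MASS[["H"]] + .MONO_MASS[["O"]]
.DISULFIDE_DELTA <- -2 * .MONO_MASS[["H"]]  # loss of 2 H per S-S bond

## IUPAC isotopic compositions of the elements (mass Da, abundance fraction).
.ISOTOPES <- list(
  H = data.frame(mass = c(1.0078250319, 2.0141017780),
                 abundance = c(0.999885, 0.000115)),
  C = data.frame(mass = c(12.0, 13.0033548378),
                 abundance = c(0.9893, 0.0107)),
  N = data.frame(mass = c(14.0030740052, 15.0001088984),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146221, 16.9991315, 17.9991604),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of atom counts over
#' C, H, N, O, S (additional elements may be supplied if an isotope table is
#' registered for them). Compositions are the currency of all exact-mass
#' arithmetic in the package: residues, modifications and whole proteoforms
#' are all reduced to one before a mass is computed.
#'
#' @param ... named atom counts, e.g. `elemental(C = 6, H = 12, O = 6)`, or a
#'   single named numeric vector.
#' @return An object of class `elemental` (named integer vector).
#' @examples
#' elemental(C = 1, O = 2)              # CO2, the Gla delta
#' mono_mass(elemental(C = 6, H = 10, O = 5))  # a hexose unit
#' @export
elemental <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) {
    counts <- integer(0)
  }
  if (is.null(names(counts)) && length(counts) > 0L) {
    stop("elemental counts must be named by element symbol")
  }
  if (any(counts < 0)) stop("elemental counts must be non-negative")
  if (any(counts != round(counts))) stop("elemental counts must be integers")
  counts <- counts[counts > 0]
  structure(as.integer(counts), names = names(counts), class = "elemental")
}

#' @export
print.elemental <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(x), unclass(x), collapse = " "),
        sprintf(" (%.5f Da)\n", mono_mass(x)))
  }
  invisible(x)
}

#' Combine or subtract elemental compositions
#'
#' Addition and subtraction are element-wise; subtraction that would produce
#' a negative atom count is an error.
#'
#' @param e1,e2 `elemental` objects.
#' @return An `elemental` object.
#' @export
Ops.elemental <- function(e1, e2) {
  if (!.Generic %in% c("+", "-")) {
    stop("only + and - are defined for elemental compositions")
  }
  els <- union(names(e1), names(e2))
  a <- structure(integer(length(els)), names = els)
  b <- a
  a[names(e1)] <- unclass(e1)
  b[names(e2)] <- unclass(e2)
  out <- if (.Generic == "+") a + b else a - b
  if (any(out < 0)) {
    stop("subtraction would give negative count for element(s): ",
         paste(els[out < 0], collapse = ", "))
  }
  elemental(out)
}

#' Scale an elemental composition by an integer multiplier
#'
#' @param x an `elemental` object.
#' @param n non-negative integer.
#' @return An `elemental` object with all counts multiplied by `n`.
#' @export
elemental_times <- function(x, n) {
  stopifnot(n >= 0, n == round(n))
  if (n == 0 || length(x) == 0L) return(elemental())
  elemental(structure(unclass(x) * as.integer(n), names = names(x)))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param x an `elemental` object (or named count vector).
#' @return Mass in Da; exactly 0 for the empty composition.
#' @export
mono_mass <- function(x) {
  if (length(x) == 0L) return(0)
  unknown <- setdiff(names(x), names(.MONO_MASS))
  if (length(unknown) > 0L) {
    stop("no monoisotopic mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.MONO_MASS[names(x)] * unclass(x))
}

#' Isotope distribution of an elemental composition
#'
#' Computes the isotopologue distribution of a molecule by iterated
#' convolution of the per-element isotope distributions, aggregated by
#' nominal mass offset (number of extra neutrons relative to the
#' all-lightest-isotope species). Masses reported per offset are
#' probability-weighted centroids, which is what a centroided
#' isotope-resolved spectrum shows.
#'
#' @param composition an `elemental` object; must be non-empty.
#' @param prune_threshold isotopologue probabilities below this value are
#'   dropped after each convolution step (default 0 keeps everything, so the
#'   probabilities sum to exactly 1).
#' @return A data.frame with columns `offset` (integer neutron count),
#'   `mass` (Da) and `probability`, sorted by mass.
#' @examples
#' isotope_distribution(elemental(C = 1))
#' @export
isotope_distribution <- function(composition, prune_threshold = 0) {
  if (length(composition) == 0L) stop("composition must be non-empty")
  if (prune_threshold < 0 || prune_threshold >= 1) {
    stop("prune_threshold must be in [0, 1)")
  }
  unknown <- setdiff(names(composition), names(.ISOTOPES))
  if (length(unknown) > 0L) {
    stop("no isotope table for element(s): ", paste(unknown, collapse = ", "))
  }
  dist <- NULL  # list(p = probs by offset, m = prob-weighted mass by offset)
  for (el in names(composition)) {
    tab <- .ISOTOPES[[el]]
    el_dist <- list(
      p = tab$abundance,
      m = tab$abundance * tab$mass,
      offset = round(tab$mass - tab$mass[1])
    )
    ## re-bin element distribution on a dense offset grid
    nmax <- max(el_dist$offset)
    p <- numeric(nmax + 1); m <- numeric(nmax + 1)
    p[el_dist$offset + 1] <- el_dist$p
    m[el_dist$offset + 1] <- el_dist$m
    atom <- list(p = p, m = m)
    pow <- .dist_power(atom, composition[[el]], prune_threshold)
    dist <- if (is.null(dist)) pow else .dist_convolve(dist, pow, prune_threshold)
  }
  keep <- dist$p > 0
  offsets <- which(keep) - 1L
  data.frame(
    offset = offsets,
    mass = dist$m[keep] / dist$p[keep],
    probability = dist$p[keep]
  )
}

## Convolve two (probability, mass-moment) vectors indexed by nominal offset.
## The first moment of mass convolves as m3 = m1*p2 + p1*m2 because the mass
## of a combined isotopologue is the sum of its parts.
.dist_convolve <- function(a, b, prune = 0) {
  n <- length(a$p) + length(b$p) - 1L
  p <- numeric(n); m <- numeric(n)
  for (i in seq_along(a$p)) {
    if (a$p[i] == 0) next
    idx <- i + seq_along(b$p) - 1L
    p[idx] <- p[idx] + a$p[i] * b$p
    m[idx] <- m[idx] + a$m[i] * b$p + a$p[i] * b$m
  }
  if (prune > 0) {
    drop <- p < prune
    p[drop] <- 0; m[drop] <- 0
    last <- max(which(p > 0))
    p <- p[seq_len(last)]; m <- m[seq_len(last)]
  }
  list(p = p, m = m)
}

## Exponentiation by squaring of a per-atom distribution.
.dist_power <- function(atom, n, prune = 0) {
  result <- list(p = 1, m = 0)  # empty: probability 1, mass 0
  base <- atom
  while (n > 0) {
    if (n %% 2 == 1) result <- .dist_convolve(result, base, prune)
    n <- n %/% 2
    if (n > 0) base <- .dist_convolve(base, base, prune)
  }
  result
}

#' Convert an observed m/z at known charge to a neutral monoisotopic mass
#'
#' Assumes protonation in positive mode: M = z * (m/z) - z * m_proton.
#'
#' @param mz observed mass-to-charge ratio.
#' @param z positive integer charge.
#' @return Neutral mass in Da.
#' @examples
#' deconvolve_charge(1180.95003, 5)  # the 5+ glyco + 3 Gla OCN precursor
#' @export
deconvolve_charge <- function(mz, z) {
  .check_charge(z)
  if (any(mz <= .PROTON_MASS)) stop("m/z must exceed the proton mass")
  z * mz - z * .PROTON_MASS
}

#' Convert a neutral mass to m/z at a given charge
#'
#' Exact inverse of [deconvolve_charge()].
#'
#' @param neutral_mass neutral monoisotopic mass in Da (>= 0).
#' @param z positive integer charge.
#' @return m/z of the protonated species.
#' @export
charge_mz <- function(neutral_mass, z) {
  .check_charge(z)
  if (any(neutral_mass < 0)) stop("neutral mass must be non-negative")
  (neutral_mass + z * .PROTON_MASS) / z
}

.check_charge <- function(z) {
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  invisible(TRUE)
}
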