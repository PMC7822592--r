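## Assignment of observed deconvoluted neutral masses to ranked candidate
## PTM compositions — the automated counterpart of annotating a top-down
## deconvolution table by hand.
##
## Convention: deltas are measured from the uncarboxylated, disulfide-formed
## mature chain, so "Glycosylation" with no Gla term really means zero Gla.
## Gla is an ordinary alphabet member like any other delta.

#' Enumerate modification compositions matching a target delta mass
#'
#' Bounded depth-first search over count vectors of the modification
#' alphabet, pruning branches whose residual target can no longer be reached
#' given the remaining modifications' count bounds. The ppm tolerance is
#' interpreted relative to `reference_mass` — the full proteoform mass — not
#' the (much smaller) delta, matching how instrument accuracy is quoted.
#'
#' @param target_delta target delta mass in Da.
#' @param alphabet named list of `modification_def` objects.
#' @param tolerance_ppm matching tolerance in ppm of `reference_mass`.
#' @param reference_mass full proteoform mass in Da the tolerance refers to.
#' @param core1 enforce the core-1 glycan structure: `Hex <= HexNAc` and
#'   `NeuAc <= 2 * Hex` (each GalNAc-initiated glycan extends by at most one
#'   galactose, capped by up to two sialic acids). Default TRUE.
#' @return List of `proteoform_composition` objects (unordered; see
#'   [rank_candidates()]).
#' @export
enumerate_compositions <- function(target_delta, alphabet, tolerance_ppm,
                                   reference_mass, core1 = TRUE) {
  if (length(alphabet) == 0L) stop("modification alphabet is empty")
  tol_da <- tolerance_ppm * 1e-6 * reference_mass
  .enumerate_range(target_delta - tol_da, target_delta + tol_da,
                   alphabet, core1)
}

## DFS over compositions with total delta in [lo, hi].
.enumerate_range <- function(lo, hi, alphabet, core1 = TRUE) {
  names_ <- names(alphabet)
  masses <- vapply(alphabet, function(m) m$mass, numeric(1))
  bounds <- vapply(alphabet, function(m) m$max_count, integer(1))
  if (any(masses <= 0)) stop("modification deltas must be positive")
  ## remaining reachable mass after (and including) position i
  max_tail <- rev(cumsum(rev(masses * bounds)))
  results <- list()
  counts <- integer(length(names_))
  recurse <- function(i, acc) {
    if (acc > hi + 1e-12) return()
    if (i > length(names_)) {
      if (acc >= lo - 1e-12) {
        cnt <- counts
        names(cnt) <- names_
        if (!core1 || .core1_ok(cnt)) {
          results[[length(results) + 1L]] <<- proteoform_composition(cnt)
        }
      }
      return()
    }
    if (acc + max_tail[i] < lo - 1e-12) return()  # can't reach target any more
    for (k in 0:bounds[i]) {
      counts[i] <<- k
      recurse(i + 1L, acc + k * masses[i])
    }
    counts[i] <<- 0L
  }
  recurse(1L, 0)
  results
}

.core1_ok <- function(cnt) {
  g <- function(nm) if (nm %in% names(cnt)) cnt[[nm]] else 0L
  g("Hex") <= g("HexNAc") && g("NeuAc") <= 2L * g("Hex")
}

#' Rank candidate compositions
#'
#' Parsimony-first stable ordering: fewest total modification copies, then
#' smallest absolute ppm error, then lexicographic composition key — so the
#' top-ranked candidate is deterministic across runs even under exact ties.
#'
#' @param candidates list of `proteoform_composition`.
#' @param ppm_errors numeric vector of signed ppm errors, same length.
#' @return List with elements `candidates` and `ppm_errors`, reordered.
#' @export
rank_candidates <- function(candidates, ppm_errors) {
  if (length(candidates) == 0L) stop("no candidates to rank")
  if (length(candidates) != length(ppm_errors)) {
    stop("candidates and ppm_errors differ in length")
  }
  total <- vapply(candidates, function(x) sum(x$counts), integer(1))
  key <- vapply(candidates, .composition_key, character(1))
  ord <- order(total, abs(ppm_errors), key)
  list(candidates = candidates[ord], ppm_errors = ppm_errors[ord])
}

.composition_key <- function(composition) {
  cnt <- composition$counts
  if (length(cnt) == 0L) return("")
  nm <- sort(names(cnt))
  paste(sprintf("%s:%d", nm, cnt[nm]), collapse = ",")
}

#' Assign observed neutral masses to proteoform compositions
#'
#' For each observation the delta from the base mass (uncarboxylated,
#' disulfide-formed chain) is matched against the modification alphabet:
#'
#' * `exact` — at least one composition lies within `tolerance_ppm` of the
#'   observation; candidates are ranked parsimony-first.
#' * `residual` — no exact match, but some composition leaves a leftover of
#'   at most `residual_window` Da above it; the largest-mass such
#'   composition anchors the assignment and the leftover is reported as
#'   residual mass (this is how ranges of partially explained adduct-bearing
#'   forms are represented, not resolved).
#' * `unassigned` — neither applies, including observations below the base
#'   mass beyond tolerance (flagged as negative delta).
#'
#' @param observations data.frame with column `neutral_mass_da` and optional
#'   `relative_abundance_pct` and `label` (see [read_peaklist()]), or a bare
#'   numeric vector of neutral masses.
#' @param protein a `protein_spec` (validated against its mass anchor).
#' @param alphabet modification alphabet; default [default_alphabet()].
#' @param tolerance_ppm matching tolerance (default 10 ppm, wide enough to
#'   admit the observed spread of intact-mass calibration).
#' @param residual_window maximum unexplained leftover in Da (default 250).
#' @param core1 enforce core-1 glycan structure (default TRUE).
#' @return An object of class `assignment_set`: a list of assignments, each
#'   with `observation`, `status`, `candidates`, `ppm_errors`,
#'   `negative_delta`. Convert with `as.data.frame()`.
#' @examples
#' a <- assign_masses(c(5767.6961, 6146.7609), ocn_mouse())
#' as.data.frame(a)
#' @export
assign_masses <- function(observations, protein,
                          alphabet = default_alphabet(protein),
                          tolerance_ppm = 10, residual_window = 250,
                          core1 = TRUE) {
  obs <- .as_observations(observations)
  base <- monoisotopic_mass(protein)
  out <- lapply(seq_len(nrow(obs)), function(i) {
    .assign_one(obs[i, ], base, alphabet, tolerance_ppm, residual_window, core1)
  })
  structure(out, class = "assignment_set",
            base_mass = base, protein_id = protein$id,
            tolerance_ppm = tolerance_ppm)
}

.as_observations <- function(observations) {
  if (is.numeric(observations)) {
    observations <- data.frame(neutral_mass_da = observations)
  }
  if (!"neutral_mass_da" %in% names(observations)) {
    stop("observations need a 'neutral_mass_da' column")
  }
  if (any(observations$neutral_mass_da <= 0)) {
    stop("neutral masses must be positive")
  }
  if (!"relative_abundance_pct" %in% names(observations)) {
    observations$relative_abundance_pct <- NA_real_
  }
  ra <- observations$relative_abundance_pct
  if (any(!is.na(ra) & (ra < 0 | ra > 100))) {
    stop("relative abundances must lie in [0, 100]")
  }
  if (!"label" %in% names(observations)) {
    observations$label <- sprintf("obs_%02d", seq_len(nrow(observations)))
  }
  observations
}

.assign_one <- function(obs, base, alphabet, tolerance_ppm, residual_window,
                        core1) {
  mass <- obs$neutral_mass_da
  delta <- mass - base
  tol_da <- tolerance_ppm * 1e-6 * mass
  res <- list(
    observation = list(neutral_mass = mass,
                       relative_abundance = obs$relative_abundance_pct,
                       label = obs$label),
    status = "unassigned", candidates = list(), ppm_errors = numeric(),
    negative_delta = FALSE
  )
  if (delta < -tol_da) {
    res$negative_delta <- TRUE
    return(res)
  }
  exact <- enumerate_compositions(delta, alphabet, tolerance_ppm, mass,
                                  core1 = core1)
  if (length(exact) > 0L) {
    ppm <- vapply(exact, function(cc) {
      (mass - (base + composition_delta(cc, alphabet))) / mass * 1e6
    }, numeric(1))
    ranked <- rank_candidates(exact, ppm)
    res$status <- "exact"
    res$candidates <- ranked$candidates
    res$ppm_errors <- ranked$ppm_errors
    return(res)
  }
  ## residual: largest-mass composition leaving 0 <= leftover <= window
  anchors <- .enumerate_range(max(0, delta - residual_window), delta,
                              alphabet, core1)
  if (length(anchors) > 0L) {
    amass <- vapply(anchors, function(cc) composition_delta(cc, alphabet),
                    numeric(1))
    best_mass <- max(amass)
    at_best <- which(abs(amass - best_mass) < 1e-9)
    best <- if (length(at_best) > 1L) {
      rank_candidates(anchors[at_best], rep(0, length(at_best)))$candidates[[1L]]
    } else {
      anchors[[at_best]]
    }
    best$residual_mass <- delta - best_mass
    res$status <- "residual"
    res$candidates <- list(best)
    res$ppm_errors <- NA_real_
    return(res)
  }
  res
}

#' @export
print.assignment_set <- function(x, ...) {
  cat(sprintf("assignment_set: %d observation(s) against %s (base %.4f Da, %g ppm)\n",
              length(x), attr(x, "protein_id"), attr(x, "base_mass"),
              attr(x, "tolerance_ppm")))
  print(as.data.frame(x))
  invisible(x)
}

#' Tabulate an assignment set
#'
#' @param x an `assignment_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with one row per observation: label, neutral mass,
#'   relative abundance, status, rank-1 composition in reporting notation,
#'   oligosaccharide, signed ppm error, residual mass and candidate count.
#' @export
as.data.frame.assignment_set <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  rows <- lapply(x, function(a) {
    top <- if (length(a$candidates) > 0L) a$candidates[[1L]] else NULL
    data.frame(
      label = a$observation$label,
      neutral_mass_da = a$observation$neutral_mass,
      relative_abundance_pct = a$observation$relative_abundance,
      status = a$status,
      composition = if (is.null(top)) NA_character_ else format_composition(top),
      oligosaccharide = if (is.null(top)) NA_character_ else format_oligosaccharide(top),
      ppm_error = if (length(a$ppm_errors) > 0L) a$ppm_errors[1L] else NA_real_,
      residual_mass_da = if (is.null(top)) NA_real_ else top$residual_mass,
      n_candidates = length(a$candidates),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
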