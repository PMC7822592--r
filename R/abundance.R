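## Proteoform-class ledgers: classify assignments and aggregate relative
## abundances (glycosylated vs not, by oligosaccharide, by Gla count, by
## number of glycan adducts).

.GROUPINGS <- c("glyco_vs_not", "by_oligosaccharide", "by_gla_count",
                "by_glycan_multiplicity")

#' Classify one assignment into a proteoform class
#'
#' The rank-1 candidate determines the class. A form counts as glycosylated
#' iff it carries at least one HexNAc (the initiating GalNAc of a mucin-type
#' O-glycan). Unassigned observations are routed to class `"unassigned"`.
#'
#' @param assignment one element of an `assignment_set`.
#' @param grouping one of `"glyco_vs_not"`, `"by_oligosaccharide"`,
#'   `"by_gla_count"`, `"by_glycan_multiplicity"`.
#' @return Class label string.
#' @export
classify <- function(assignment, grouping = "glyco_vs_not") {
  grouping <- match.arg(grouping, .GROUPINGS)
  if (length(assignment$candidates) == 0L) return("unassigned")
  top <- assignment$candidates[[1L]]
  switch(grouping,
    glyco_vs_not = if (.count_of(top, "HexNAc") >= 1L) "glycosylated" else "non-glycosylated",
    by_oligosaccharide = format_oligosaccharide(top),
    by_gla_count = sprintf("%dx Gla", .count_of(top, "Gla")),
    by_glycan_multiplicity = sprintf("%d glycan(s)", .count_of(top, "HexNAc"))
  )
}

#' Aggregate relative abundances by proteoform class
#'
#' Sums the observation-level relative abundances within each class; output
#' is sorted by descending abundance. Totals are conserved exactly: the sum
#' over classes equals the sum of the input abundances.
#'
#' @param assignments an `assignment_set` whose observations carry relative
#'   abundances.
#' @param grouping see [classify()].
#' @param drop_unassigned exclude unassigned observations from the table
#'   (and hence the denominator); default FALSE.
#' @return data.frame with columns `class_label`, `relative_abundance`.
#' @examples
#' tab3 <- read_peaklist(system.file("extdata", "table3_bone_homogenate.tsv",
#'                                   package = "ocnforms"))
#' aggregate_abundance(assign_masses(tab3, ocn_mouse()))
#' @export
aggregate_abundance <- function(assignments, grouping = "glyco_vs_not",
                                drop_unassigned = FALSE) {
  grouping <- match.arg(grouping, .GROUPINGS)
  ra <- vapply(assignments, function(a) a$observation$relative_abundance,
               numeric(1))
  if (any(is.na(ra))) {
    bad <- vapply(assignments, function(a) a$observation$label, character(1))[is.na(ra)]
    stop("missing relative abundance for observation(s): ",
         paste(bad, collapse = ", "))
  }
  labels <- vapply(assignments, classify, character(1), grouping = grouping)
  if (drop_unassigned) {
    keep <- labels != "unassigned"
    labels <- labels[keep]; ra <- ra[keep]
  }
  sums <- tapply(ra, labels, sum)
  out <- data.frame(class_label = names(sums),
                    relative_abundance = as.numeric(sums),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$relative_abundance, out$class_label), ]
  rownames(out) <- NULL
  out
}

#' Glycosylated and two-adduct fractions of a proteoform mixture
#'
#' Intensity-weighted fraction of forms carrying at least one glycan, and —
#' conditional on being glycosylated — the fraction carrying two glycan
#' adducts (two HexNAc-initiated chains). This is the summary used to
#' characterize purified protein preparations, e.g. ">99% glycosylated,
#' ~30% with two adducts".
#'
#' @param assignments an `assignment_set` with abundances/intensities.
#' @return List with `fraction_glycosylated`, `fraction_two_adducts` (0 with
#'   `no_glyco = TRUE` when nothing is glycosylated) and `no_glyco` flag.
#' @export
glyco_fraction <- function(assignments) {
  ra <- vapply(assignments, function(a) a$observation$relative_abundance,
               numeric(1))
  if (any(is.na(ra))) stop("all observations need an abundance/intensity")
  total <- sum(ra)
  if (total <= 0) stop("total intensity is zero")
  n_glycan <- vapply(assignments, function(a) {
    if (length(a$candidates) == 0L) 0L else .count_of(a$candidates[[1L]], "HexNAc")
  }, integer(1))
  w_glyco <- sum(ra[n_glycan >= 1L])
  if (w_glyco == 0) {
    return(list(fraction_glycosylated = 0, fraction_two_adducts = 0,
                no_glyco = TRUE))
  }
  list(
    fraction_glycosylated = w_glyco / total,
    fraction_two_adducts = sum(ra[n_glycan >= 2L]) / w_glyco,
    no_glyco = FALSE
  )
}
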