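## Readers and writers: FASTA + sidecar site config for proteins, TSV/CSV
## peak lists and time courses, assignment/estimate tables. All writers use
## full-precision period-decimal TSV and round-trip losslessly with the
## readers.

#' Read a protein spec from FASTA plus a sidecar site configuration
#'
#' The FASTA supplies the mature-chain residues; the YAML sidecar supplies
#' what FASTA cannot carry: disulfide pairs, carboxylation-eligible
#' glutamate positions and candidate glycosites, e.g.
#'
#' ```yaml
#' disulfide_bonds: [[19, 25]]
#' gla_sites: [13, 17, 20]
#' glycosites: [5, 8, 15]
#' anchor_mass_da: 5243.45      # optional: verified when verify_anchor=TRUE
#' anchor_gla_count: 3
#' ```
#'
#' @param fasta_path path to a FASTA file (first record used).
#' @param sidecar_path path to the YAML sidecar.
#' @param verify_anchor if TRUE and the sidecar carries `anchor_mass_da`,
#'   check that the chain with `anchor_gla_count` Gla and formed disulfides
#'   reproduces it within `anchor_tol_da`.
#' @param anchor_tol_da anchor tolerance in Da (default 0.05).
#' @return A validated `protein_spec`.
#' @examples
#' fa <- system.file("extdata", "ocn_mouse.fasta", package = "ocnforms")
#' yml <- system.file("extdata", "ocn_mouse.yml", package = "ocnforms")
#' read_protein(fa, yml, verify_anchor = TRUE)
#' @export
read_protein <- function(fasta_path, sidecar_path, verify_anchor = FALSE,
                         anchor_tol_da = 0.05) {
  fa <- .read_fasta(fasta_path)
  side <- yaml::read_yaml(sidecar_path)
  spec <- protein_spec(
    id = fa$id,
    residues = fa$seq,
    disulfide_bonds = lapply(side$disulfide_bonds %||% list(), as.integer),
    gla_sites = as.integer(unlist(side$gla_sites %||% integer())),
    glycosites = as.integer(unlist(side$glycosites %||% integer()))
  )
  if (verify_anchor) {
    if (is.null(side$anchor_mass_da)) {
      stop("sidecar has no anchor_mass_da to verify against")
    }
    gla <- as.integer(side$anchor_gla_count %||% 0L)
    got <- monoisotopic_mass(spec, proteoform_composition(c(Gla = gla)))
    if (abs(got - side$anchor_mass_da) > anchor_tol_da) {
      stop(sprintf("anchor check failed: computed %.4f Da vs expected %.4f Da (tol %.3f)",
                   got, side$anchor_mass_da, anchor_tol_da))
    }
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(recs) == 0L) stop("malformed FASTA: no records in ", path)
  list(id = names(recs)[1], seq = as.character(recs[[1]]))
}

.read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          comment.char = "#")
  if (nrow(df) == 0L) stop("no records in ", what, " file: ", path)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read a deconvoluted peak list
#'
#' TSV or CSV with required column `neutral_mass_da` and optional
#' `relative_abundance_pct` and `label`; further columns pass through.
#'
#' @param path file path (`.csv` implies comma, anything else tab).
#' @return data.frame of observations.
#' @export
read_peaklist <- function(path) {
  .read_table_checked(path, "neutral_mass_da", "peak list")
}

#' Read a concentration time course
#'
#' TSV or CSV with required columns `time_min`, `conc_ng_ml`,
#' `replicate_id`; an optional `condition` column splits the file into one
#' curve per condition.
#'
#' @param path file path.
#' @param baseline_time T0 for normalization (default 0 min).
#' @return A `decay_curve`, or a named list of them if `condition` is
#'   present with more than one level.
#' @export
read_timecourse <- function(path, baseline_time = 0) {
  df <- .read_table_checked(path, c("time_min", "conc_ng_ml", "replicate_id"),
                            "time course")
  if ("condition" %in% names(df) && length(unique(df$condition)) > 1L) {
    lapply(split(df, df$condition), decay_curve, baseline_time = baseline_time)
  } else {
    decay_curve(df, baseline_time = baseline_time)
  }
}

#' Write an assignment table
#'
#' @param assignments an `assignment_set`.
#' @param path output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  df <- as.data.frame(assignments)
  .write_tsv(df, path)
}

#' Write a table of half-life estimates
#'
#' @param estimates named list of `half_life_estimate` objects (names are
#'   analyte/condition labels).
#' @param path output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(label = nm, t_half_min = e$t_half, rate_k_per_min = e$rate_k,
               ci_low_min = e$ci_low, ci_high_min = e$ci_high,
               method = e$method, mode = e$mode,
               n_replicates = e$n_replicates, stable = e$stable,
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Emit the packaged fixtures and demo time courses into a directory
#'
#' Copies the transcribed proteoform abundance tables and protein specs, and
#' generates seeded demo decay curves (an ex vivo 120-min half-life design
#' and an in vivo 30-min-peak, 108-min declining-phase design).
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the demo time courses.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pkg_files <- c("table2_osteoblast_supernatant.tsv",
                 "table3_bone_homogenate.tsv",
                 "ocn_mouse.fasta", "ocn_mouse.yml",
                 "ocn_human.fasta", "ocn_human.yml")
  written <- character()
  for (f in pkg_files) {
    src <- system.file("extdata", f, package = "ocnforms")
    dst <- file.path(dir, f)
    file.copy(src, dst, overwrite = TRUE)
    written <- c(written, dst)
  }
  exvivo <- simulate_decay(decay_truth(t_half = 120, seed = seed))
  path1 <- file.path(dir, "demo_exvivo_timecourse.tsv")
  .write_tsv(exvivo$records, path1)
  invivo <- simulate_decay(decay_truth(
    t_half = 108, sample_times = c(15, 30, 60, 90, 120), n_replicates = 5L,
    peak_time = 30, seed = seed + 1L))
  path2 <- file.path(dir, "demo_invivo_timecourse.tsv")
  .write_tsv(invivo$records, path2)
  invisible(c(written, path1, path2))
}
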