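test_that("glycan delta targets enumerate to their oracle-derived sets", {
  # mono-sialylated core-1 glycan delta; brute force also admits the
  # near-degenerate two-site {2 HexNAc + Hex + 2 Gla} (36 mDa away), which
  # parsimony ranking demotes below the true glycan
  out <- enumerate_compositions(656.2276, mouse_alphabet, 10, 5767.7)
  expect_equal(composition_keys(out),
               c("Gla:2,Hex:1,HexNAc:2", "Hex:1,HexNAc:1,NeuAc:1"))
  ppm <- rep(0, length(out))
  expect_equal(composition_keys(rank_candidates(out, ppm)$candidates[1]),
               "Hex:1,HexNAc:1,NeuAc:1")
  # di-sialylated: same structure one NeuAc up
  out2 <- enumerate_compositions(947.3230, mouse_alphabet, 10, 6058.8)
  expect_equal(composition_keys(out2),
               c("Gla:2,Hex:1,HexNAc:2,NeuAc:1", "Hex:1,HexNAc:1,NeuAc:2"))
  expect_equal(composition_keys(rank_candidates(out2, rep(0, 2))$candidates[1]),
               "Hex:1,HexNAc:1,NeuAc:2")
  # zero delta admits only the empty composition
  out0 <- enumerate_compositions(0, mouse_alphabet, 10, 5767.7)
  expect_equal(composition_keys(out0), "")
  expect_error(enumerate_compositions(10, list(), 10, 5000), "empty")
})

test_that("depth-first enumeration equals brute-force Cartesian product", {
  alpha <- mouse_alphabet
  max_delta <- sum(vapply(alpha, function(m) m$mass * m$max_count, numeric(1)))
  set.seed(202)
  for (core1 in c(TRUE, FALSE)) {
    targets <- runif(60, 0, max_delta)
    for (target in targets) {
      tol_da <- 10 * 1e-6 * 6000
      got <- composition_keys(
        enumerate_compositions(target, alpha, 10, 6000, core1 = core1))
      want <- oracle_enumerate(target, alpha, tol_da, core1 = core1)
      expect_identical(got, want)
    }
  }
})

test_that("candidate sets grow monotonically with tolerance", {
  set.seed(7)
  targets <- runif(25, 0, 1000)
  for (target in targets) {
    narrow <- composition_keys(
      enumerate_compositions(target, mouse_alphabet, 5, 6000))
    wide <- composition_keys(
      enumerate_compositions(target, mouse_alphabet, 25, 6000))
    expect_true(all(narrow %in% wide))
  }
})

test_that("ranking is parsimony-first, then |ppm|, then deterministic", {
  c3 <- proteoform_composition(c(Gla = 3))
  c5 <- proteoform_composition(c(Gla = 3, Oxidation = 2))
  r <- rank_candidates(list(c5, c3), c(0.1, 9.9))
  expect_equal(sum(r$candidates[[1]]$counts), 3L)
  # equal counts: smaller |ppm| first
  r2 <- rank_candidates(list(c3, c3), c(4.8, -1.2))
  expect_equal(r2$ppm_errors, c(-1.2, 4.8))
  # full tie: lexicographic composition key, stable across repeated calls
  a <- proteoform_composition(c(HexNAc = 1))
  b <- proteoform_composition(c(Gla = 1))
  r3 <- rank_candidates(list(a, b), c(1, 1))
  r4 <- rank_candidates(list(b, a), c(1, 1))
  expect_equal(names(r3$candidates[[1]]$counts), "Gla")
  expect_identical(composition_keys(r3$candidates),
                   composition_keys(r4$candidates))
})

test_that("observed supernatant masses get their annotated compositions", {
  asg <- assign_masses(c(5767.6961, 6146.7609), mouse_protein)
  df <- as.data.frame(asg)
  expect_equal(df$status, c("exact", "exact"))
  top1 <- asg[[1]]$candidates[[1]]$counts
  expect_equal(top1[["HexNAc"]], 1L)
  expect_equal(top1[["Hex"]], 1L)
  expect_equal(top1[["NeuAc"]], 1L)
  expect_false("Gla" %in% names(top1))  # "Glycosylation" alone means 0 Gla
  top2 <- asg[[2]]$candidates[[1]]$counts
  expect_equal(top2[["NeuAc"]], 2L)
  expect_equal(top2[["Gla"]], 2L)
})

test_that("the base mass itself is an exact, empty assignment", {
  base <- monoisotopic_mass(mouse_protein)
  asg <- assign_masses(base, mouse_protein)
  expect_equal(asg[[1]]$status, "exact")
  expect_length(asg[[1]]$candidates[[1]]$counts, 0L)
  expect_equal(asg[[1]]$ppm_errors[1], 0, tolerance = 1e-9)
})

test_that("partially explained masses fall back to an anchored residual", {
  # upper end of an adduct-bearing range: no exact composition within 10 ppm
  asg <- assign_masses(5968.5796, mouse_protein)
  a <- asg[[1]]
  expect_equal(a$status, "residual")
  anchor <- a$candidates[[1]]
  expect_gte(anchor$counts[["HexNAc"]], 1L)  # stays in the glycosylated class
  expect_gt(anchor$residual_mass, 0)
  expect_lte(anchor$residual_mass, 250)
  # brute force confirms no exact composition exists at 10 ppm
  delta <- 5968.5796 - monoisotopic_mass(mouse_protein)
  expect_length(oracle_enumerate(delta, mouse_alphabet, 10e-6 * 5968.5796), 0L)
  # and that the anchor is the largest-mass composition inside the window
  window_keys <- oracle_enumerate(delta - 125, mouse_alphabet, 125)
  anchor_delta <- delta - anchor$residual_mass
  alpha_mass <- vapply(mouse_alphabet, function(m) m$mass, numeric(1))
  key_mass <- function(key) {
    if (!nzchar(key)) return(0)
    parts <- strsplit(strsplit(key, ",")[[1]], ":")
    sum(vapply(parts, function(p) alpha_mass[[p[1]]] * as.integer(p[2]),
               numeric(1)))
  }
  expect_equal(anchor_delta, max(vapply(window_keys, key_mass, numeric(1))),
               tolerance = 1e-9)
})

test_that("residual assignments are monotone in the window size", {
  obs <- c(5968.5796, 6441.7636)
  narrow <- as.data.frame(assign_masses(obs, mouse_protein, residual_window = 40))
  wide <- as.data.frame(assign_masses(obs, mouse_protein, residual_window = 250))
  assigned <- function(df) df$label[df$status != "unassigned"]
  expect_true(all(assigned(narrow) %in% assigned(wide)))
})

test_that("masses below the base beyond tolerance are flagged unassigned", {
  asg <- assign_masses(4000, mouse_protein)
  expect_equal(asg[[1]]$status, "unassigned")
  expect_true(asg[[1]]$negative_delta)
})

test_that("zero-noise synthetic mixtures are recovered exactly at rank 1", {
  truth <- bone_like_mixture(ppm_noise_sd = 0, abundance_noise_cv = 0, seed = 5)
  obs <- simulate_mass_list(truth, mouse_protein)
  asg <- assign_masses(obs, mouse_protein)
  for (i in seq_along(asg)) {
    expect_equal(asg[[i]]$status, "exact")
    expect_identical(composition_keys(asg[[i]]$candidates[1]),
                     composition_keys(truth$components[i]))
    expect_equal(asg[[i]]$ppm_errors[1], 0, tolerance = 1e-6)
  }
})

test_that("recovery degrades gracefully with ppm mass noise", {
  rate_at <- function(ppm_sd) {
    hits <- 0L; total <- 0L
    for (seed in 1:20) {
      truth <- bone_like_mixture(ppm_noise_sd = ppm_sd, seed = seed)
      obs <- simulate_mass_list(truth, mouse_protein)
      asg <- assign_masses(obs, mouse_protein)
      for (i in seq_along(asg)) {
        total <- total + 1L
        ok <- asg[[i]]$status == "exact" &&
          identical(composition_keys(asg[[i]]$candidates[1]),
                    composition_keys(truth$components[i]))
        hits <- hits + ok
      }
    }
    hits / total
  }
  r0 <- rate_at(0); r2 <- rate_at(2); r10 <- rate_at(10)
  expect_equal(r0, 1)
  expect_gte(r2, r10)
  expect_gt(r2, 0.9)  # 2 ppm noise against a 10 ppm gate barely misses
})

test_that("printed proteoform tables are reproduced row by row at 10 ppm", {
  for (fix in c("table2_osteoblast_supernatant.tsv",
                "table3_bone_homogenate.tsv")) {
    tab <- read_peaklist(fixture_path(fix))
    asg <- assign_masses(tab, mouse_protein, tolerance_ppm = 10)
    df <- as.data.frame(asg)
    single <- is.na(tab$mass_range_high_da)
    # single-valued rows: annotation and oligosaccharide match exactly
    expect_equal(tolower(df$composition[single]),
                 tolower(tab$reported_modification[single]))
    want_oligo <- tab$reported_oligosaccharide[single]
    want_oligo[is.na(want_oligo)] <- "NA"  # read.table eats the literal "NA"
    expect_equal(df$oligosaccharide[single], want_oligo)
    expect_true(all(abs(df$ppm_error[single]) <= 10))
    expect_true(all(df$status != "unassigned"))
  }
})
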