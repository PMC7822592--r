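# Independent oracles and shared fixtures for the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force composition enumeration: full Cartesian product over count
# vectors, no pruning, no recursion — deliberately naive so it cannot share
# a bug with the package's depth-first search.
oracle_enumerate <- function(target, alphabet, tol_da, core1 = TRUE) {
  grid <- expand.grid(lapply(alphabet, function(m) 0:m$max_count),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(alphabet)
  masses <- as.matrix(grid) %*% vapply(alphabet, function(m) m$mass, numeric(1))
  keep <- abs(masses - target) <= tol_da
  if (core1) {
    g <- function(nm) if (nm %in% names(grid)) grid[[nm]] else 0L
    keep <- keep & (g("Hex") <= g("HexNAc")) & (g("NeuAc") <= 2L * g("Hex"))
  }
  out <- character(0)
  for (i in which(keep)) {
    cnt <- unlist(grid[i, , drop = FALSE])
    cnt <- cnt[cnt > 0]
    key <- if (length(cnt) == 0L) "" else {
      nm <- sort(names(cnt))
      paste(sprintf("%s:%d", nm, cnt[nm]), collapse = ",")
    }
    out <- c(out, key)
  }
  sort(out)
}

composition_keys <- function(compositions) {
  sort(vapply(compositions, function(cc) {
    cnt <- cc$counts
    if (length(cnt) == 0L) return("")
    nm <- sort(names(cnt))
    paste(sprintf("%s:%d", nm, cnt[nm]), collapse = ",")
  }, character(1)))
}

mouse_protein <- ocn_mouse()
mouse_alphabet <- default_alphabet(mouse_protein)

fixture_path <- function(name) {
  system.file("extdata", name, package = "ocnforms")
}

# Closed-form oracle for decay sampling (independent of simulate_decay).
expected_conc <- function(t, t_half, C0 = 100, peak_time = 0) {
  ifelse(peak_time > 0 & t < peak_time,
         C0 * t / peak_time,
         C0 * 2^(-(t - max(peak_time, 0)) / t_half))
}
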