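# Shared fixtures and independent oracles for the test suite.

# Brute-force modified-cosine oracle: enumerates every one-to-one matching
# over the candidate peak pairs (direct or precursor-shifted) and returns
# the maximum summed product of L2-normalized weights. Written as plain
# recursion over the pair list, independent of the package's assignment
# solver.
oracle_modified_cosine <- function(a, b, fragment_tol = 0.05, precursor_tol = 0.02) {
  wa <- a$intensity / sqrt(sum(a$intensity^2))
  wb <- b$intensity / sqrt(sum(b$intensity^2))
  shift <- a$precursor_mz - b$precursor_mz
  use_shift <- abs(shift) > precursor_tol
  pairs <- list()
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      hit <- abs(a$mz[i] - b$mz[j]) <= fragment_tol
      if (use_shift) hit <- hit || abs(a$mz[i] - b$mz[j] - shift) <= fragment_tol
      if (hit) pairs[[length(pairs) + 1L]] <- c(i, j, wa[i] * wb[j])
    }
  }
  best <- list(score = 0, n = 0L)
  recurse <- function(k, used_i, used_j, score, n) {
    if (score > best$score) best <<- list(score = score, n = n)
    if (k > length(pairs)) return(invisible(NULL))
    recurse(k + 1L, used_i, used_j, score, n)  # skip pair k
    p <- pairs[[k]]
    if (!(p[1] %in% used_i) && !(p[2] %in% used_j)) {
      recurse(k + 1L, c(used_i, p[1]), c(used_j, p[2]), score + p[3], n + 1L)
    }
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  best
}

# Random small spectrum drawing some peaks from a shared m/z pool so that
# spectrum pairs have non-trivial similarity structure.
random_spectrum <- function(id, pool, n_peaks, polarity = "positive") {
  n_shared <- sample.int(n_peaks, 1L)
  mz <- c(sample(pool, n_shared),
          runif(n_peaks - n_shared, 100, 900))
  mz <- mz + rnorm(n_peaks, 0, 0.01)
  ms2_spectrum(id, runif(1, 400, 900), polarity, rt = runif(1, 1, 30),
               mz = mz, intensity = runif(n_peaks, 10, 100))
}

# The m/z values quoted for diagnostic fragments in the lipid
# fragmentation descriptions, paired with their ion formulas.
quoted_fragment_manifest <- function() {
  rbind(
    data.frame(formula = "C9H20O11P",  charge = +1, printed = 335.0738),
    data.frame(formula = "C6H14O9P",   charge = +1, printed = 261.0370),
    data.frame(formula = "C6H16O8P",   charge = +1, printed = 247.0577),
    data.frame(formula = "C3H10O6P",   charge = +1, printed = 173.0210),
    data.frame(formula = "C6H15NO8P",  charge = +1, printed = 260.0530),
    data.frame(formula = "C3H8NO3",    charge = +1, printed = 106.0503),
    data.frame(formula = "C3H6NO2",    charge = +1, printed = 88.0393),
    data.frame(formula = "C5H15NO4P",  charge = +1, printed = 184.0733),
    data.frame(formula = "C5H14NO",    charge = +1, printed = 104.1070),
    data.frame(formula = "C8H21NO6P",  charge = +1, printed = 258.1101),
    data.frame(formula = "C21H42O6P",  charge = +1, printed = 421.2714),
    data.frame(formula = "C6H12O9P",   charge = -1, printed = 259.0224),
    data.frame(formula = "C9H18O11P",  charge = -1, printed = 333.0592),
    data.frame(formula = "C9H16O10P",  charge = -1, printed = 315.0487),
    data.frame(formula = "C3H8O6P",    charge = -1, printed = 171.0064),
    data.frame(formula = "C3H6O5P",    charge = -1, printed = 152.9958),
    data.frame(formula = "C6H14O8P",   charge = -1, printed = 245.0432),
    data.frame(formula = "C5H13NO6P",  charge = -1, printed = 214.0486),
    data.frame(formula = "C2H7NO4P",   charge = -1, printed = 140.0118),
    data.frame(formula = "H2O4P",      charge = -1, printed = 96.9696),
    data.frame(formula = "C6H10O8P",   charge = -1, printed = 241.0119),
    data.frame(formula = "C18H35O2",   charge = -1, printed = 283.2643),
    data.frame(formula = "C21H42O7P",  charge = -1, printed = 437.2674)
  )
}

# Formula strings appearing anywhere in a rule (all item groups).
rule_formulas <- function(rule) {
  vapply(c(rule$required, rule$supporting, rule$chain_release),
         function(it) it$formula, character(1))
}
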