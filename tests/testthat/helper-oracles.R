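# Independent oracles and small generators used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force duplex mass: accumulate per-base-pair masses nucleotide by
# nucleotide along the given strand.
brute_force_mw <- function(sequence, constants = mass_constants()) {
  ch <- strsplit(sequence, "")[[1]]
  total <- constants$end_correction
  for (c in ch) {
    total <- total + if (c %in% c("A", "T")) constants$mass_at_pair else
      constants$mass_gc_pair
  }
  total
}

# Exhaustive cross-dimer oracle for short ACGT primers: every antiparallel
# diagonal, every contiguous window, all positions must pair.
.comp <- c(A = "T", C = "G", G = "C", T = "A")
brute_force_dimer <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  best <- 0L
  for (d in 2L:(na + nb)) {
    is <- max(1L, d - nb):min(na, d - 1L)
    for (s in seq_along(is)) {
      for (e in s:length(is)) {
        win <- is[s:e]
        if (all(.comp[ca[win]] == cb[d - win])) {
          best <- max(best, length(win))
        }
      }
    }
  }
  best
}

# Fewest integer factors (2..fmax) whose product is ratio; NA if impossible.
min_integer_steps <- function(ratio, fmax = 10L) {
  best <- Inf
  recurse <- function(rem, count, last) {
    if (count >= best) return()
    if (rem == 1L) {
      best <<- min(best, count)
      return()
    }
    for (f in seq(min(fmax, rem, last), 2L)) {
      if (rem %% f == 0L) recurse(rem %/% f, count + 1L, f)
    }
  }
  recurse(as.integer(ratio), 0L, fmax)
  if (is.finite(best)) best else NA_integer_
}

fixture_dir <- function(seed = 1L) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  generate_fixture(d, seed = seed)
}
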