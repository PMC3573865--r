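# Allawi & SantaLucia (1997) unified nearest-neighbour parameters.
# dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide on one strand.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.nn_init <- list(AT = c(dh = 2.3, ds = 4.1), GC = c(dh = 0.1, ds = -2.8))

tm_wallace_one <- function(s) {
  ch <- seq_chars(s)
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

tm_nn_one <- function(s, na_molar, primer_molar) {
  ch <- seq_chars(s)
  n <- length(ch)
  dinuc <- paste0(ch[-n], ch[-1L])
  dh <- sum(.nn_dh[dinuc])
  ds <- sum(.nn_ds[dinuc])
  for (end in c(ch[1L], ch[n])) {
    ini <- if (end %in% c("A", "T")) .nn_init$AT else .nn_init$GC
    dh <- dh + ini[["dh"]]
    ds <- ds + ini[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)   # entropic salt correction
  # non-self-complementary duplex: symmetry factor CT/4
  dh * 1000 / (ds + 1.987 * log(primer_molar / 4)) - 273.15
}

#' Oligonucleotide melting temperature (Wallace or nearest-neighbour)
#'
#' Two estimators are offered. `wallace` is the bench rule
#' `Tm = 2(A+T) + 4(G+C)` degrees C — crude, but transparent and adequate for
#' checking that a panel's primers are mutually balanced. `nearest_neighbor`
#' sums the Allawi & SantaLucia (1997) unified dinucleotide stacking
#' enthalpies/entropies with terminal initiation terms, an entropic salt
#' correction `0.368 (N-1) ln[Na+]`, and the `CT/4` symmetry factor for a
#' non-self-complementary duplex:
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15`.
#'
#' Degenerate primers (IUPAC codes) are expanded into all concrete variants
#' (up to `cap`) and the Tm is reported as min/mean/max over the expansions.
#'
#' @param seq a single IUPAC DNA string.
#' @param method `"wallace"` or `"nearest_neighbor"`.
#' @param na_molar monovalent cation concentration, mol/L (nearest-neighbour
#'   only; default 50 mM).
#' @param primer_molar total oligo concentration CT, mol/L (nearest-neighbour
#'   only; default 500 nM).
#' @param cap maximum number of degeneracy expansions (error above it).
#' @return named numeric vector `c(min = , mean = , max = , n_variants = )`,
#'   in degrees C; for a non-degenerate primer min == mean == max.
#' @examples
#' melting_temperature("ACGT", "wallace")                 # 12
#' melting_temperature("GGACGATYTTRTTRGTTCGT", "wallace") # 8 variants
#' @export
melting_temperature <- function(seq, method = c("wallace", "nearest_neighbor"),
                                na_molar = 0.05, primer_molar = 5e-7,
                                cap = 64L) {
  method <- match.arg(method)
  seq <- assert_iupac(seq, "primer sequence")
  if (method == "nearest_neighbor" && nchar(seq) < 8L) {
    stop("nearest-neighbor Tm needs a sequence of at least 8 nt", call. = FALSE)
  }
  variants <- expand_degenerate(seq, cap = cap)
  tms <- vapply(variants, function(v) {
    switch(method,
           wallace = tm_wallace_one(v),
           nearest_neighbor = tm_nn_one(v, na_molar, primer_molar))
  }, numeric(1))
  c(min = min(tms), mean = mean(tms), max = max(tms),
    n_variants = length(tms))
}

#' Check melting-temperature balance across a multiplex panel
#'
#' Primers in one multiplex reaction must have similar melting temperatures
#' or the better-matched pairs will dominate. Computes the Tm of every
#' multiplex primer (mean over degeneracy expansions), the panel spread
#' (max - min), and a pass/fail verdict against `tolerance`.
#'
#' @param panel a [primer_panel()].
#' @param tolerance maximal acceptable Tm spread, degrees C.
#' @param method,... passed to [melting_temperature()].
#' @return list with `tm_table` (data frame: primer, target, tm_min, tm_mean,
#'   tm_max), `spread`, `tolerance`, `method`, and logical `pass`.
#' @export
tm_spread_check <- function(panel, tolerance = 5,
                            method = c("wallace", "nearest_neighbor"), ...) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "primer_panel"))
  pr <- panel_primers(panel, multiplex_only = TRUE)
  tms <- lapply(pr$seq, melting_temperature, method = method, ...)
  tab <- data.frame(
    primer = pr$name, target = pr$target,
    tm_min = vapply(tms, `[[`, numeric(1), "min"),
    tm_mean = vapply(tms, `[[`, numeric(1), "mean"),
    tm_max = vapply(tms, `[[`, numeric(1), "max"),
    stringsAsFactors = FALSE)
  spread <- max(tab$tm_max) - min(tab$tm_min)
  list(tm_table = tab, spread = spread, tolerance = tolerance,
       method = method, pass = spread <= tolerance)
}
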