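#' Mass constants for double-stranded DNA copy-number calculation
#'
#' A duplex fragment's molecular weight is computed per base pair:
#' `MW = n_at * mass_at_pair + n_gc * mass_gc_pair + end_correction`.
#' The defaults are the anhydrous average masses of an A-T and a G-C
#' nucleotide-monophosphate pair (dAMP 313.21 + dTMP 304.2 = 617.4;
#' dGMP 329.21 + dCMP 289.18 = 618.4 g/mol) with no end-group term, so any
#' alternative coefficient set can be reproduced by overriding the fields.
#'
#' @param mass_at_pair g/mol contributed by one A-T base pair.
#' @param mass_gc_pair g/mol contributed by one G-C base pair.
#' @param end_correction g/mol added once per duplex (may be 0 or negative,
#'   e.g. for 5'-phosphate/hydroxyl end chemistry).
#' @param avogadro Avogadro constant, 1/mol.
#' @return an object of class `mass_constants`.
#' @examples
#' mass_constants()
#' mass_constants(end_correction = 36.04) # add back the water of two ends
#' @export
mass_constants <- function(mass_at_pair = 617.4, mass_gc_pair = 618.4,
                           end_correction = 0, avogadro = 6.02214076e23) {
  stopifnot(is.numeric(mass_at_pair), mass_at_pair > 0,
            is.numeric(mass_gc_pair), mass_gc_pair > 0,
            is.numeric(end_correction), is.finite(end_correction),
            is.numeric(avogadro), avogadro > 0)
  structure(list(mass_at_pair = mass_at_pair, mass_gc_pair = mass_gc_pair,
                 end_correction = end_correction, avogadro = avogadro),
            class = "mass_constants")
}

#' @export
print.mass_constants <- function(x, ...) {
  cat("Mass constants: A-T pair", x$mass_at_pair, "g/mol; G-C pair",
      x$mass_gc_pair, "g/mol; end correction", x$end_correction,
      "g/mol; N_A", format(x$avogadro), "\n")
  invisible(x)
}

#' Count A-T and G-C base pairs in one strand of a duplex
#'
#' Each A or T character on the given strand corresponds to one A-T pair in
#' the duplex, each G or C to one G-C pair, so the counts are invariant under
#' reverse complementation. Degenerate IUPAC codes are rejected: quantified
#' fragments are sequenced products and an ambiguity code indicates a data
#' problem, not a property to average over.
#'
#' @param sequence a single DNA string over A/C/G/T (case-insensitive).
#' @return named integer vector `c(n_at = , n_gc = )`.
#' @examples
#' count_pairs("ATGC")
#' @export
count_pairs <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  ch <- seq_chars(sequence)
  bad <- which(!ch %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(sprintf(
      "non-ACGT character '%s' at position %d (degenerate codes not allowed in quantified fragments)",
      ch[bad[1L]], bad[1L]), call. = FALSE)
  }
  c(n_at = sum(ch %in% c("A", "T")), n_gc = sum(ch %in% c("G", "C")))
}

#' Molecular weight of a double-stranded fragment from its pair counts
#'
#' @param n_at,n_gc non-negative integer counts of A-T and G-C base pairs;
#'   `n_at + n_gc >= 1`.
#' @param constants a [mass_constants()] object.
#' @return molecular weight in g/mol.
#' @examples
#' molecular_weight(50, 50) # 100-bp fragment, 50% GC -> 61790 g/mol
#' @export
molecular_weight <- function(n_at, n_gc, constants = mass_constants()) {
  stopifnot(is.numeric(n_at), is.numeric(n_gc), n_at >= 0, n_gc >= 0)
  if (n_at + n_gc < 1) stop("zero-length fragment", call. = FALSE)
  n_at * constants$mass_at_pair + n_gc * constants$mass_gc_pair +
    constants$end_correction
}

#' Double-stranded copies per microlitre from a mass concentration
#'
#' `copies/uL = q * 1e-9 * N_A / MW`, where `q` is the measured DNA quantity
#' in ng/uL and `MW` the duplex molecular weight in g/mol. Linear in `q`.
#'
#' @param q_mean mean measured concentration, ng/uL (>= 0).
#' @param mw duplex molecular weight, g/mol (> 0).
#' @param constants a [mass_constants()] object (supplies Avogadro's number).
#' @return copies per microlitre.
#' @examples
#' copies_per_ul(10, molecular_weight(50, 50)) # ~9.75e10 copies/uL
#' @export
copies_per_ul <- function(q_mean, mw, constants = mass_constants()) {
  stopifnot(is.numeric(q_mean), is.numeric(mw))
  if (any(q_mean < 0)) stop("q_mean must be >= 0", call. = FALSE)
  if (any(mw <= 0)) stop("molecular weight must be > 0", call. = FALSE)
  q_mean * 1e-9 * constants$avogadro / mw
}

#' Bundle replicated concentration measurements of one fragment
#'
#' Replicates (three are expected practice) are averaged arithmetically. A
#' coefficient of variation above `cv_warn` raises a warning: a scattered
#' triplicate usually means a pipetting problem upstream of everything this
#' package computes.
#'
#' @param fragment_id label linking the measurement to a fragment.
#' @param replicates numeric vector of ng/uL readings (NA entries dropped).
#' @param cv_warn warn when sd/mean of the replicates exceeds this fraction.
#' @return object of class `concentration_measurement` with fields
#'   `fragment_id`, `replicates`, `q_mean`, `cv`.
#' @examples
#' concentration_measurement("colA", c(9.8, 10.0, 10.2))
#' @export
concentration_measurement <- function(fragment_id, replicates, cv_warn = 0.10) {
  replicates <- as.numeric(replicates[!is.na(replicates)])
  if (length(replicates) < 1L) {
    stop("at least one non-missing replicate is required", call. = FALSE)
  }
  if (any(replicates < 0)) stop("replicates must be >= 0", call. = FALSE)
  q_mean <- mean(replicates)
  cv <- if (length(replicates) > 1L && q_mean > 0) {
    stats::sd(replicates) / q_mean
  } else 0
  if (cv > cv_warn) {
    warning(sprintf("fragment '%s': replicate CV %.1f%% exceeds %.0f%%",
                    fragment_id, 100 * cv, 100 * cv_warn), call. = FALSE)
  }
  structure(list(fragment_id = as.character(fragment_id),
                 replicates = replicates, q_mean = q_mean, cv = cv),
            class = "concentration_measurement")
}

#' Quantify a template stock: sequence + measurements -> copies/uL
#'
#' Composes [count_pairs()], [molecular_weight()] and [copies_per_ul()],
#' retaining all intermediate values, to turn one cleaned PCR product into a
#' quantified template stock.
#'
#' @param id fragment label; must match `measurement$fragment_id`.
#' @param sequence one strand of the duplex, A/C/G/T only.
#' @param measurement a [concentration_measurement()] (or a numeric vector of
#'   replicate ng/uL readings, converted on the fly).
#' @param constants a [mass_constants()] object.
#' @return object of class `template_stock` with fields `fragment_id`,
#'   `sequence`, `length_bp`, `n_at`, `n_gc`, `molecular_weight`, `q_mean`,
#'   `replicates`, `copies_per_ul`.
#' @examples
#' quantify_stock("frag1", strrep("ATGC", 25), c(9.8, 10.0, 10.2))
#' @export
quantify_stock <- function(id, sequence, measurement,
                           constants = mass_constants()) {
  if (is.numeric(measurement)) {
    measurement <- concentration_measurement(id, measurement)
  }
  stopifnot(inherits(measurement, "concentration_measurement"))
  if (!identical(as.character(id), measurement$fragment_id)) {
    stop(sprintf("measurement is for fragment '%s', not '%s'",
                 measurement$fragment_id, id), call. = FALSE)
  }
  pairs <- count_pairs(sequence)
  mw <- molecular_weight(pairs[["n_at"]], pairs[["n_gc"]], constants)
  structure(list(
    fragment_id = as.character(id),
    sequence = toupper(sequence),
    length_bp = sum(pairs),
    n_at = pairs[["n_at"]],
    n_gc = pairs[["n_gc"]],
    molecular_weight = mw,
    q_mean = measurement$q_mean,
    replicates = measurement$replicates,
    copies_per_ul = copies_per_ul(measurement$q_mean, mw, constants)
  ), class = "template_stock")
}

#' @export
print.template_stock <- function(x, ...) {
  cat(sprintf(
    "Template stock '%s': %d bp (%d AT / %d GC), MW %.1f g/mol\n  q = %.3f ng/uL (n = %d) -> %.4g DS copies/uL\n",
    x$fragment_id, x$length_bp, x$n_at, x$n_gc, x$molecular_weight,
    x$q_mean, length(x$replicates), x$copies_per_ul))
  invisible(x)
}

#' Quantify every fragment in a FASTA file against a measurement table
#'
#' @param sequences named character vector of A/C/G/T sequences (as returned
#'   by [read_fasta()]) or a path to a FASTA file.
#' @param measurements data frame with column `fragment_id` and replicate
#'   columns `rep1..repN` (as returned by [read_measurements()]) or a path to
#'   such a CSV.
#' @param constants a [mass_constants()] object.
#' @return data frame with one row per measured fragment: `fragment_id`,
#'   `length_bp`, `n_at`, `n_gc`, `mw_g_per_mol`, `q_mean_ng_ul`,
#'   `copies_per_ul`.
#' @export
quantify_stocks <- function(sequences, measurements,
                            constants = mass_constants()) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- read_fasta(sequences)
  }
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  missing_seq <- setdiff(measurements$fragment_id, names(sequences))
  if (length(missing_seq)) {
    stop("no sequence for measured fragment(s): ",
         paste(missing_seq, collapse = ", "), call. = FALSE)
  }
  rep_cols <- grep("^rep[0-9]+$", names(measurements), value = TRUE)
  rows <- lapply(seq_len(nrow(measurements)), function(i) {
    id <- measurements$fragment_id[i]
    reps <- as.numeric(measurements[i, rep_cols])
    st <- quantify_stock(id, sequences[[id]],
                         concentration_measurement(id, reps), constants)
    data.frame(fragment_id = st$fragment_id, length_bp = st$length_bp,
               n_at = st$n_at, n_gc = st$n_gc,
               mw_g_per_mol = st$molecular_weight,
               q_mean_ng_ul = st$q_mean, copies_per_ul = st$copies_per_ul,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
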