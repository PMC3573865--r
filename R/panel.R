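#' Construct a multiplex primer panel
#'
#' A panel is a data frame of primer pairs plus the separation platform and
#' whether the assay targets degraded DNA (which activates the <300 bp
#' amplicon length rule). Pairs with `in_multiplex = FALSE` (e.g. a
#' verification pair used only in singleplex) are retained but excluded from
#' multiplex-level checks.
#'
#' @param pairs data frame with columns `target`, `fwd_name`, `fwd_seq`,
#'   `rev_name`, `rev_seq`, `conc_uM`, `size_bp`, `in_multiplex`.
#' @param platform separation platform: `"capillary"`, `"agarose"` or
#'   `"sequencer"`; sets the minimum resolvable amplicon size gap.
#' @param degraded_dna_mode logical; `TRUE` when templates are degraded
#'   (gut contents, faeces, museum material).
#' @return object of class `primer_panel` (a data frame with attributes).
#' @seealso [parse_panel()] to read a panel from a TSV/CSV file.
#' @export
primer_panel <- function(pairs,
                         platform = c("capillary", "agarose", "sequencer"),
                         degraded_dna_mode = FALSE) {
  platform <- match.arg(platform)
  req <- c("target", "fwd_name", "fwd_seq", "rev_name", "rev_seq",
           "conc_uM", "size_bp", "in_multiplex")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pairs <- as.data.frame(pairs)[, req]
  if (nrow(pairs) == 0L) stop("panel has no primer pairs", call. = FALSE)
  pairs$in_multiplex <- as.logical(pairs$in_multiplex)
  pairs$fwd_seq <- toupper(pairs$fwd_seq)
  pairs$rev_seq <- toupper(pairs$rev_seq)
  for (i in seq_len(nrow(pairs))) {
    for (col in c("fwd_seq", "rev_seq")) {
      tryCatch(assert_iupac(pairs[[col]][i]),
               error = function(e) stop(sprintf("row %d (%s), %s: %s", i,
                 pairs$target[i], col, conditionMessage(e)), call. = FALSE))
    }
    if (pairs$size_bp[i] < nchar(pairs$fwd_seq[i]) + nchar(pairs$rev_seq[i])) {
      stop(sprintf(
        "row %d (%s): product size %d bp is shorter than the two primers combined",
        i, pairs$target[i], pairs$size_bp[i]), call. = FALSE)
    }
  }
  if (any(pairs$conc_uM <= 0)) {
    stop("primer concentrations must be > 0 uM", call. = FALSE)
  }
  mplex <- pairs$target[pairs$in_multiplex]
  if (anyDuplicated(mplex)) {
    stop("duplicate multiplex target(s): ",
         paste(unique(mplex[duplicated(mplex)]), collapse = ", "),
         call. = FALSE)
  }
  structure(pairs, platform = platform,
            degraded_dna_mode = isTRUE(degraded_dna_mode),
            class = c("primer_panel", "data.frame"))
}

#' Read a primer panel from a delimited file
#'
#' Expects a TSV (or CSV, by file extension) with the columns documented in
#' [primer_panel()]. The bundled example panel — a seven-target assay for
#' tracking predator-prey interactions in a high-alpine arthropod community,
#' plus one singleplex verification pair — ships at
#' `system.file("extdata", "panel.tsv", package = "plexcal")`.
#'
#' @param path file path.
#' @inheritParams primer_panel
#' @return a [primer_panel()].
#' @examples
#' p <- parse_panel(system.file("extdata", "panel.tsv", package = "plexcal"))
#' sum(p$in_multiplex)  # 7 multiplex pairs
#' @export
parse_panel <- function(path,
                        platform = c("capillary", "agarose", "sequencer"),
                        degraded_dna_mode = FALSE) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("panel file is empty: ", path, call. = FALSE)
  primer_panel(tab, platform = platform, degraded_dna_mode = degraded_dna_mode)
}

#' @export
print.primer_panel <- function(x, ...) {
  cat(sprintf("Primer panel: %d multiplex pair(s) + %d other, platform %s%s\n",
              sum(x$in_multiplex), sum(!x$in_multiplex), attr(x, "platform"),
              if (attr(x, "degraded_dna_mode")) ", degraded-DNA mode" else ""))
  print(as.data.frame(x))
  invisible(x)
}

# Long view: one row per primer.
panel_primers <- function(panel, multiplex_only = TRUE) {
  p <- as.data.frame(panel)
  if (multiplex_only) p <- p[p$in_multiplex, , drop = FALSE]
  data.frame(
    name = c(p$fwd_name, p$rev_name),
    target = rep(p$target, 2L),
    seq = c(p$fwd_seq, p$rev_seq),
    stringsAsFactors = FALSE)
}

# Minimum resolvable gap for the smaller fragment of an adjacent pair.
platform_min_gap <- function(platform, smaller_size) {
  switch(platform,
    capillary = 20,
    agarose = if (smaller_size < 300) 30 else 0.1 * smaller_size,
    sequencer = 1,
    stop("unknown platform: ", platform, call. = FALSE))
}

#' Check amplicon size spacing for a separation platform
#'
#' Sorts the multiplex product sizes and checks every adjacent gap against
#' the platform's resolution: capillary electrophoresis resolves 20 bp,
#' agarose needs 30 bp below 300 bp (and, as a house rule, 10% of the
#' fragment size above that), a dye-labelled sequencer resolves 1 bp.
#'
#' @param panel a [primer_panel()].
#' @return data frame with one row per adjacent size pair: `target_small`,
#'   `target_large`, `size_small`, `size_large`, `gap`, `min_gap`, `pass`.
#'   Zero rows when fewer than two multiplex pairs are present (vacuous pass).
#' @export
spacing_check <- function(panel) {
  stopifnot(inherits(panel, "primer_panel"))
  p <- as.data.frame(panel)
  p <- p[p$in_multiplex, , drop = FALSE]
  p <- p[order(p$size_bp), , drop = FALSE]
  if (nrow(p) < 2L) {
    return(data.frame(target_small = character(0), target_large = character(0),
                      size_small = numeric(0), size_large = numeric(0),
                      gap = numeric(0), min_gap = numeric(0),
                      pass = logical(0)))
  }
  i <- seq_len(nrow(p) - 1L)
  out <- data.frame(
    target_small = p$target[i], target_large = p$target[i + 1L],
    size_small = p$size_bp[i], size_large = p$size_bp[i + 1L],
    gap = p$size_bp[i + 1L] - p$size_bp[i],
    stringsAsFactors = FALSE)
  out$min_gap <- vapply(out$size_small, platform_min_gap,
                        numeric(1), platform = attr(panel, "platform"))
  out$pass <- out$gap >= out$min_gap
  out
}

#' Check amplicon lengths against the degraded-DNA limit
#'
#' Degraded templates (gut contents, faeces, museum specimens) rarely retain
#' fragments of 300 bp or more, so such assays should only include amplicons
#' strictly shorter than `max_len`. The check is active only when the panel
#' was built with `degraded_dna_mode = TRUE`.
#'
#' @param panel a [primer_panel()].
#' @param max_len bp; products of this length or longer fail (default 300,
#'   i.e. the rule is "less than 300 bp").
#' @return data frame `target`, `size_bp`, `pass`; zero rows when the mode is
#'   off.
#' @export
degraded_dna_check <- function(panel, max_len = 300) {
  stopifnot(inherits(panel, "primer_panel"))
  if (!attr(panel, "degraded_dna_mode")) {
    return(data.frame(target = character(0), size_bp = numeric(0),
                      pass = logical(0)))
  }
  p <- as.data.frame(panel)
  p <- p[p$in_multiplex, , drop = FALSE]
  data.frame(target = p$target, size_bp = p$size_bp,
             pass = p$size_bp < max_len, stringsAsFactors = FALSE)
}

#' Run the full panel QC battery
#'
#' Combines [tm_spread_check()], [dimer_matrix()], [spacing_check()] and
#' [degraded_dna_check()] into one report with an overall verdict.
#'
#' @param panel a [primer_panel()].
#' @param tm_tolerance maximal Tm spread, degrees C.
#' @param tm_method Tm estimator, see [melting_temperature()].
#' @param dimer_score_threshold,dimer_anchored_threshold see [dimer_matrix()].
#' @param degraded_max_len see [degraded_dna_check()].
#' @return object of class `qc_report`: the four finding tables plus
#'   `overall_pass` (TRUE iff no check fails at the current thresholds).
#' @export
panel_qc <- function(panel, tm_tolerance = 5,
                     tm_method = c("wallace", "nearest_neighbor"),
                     dimer_score_threshold = 8, dimer_anchored_threshold = 5,
                     degraded_max_len = 300) {
  stopifnot(inherits(panel, "primer_panel"))
  tm <- tm_spread_check(panel, tolerance = tm_tolerance,
                        method = match.arg(tm_method))
  dimers <- dimer_matrix(panel, score_threshold = dimer_score_threshold,
                         anchored_threshold = dimer_anchored_threshold)
  spacing <- spacing_check(panel)
  lengths <- degraded_dna_check(panel, max_len = degraded_max_len)
  structure(list(
    platform = attr(panel, "platform"),
    tm = tm, dimers = dimers, spacing = spacing, lengths = lengths,
    overall_pass = tm$pass && !any(dimers$fail) && all(spacing$pass) &&
      all(lengths$pass)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("== Multiplex panel QC (platform:", x$platform, ") ==\n")
  cat(sprintf("Tm (%s): spread %.1f C (tolerance %.1f) -> %s\n",
              x$tm$method, x$tm$spread, x$tm$tolerance,
              if (x$tm$pass) "pass" else "FAIL"))
  nfail <- sum(x$dimers$fail)
  cat(sprintf("Cross-dimers: %d combination(s) scored, %d flagged%s\n",
              nrow(x$dimers), nfail,
              if (nfail) "" else " -> pass"))
  if (nfail) {
    print(utils::head(x$dimers[x$dimers$fail, ], 10L), row.names = FALSE)
  }
  if (nrow(x$spacing)) {
    bad <- x$spacing[!x$spacing$pass, , drop = FALSE]
    cat(sprintf("Size spacing: %d adjacent gap(s), %d below the %s minimum%s\n",
                nrow(x$spacing), nrow(bad), x$platform,
                if (nrow(bad)) "" else " -> pass"))
    if (nrow(bad)) print(bad, row.names = FALSE)
  } else {
    cat("Size spacing: fewer than two multiplex products -> vacuous pass\n")
  }
  if (nrow(x$lengths)) {
    bad <- x$lengths[!x$lengths$pass, , drop = FALSE]
    cat(sprintf("Degraded-DNA length rule: %d product(s) checked, %d at/over the limit\n",
                nrow(x$lengths), nrow(bad)))
    if (nrow(bad)) print(bad, row.names = FALSE)
  }
  cat("Overall:", if (x$overall_pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
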