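# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' The bundled example multiplex panel
#'
#' A seven-target panel for molecular gut-content analysis of a high-alpine
#' arthropod community (four *Nebria*/*Oreonebria* ground beetles, *Pardosa*
#' wolf spiders, the harvestman *Mitopus glacialis*, and a group-specific
#' Collembola pair), plus one singleplex pair used to verify *N. germari*
#' amplicons. Product sizes span 86-228 bp on a capillary platform.
#'
#' @inheritParams primer_panel
#' @return a [primer_panel()].
#' @export
example_panel <- function(platform = "capillary", degraded_dna_mode = FALSE) {
  parse_panel(system.file("extdata", "panel.tsv", package = "plexcal"),
              platform = platform, degraded_dna_mode = degraded_dna_mode)
}

# Whitespace-free fragment id for FASTA headers / measurement tables.
fragment_id <- function(target, in_multiplex = TRUE) {
  id <- gsub("[^A-Za-z0-9]+", "_", target)
  id <- sub("_+$", "", id)
  ifelse(in_multiplex, id, paste0(id, "_singleplex"))
}

#' A toy monotone concentration-to-signal response model
#'
#' Returns a function mapping a named concentration vector (uM) to summary
#' RFU, `rfu = efficiency * concentration`. This is *not* a PCR chemistry
#' model — it is the minimal strictly increasing response needed to exercise
#' the balancing loop in tests.
#'
#' @param efficiencies named numeric vector of per-target RFU-per-uM slopes.
#' @return function from named concentrations to named RFU.
#' @examples
#' resp <- toy_response_model(c(a = 1, b = 2))
#' resp(c(a = 0.4, b = 0.4))
#' @export
toy_response_model <- function(efficiencies) {
  stopifnot(is.numeric(efficiencies), !is.null(names(efficiencies)),
            all(efficiencies > 0))
  function(concentrations) {
    stopifnot(setequal(names(concentrations), names(efficiencies)))
    efficiencies[names(concentrations)] * concentrations
  }
}

# RFU grid consistent with the sensitivity narrative: fully detected from 20
# copies upward (0.3-1.5 RFU), partial at 7 (one replicate per triplet below
# the 0.1 RFU bound).
synthetic_readings <- function(targets,
                               levels = c(7, 20, 30, 100, 1000, 10000),
                               conditions = c("single_target", "target_mix",
                                              "single_plus_background",
                                              "mix_plus_background"),
                               replicates = 3L) {
  g <- design_sensitivity_grid(targets, levels, conditions, replicates)
  detected <- g$copies >= 20
  # partial level: last replicate of each triplet fails
  fail_rep <- g$copies < 20 & g$replicate == replicates
  g$rfu <- ifelse(detected, round(stats::runif(nrow(g), 0.3, 1.5), 3),
                  ifelse(fail_rep, round(stats::runif(nrow(g), 0.01, 0.09), 3),
                         round(stats::runif(nrow(g), 0.12, 0.4), 3)))
  g[, c("target", "copies", "condition", "replicate", "rfu")]
}

# Synthetic template of exactly size_bp: concrete forward footprint, random
# ACGT filler, reverse-complemented concrete reverse footprint.
synthetic_template <- function(fwd_seq, rev_seq, size_bp) {
  f <- resolve_degenerate(fwd_seq)
  r <- resolve_degenerate(rev_seq)
  fill <- size_bp - nchar(f) - nchar(r)
  stopifnot(fill >= 0)
  paste0(f, paste(sample(c("A", "C", "G", "T"), fill, replace = TRUE),
                  collapse = ""),
         reverse_complement(r))
}

#' Generate the complete synthetic fixture set
#'
#' Writes, deterministically for a given seed, everything needed to run the
#' whole toolkit end to end without external data:
#'
#' * `panel.tsv` — the bundled example panel (byte-identical across runs);
#' * `templates.fasta` — one synthetic template per pair, of exactly the
#'   panel's product sizes, carrying the concrete primer footprints at its
#'   ends (so [predict_amplicon()] round-trips) with random filler between
#'   them; labelled synthetic, non-biological;
#' * `measurements.csv` — triplicate fluorometric readings (ng/uL) per
#'   fragment, drawn around a per-fragment true concentration with 2%
#'   measurement noise;
#' * `readings.csv` — a replicated sensitivity grid for all seven targets
#'   under the four template conditions (copy levels 7, 20, 30, 100, 1000,
#'   10000): fully detected at 0.3-1.5 RFU from 20 copies upward, partial
#'   detection at 7 copies (values straddling the 0.1 RFU bound);
#' * `config.json` — the default [plexcal_config()] with this seed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; the same seed reproduces identical files.
#' @return (invisibly) named character vector of the written file paths.
#' @export
generate_fixture <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create fixture directory: ", out_dir, call. = FALSE)
  }
  paths <- c(panel = file.path(out_dir, "panel.tsv"),
             fasta = file.path(out_dir, "templates.fasta"),
             measurements = file.path(out_dir, "measurements.csv"),
             readings = file.path(out_dir, "readings.csv"),
             config = file.path(out_dir, "config.json"))

  ok <- file.copy(system.file("extdata", "panel.tsv", package = "plexcal"),
                  paths[["panel"]], overwrite = TRUE)
  if (!ok) stop("cannot write to ", out_dir, call. = FALSE)
  panel <- parse_panel(paths[["panel"]])

  with_seed(seed, {
    ids <- fragment_id(panel$target, panel$in_multiplex)
    fa <- character(0)
    for (i in seq_len(nrow(panel))) {
      tmpl <- synthetic_template(panel$fwd_seq[i], panel$rev_seq[i],
                                 panel$size_bp[i])
      fa <- c(fa, paste0(">", ids[i],
                         " synthetic template (non-biological filler)"),
              tmpl)
    }
    writeLines(fa, paths[["fasta"]])

    true_q <- round(stats::runif(nrow(panel), 5, 20), 2)
    reps <- sapply(1:3, function(j) {
      round(true_q * (1 + stats::rnorm(nrow(panel), 0, 0.02)), 3)
    })
    meas <- data.frame(fragment_id = ids, rep1 = reps[, 1], rep2 = reps[, 2],
                       rep3 = reps[, 3])
    utils::write.csv(meas, paths[["measurements"]], row.names = FALSE,
                     quote = FALSE)

    readings <- synthetic_readings(panel$target[panel$in_multiplex])
    utils::write.csv(readings, paths[["readings"]], row.names = FALSE,
                     quote = FALSE)
  })

  save_config(plexcal_config(seed = seed), paths[["config"]])
  invisible(paths)
}
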