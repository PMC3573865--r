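#' Predict multiplex amplicons on a template (in-silico PCR)
#'
#' Finds exact, degeneracy-aware matches of the forward primer on the given
#' strand of the template and of the reverse primer's reverse complement
#' downstream of each forward site. Matching uses IUPAC base-set intersection
#' semantics on both primer and template (a `Y` in the primer matches a `C`
#' or `T` — or a `Y` — in the template); mismatches are not tolerated. The
#' product includes both primer footprints, so its length is
#' `rev_end - fwd_start`.
#'
#' @param template a single IUPAC DNA string (one strand; the search is not
#'   repeated on the reverse strand).
#' @param pair one row of a [primer_panel()] (a list/data frame with
#'   `fwd_seq` and `rev_seq`), or a character vector
#'   `c(fwd_seq, rev_seq)`.
#' @param max_product_len longest product reported, bp.
#' @return data frame of predicted products, sorted by start: `start`, `end`
#'   (0-based, half-open), `length_bp`. Zero rows when either site is absent.
#' @examples
#' tmpl <- paste0("ACGTACGTAC", strrep("A", 50),
#'                reverse_complement("TTGCATTGCA"))
#' predict_amplicon(tmpl, c("ACGTACGTAC", "TTGCATTGCA"))
#' @export
predict_amplicon <- function(template, pair, max_product_len = 5000) {
  template <- assert_iupac(template, "template")
  if (is.character(pair) && length(pair) == 2L) {
    fwd <- pair[[1L]]
    rev <- pair[[2L]]
  } else {
    fwd <- pair$fwd_seq
    rev <- pair$rev_seq
  }
  fwd <- assert_iupac(fwd, "forward primer")
  rev <- assert_iupac(rev, "reverse primer")

  subj <- Biostrings::DNAString(template)
  fwd_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subj,
                                       fixed = FALSE)
  rev_hits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)), subj,
    fixed = FALSE)
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      length_bp = integer(0)))
  }
  fs <- Biostrings::start(fwd_hits)   # 1-based
  re <- Biostrings::end(rev_hits)
  grid <- expand.grid(fs = fs, re = re)
  # reverse site must start at or after the forward site's end
  grid <- grid[grid$re - nchar(rev) + 1L > grid$fs + nchar(fwd) - 1L, ,
               drop = FALSE]
  len <- grid$re - grid$fs + 1L
  keep <- len <= max_product_len
  out <- data.frame(start = grid$fs[keep] - 1L,   # 0-based half-open
                    end = grid$re[keep],
                    length_bp = len[keep])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
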