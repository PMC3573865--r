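# Internal IUPAC helpers shared by the panel-QC and fixture code.
# Base-set semantics throughout: a degenerate code stands for the set of
# bases it can resolve to; two characters are "compatible" if the sets
# intersect, and "complementary" if one set intersects the complement of
# the other. N matches everything.

.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

.iupac_chars <- names(.iupac_sets)

.complement_char <- local({
  src <- paste(.iupac_chars, collapse = "")
  dst <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", src)
  setNames(strsplit(dst, "")[[1]], .iupac_chars)
})

# 15x15 lookup: do the base sets of two IUPAC characters intersect?
.iupac_compat <- local({
  n <- length(.iupac_sets)
  m <- matrix(FALSE, n, n, dimnames = list(.iupac_chars, .iupac_chars))
  for (a in .iupac_chars) {
    for (b in .iupac_chars) {
      m[a, b] <- length(intersect(.iupac_sets[[a]], .iupac_sets[[b]])) > 0L
    }
  }
  m
})

# a can pair (Watson-Crick) with b iff set(a) intersects complement-set(b)
.iupac_pairs <- local({
  m <- .iupac_compat
  for (b in .iupac_chars) m[, b] <- .iupac_compat[, .complement_char[[b]]]
  m
})

seq_chars <- function(x) strsplit(toupper(x), "")[[1]]

assert_iupac <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  ch <- seq_chars(x)
  bad <- which(!ch %in% .iupac_chars)
  if (length(bad)) {
    stop(sprintf("%s contains non-IUPAC character '%s' at position %d",
                 what, ch[bad[1L]], bad[1L]), call. = FALSE)
  }
  invisible(paste(ch, collapse = ""))
}

#' Reverse complement of a (possibly degenerate) DNA string
#'
#' @param x a single DNA string over the IUPAC alphabet.
#' @return the reverse complement, uppercase.
#' @examples
#' reverse_complement("ATGC")
#' reverse_complement("GGACGATYTTRTTRGTTCGT")
#' @export
reverse_complement <- function(x) {
  x <- assert_iupac(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Expand a degenerate IUPAC string into all concrete ACGT sequences.
# cap guards against combinatorial blow-up; counted before expansion.
expand_degenerate <- function(x, cap = 64L) {
  ch <- seq_chars(assert_iupac(x))
  sets <- .iupac_sets[ch]
  n <- prod(vapply(sets, length, integer(1)))
  if (n > cap) {
    stop(sprintf("degeneracy expansion of '%s' has %d variants (cap %d)",
                 x, n, cap), call. = FALSE)
  }
  apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)),
        1L, function(r) paste(rev(r), collapse = ""))
}

# First base of each degenerate set: a deterministic concrete representative.
resolve_degenerate <- function(x) {
  ch <- seq_chars(assert_iupac(x))
  paste(vapply(.iupac_sets[ch], `[`, character(1), 1L), collapse = "")
}
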