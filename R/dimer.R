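#' Score a potential cross-dimer between two primers
#'
#' Slides the reverse complement of `b` along `a` without gaps and, at every
#' offset, finds the longest run of complementary positions; the score is the
#' longest such run over all offsets. Degenerate IUPAC characters are
#' complementary if their base sets allow a Watson-Crick pair (set
#' intersection semantics; N pairs with everything). A dimer is flagged as
#' 3'-anchored when some run achieving the maximal score covers the 3'
#' terminus of either primer — those duplexes are extensible by the
#' polymerase and are the most damaging in a reaction.
#'
#' The score is symmetric, `cross_dimer_score(a, b) ==
#' cross_dimer_score(b, a)`, and invariant under reverse-complementing both
#' primers.
#'
#' @param a,b primer sequences, 5' to 3', IUPAC alphabet.
#' @return list with `score` (longest complementary run, 0 if none),
#'   `three_prime_anchored` (logical), and `alignment` (a three-line text
#'   rendering of one maximal-scoring offset, `""` when score is 0).
#' @examples
#' cross_dimer_score("ACGTACGT", reverse_complement("ACGTACGT"))$score  # 8
#' cross_dimer_score("AAAAAAAAAA", "AAAAAAAAAA")$score                  # 0
#' @export
cross_dimer_score <- function(a, b) {
  a <- assert_iupac(a, "primer a")
  b <- assert_iupac(b, "primer b")
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  na <- length(ca)
  nb <- length(cb)

  best <- 0L
  best_run <- NULL  # c(diagonal, start_in_overlap, length)
  best_anchored <- FALSE
  # antiparallel annealing: a[i] (5'->3') faces b[j] (3'->5') with i + j = d
  for (d in 2L:(na + nb)) {
    i <- max(1L, d - nb):min(na, d - 1L)
    j <- d - i
    hit <- .iupac_pairs[cbind(ca[i], cb[j])]
    r <- rle(hit)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      if (len < best) next
      # run covers a's 3' end (i == na) or b's 3' end (j == nb)
      i_run <- i[starts[k]:ends[k]]
      j_run <- j[starts[k]:ends[k]]
      anchored <- (na %in% i_run) || (nb %in% j_run)
      if (len > best || (len == best && anchored && !best_anchored)) {
        if (len > best) best_anchored <- FALSE
        best <- len
        best_run <- c(d, starts[k], len)
        best_anchored <- best_anchored || anchored
      }
    }
  }
  if (best == 0L) {
    return(list(score = 0L, three_prime_anchored = FALSE, alignment = ""))
  }
  list(score = best, three_prime_anchored = best_anchored,
       alignment = render_dimer(ca, cb, best_run))
}

# text rendering: a 5'->3' on top, b 3'->5' (reversed) below, '|' at pairs.
# On diagonal d, b[j] sits under a[i] when i + j = d; reversed b's column for
# b[j] is nb + 1 - j, so the two lines are offset by d - nb - 1.
render_dimer <- function(ca, cb, run) {
  d <- run[1L]
  na <- length(ca)
  nb <- length(cb)
  i <- max(1L, d - nb):min(na, d - 1L)
  j <- d - i
  hit <- .iupac_pairs[cbind(ca[i], cb[j])]
  shift <- d - nb - 1L
  lead_a <- max(0L, -shift)
  lead_b <- max(0L, shift)
  top <- paste0(strrep(" ", lead_a), "5'-", paste(ca, collapse = ""), "-3'")
  bot <- paste0(strrep(" ", lead_b), "3'-", paste(rev(cb), collapse = ""), "-5'")
  bars <- character(max(lead_a + na, lead_b + nb))
  bars[] <- " "
  bars[lead_a + i] <- ifelse(hit, "|", " ")
  mid <- paste0(strrep(" ", 3L), paste(bars, collapse = ""))
  paste(top, mid, bot, sep = "\n")
}

#' Score all primer combinations of a panel for cross-dimers
#'
#' Every unordered pair of panel primers, including each primer against
#' itself (self-dimers), is scored with [cross_dimer_score()]. A combination
#' fails when its score reaches `score_threshold`, or when it is 3'-anchored
#' and reaches `anchored_threshold`.
#'
#' @param panel a [primer_panel()].
#' @param score_threshold overall run-length threshold (default 8).
#' @param anchored_threshold threshold for 3'-anchored runs (default 5).
#' @param include_singleplex also score primers of pairs not in the multiplex
#'   reaction (default `FALSE`: they never meet the multiplex primers in one
#'   tube).
#' @return data frame with one row per combination: `primer_a`, `primer_b`,
#'   `score`, `three_prime_anchored`, `fail`.
#' @export
dimer_matrix <- function(panel, score_threshold = 8, anchored_threshold = 5,
                         include_singleplex = FALSE) {
  stopifnot(inherits(panel, "primer_panel"))
  pr <- panel_primers(panel, multiplex_only = !include_singleplex)
  n <- nrow(pr)
  idx <- rbind(t(utils::combn(n, 2L)), cbind(seq_len(n), seq_len(n)))
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1L]
    j <- idx[k, 2L]
    d <- cross_dimer_score(pr$seq[i], pr$seq[j])
    data.frame(primer_a = pr$name[i], primer_b = pr$name[j],
               score = d$score, three_prime_anchored = d$three_prime_anchored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fail <- out$score >= score_threshold |
    (out$three_prime_anchored & out$score >= anchored_threshold)
  out[order(-out$score, out$primer_a, out$primer_b), , drop = FALSE]
}
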