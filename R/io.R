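#' Read DNA sequences from a FASTA file
#'
#' Record ids are taken from the header up to the first whitespace; sequences
#' are uppercased. RNA (`U`) is rejected — the toolkit quantifies DNA
#' duplexes only. An empty file yields an empty vector, not an error.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (possibly length 0).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (grepl("U", seqs[[i]], fixed = TRUE)) {
      stop(sprintf("record '%s' contains U: RNA is not supported", ids[i]),
           call. = FALSE)
    }
    tryCatch(assert_iupac(seqs[[i]]),
             error = function(e) stop(sprintf("record '%s': %s", ids[i],
               conditionMessage(e)), call. = FALSE))
  }
  seqs
}

#' Read a wide-format concentration measurement table
#'
#' @param path CSV with a `fragment_id` column and replicate columns
#'   `rep1..repN` (ng/uL); missing cells are permitted and ignored during
#'   averaging.
#' @return data frame as read, with `fragment_id` as character.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"fragment_id" %in% names(tab)) {
    stop("measurement table needs a 'fragment_id' column", call. = FALSE)
  }
  rep_cols <- grep("^rep[0-9]+$", names(tab), value = TRUE)
  if (!length(rep_cols)) {
    stop("measurement table needs at least one 'rep<N>' column", call. = FALSE)
  }
  tab$fragment_id <- as.character(tab$fragment_id)
  tab
}

#' Read a sensitivity-grid readings table
#'
#' @param path CSV with columns `target`, `copies`, `condition`, `replicate`,
#'   `rfu`.
#' @return validated data frame (conditions checked against the four-level
#'   vocabulary, RFU and copies non-negative).
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path,
                               call. = FALSE)
  check_readings(utils::read.csv(path, stringsAsFactors = FALSE))
}
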