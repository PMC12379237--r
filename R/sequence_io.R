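#' Read a protein FASTA file
#'
#' Reads a multi-record, possibly line-wrapped FASTA file of amino-acid
#' sequences. Sequences are uppercased; the ambiguous/non-standard residue
#' codes B, Z, U and O are mapped to the padding symbol `"X"` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `accession` and `sequence`.
#' @export
read_proteins <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  proteins(acc, seqs)
}

#' Construct a protein table
#'
#' @param accession Character vector of identifiers.
#' @param sequence Character vector of amino-acid sequences (same length).
#' @return A data frame with columns `accession` and `sequence`.
#' @export
proteins <- function(accession, sequence) {
  stopifnot(length(accession) == length(sequence))
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("empty protein sequence")
  if (any(grepl("\\s", sequence))) stop("whitespace inside protein sequence")
  odd <- grepl("[BZUO]", sequence)
  if (any(odd)) {
    warning(sprintf("non-standard residues (B/Z/U/O) in %d sequence(s) mapped to '%s'",
                    sum(odd), PAD))
    sequence <- chartr("BZUO", paste(rep(PAD, 4), collapse = ""), sequence)
  }
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), PAD, "]"), sequence)
  if (any(bad)) {
    stop("unrecognised characters in sequence(s): ",
         paste(utils::head(accession[bad], 5), collapse = ", "))
  }
  data.frame(accession = as.character(accession), sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Read a site-annotation table
#'
#' Reads a delimited text table of modification-site annotations with a
#' mandatory header and columns `accession`, `position` (1-based residue
#' index) and `label` (`"positive"` or `"negative"`).
#'
#' @param path Path to a TSV file.
#' @return A data frame with columns `accession`, `position`, `label`.
#' @export
read_sites <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "label")
  if (!all(need %in% names(x))) {
    stop("site table must have header columns: ", paste(need, collapse = ", "))
  }
  x$position <- as.integer(x$position)
  if (any(is.na(x$position)) || any(x$position < 1)) {
    stop("site positions must be integers >= 1")
  }
  if (!all(x$label %in% c("positive", "negative"))) {
    stop("site labels must be 'positive' or 'negative'")
  }
  x[need]
}

#' Extract a padded, lysine-centred peptide window
#'
#' Returns the residues at `position - flank .. position + flank` of a protein
#' sequence as a single string of length `2 * flank + 1`, replacing positions
#' that fall outside the protein with the padding symbol `"X"`. Positions are
#' 1-based (UniProt convention); the window is the closed interval around the
#' site.
#'
#' @param sequence Protein sequence (single string).
#' @param position 1-based index of the central residue.
#' @param flank Number of residues kept on each side (default 21, i.e. a
#'   43-residue window).
#' @param strict_k If `TRUE` (default), error unless the central residue is
#'   lysine (K).
#' @param accession Identifier used in error messages.
#' @return A single window string.
#' @export
extract_window <- function(sequence, position, flank = 21, strict_k = TRUE,
                           accession = "?") {
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop(sprintf("position %d out of range 1..%d for %s", position, n, accession))
  }
  centre <- substr(sequence, position, position)
  if (strict_k && centre != "K") {
    stop(sprintf("central residue at %s:%d is '%s', not K", accession, position, centre))
  }
  lo <- position - flank
  hi <- position + flank
  left <- strrep(PAD, max(0L, 1L - lo))
  right <- strrep(PAD, max(0L, hi - n))
  paste0(left, substr(sequence, max(1L, lo), min(n, hi)), right)
}

#' Assemble a window table
#'
#' Internal constructor for the `khib_windows` data frame used throughout the
#' package: one row per peptide window with its label and provenance.
#'
#' @param window Character vector of window strings (equal length).
#' @param label `"positive"`, `"negative"` or `"unknown"` per window.
#' @param accession,position Provenance of each window.
#' @param flank Residues per side.
#' @return A `khib_windows` data frame.
#' @export
khib_windows <- function(window, label, accession = NA_character_,
                         position = NA_integer_, flank = (nchar(window[1]) - 1L) / 2L) {
  if (length(window) && length(unique(nchar(window))) != 1L) {
    stop("windows have mixed lengths")
  }
  out <- data.frame(window = as.character(window),
                    label = as.character(label),
                    accession = as.character(accession),
                    position = as.integer(position),
                    stringsAsFactors = FALSE)
  attr(out, "flank") <- as.integer(flank)
  class(out) <- c("khib_windows", "data.frame")
  out
}

#' Build labelled windows from proteins and a site table
#'
#' Extracts one padded window per annotated site. In strict mode every
#' positive site must reference a lysine in the parent sequence.
#'
#' @param prot Protein table from [read_proteins()] or [proteins()].
#' @param sites Site table from [read_sites()].
#' @inheritParams extract_window
#' @return A `khib_windows` data frame.
#' @export
build_windows <- function(prot, sites, flank = 21, strict_k = TRUE) {
  idx <- match(sites$accession, prot$accession)
  if (anyNA(idx)) {
    stop("sites reference unknown accessions: ",
         paste(unique(sites$accession[is.na(idx)]), collapse = ", "))
  }
  w <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(prot$sequence[idx[i]], sites$position[i], flank,
                   strict_k = strict_k && sites$label[i] == "positive",
                   accession = sites$accession[i])
  }, character(1))
  khib_windows(w, sites$label, sites$accession, sites$position, flank)
}

#' Enumerate candidate negative windows of a protein
#'
#' One window per lysine residue that is not a reported modification site,
#' labelled negative, in deterministic order of increasing position.
#'
#' @param sequence Protein sequence.
#' @param positive_positions Integer vector of 1-based positions of known
#'   modified lysines (excluded).
#' @param flank Residues per side.
#' @param accession Identifier recorded as provenance.
#' @return A `khib_windows` data frame (zero rows if no eligible lysine).
#' @export
enumerate_negative_windows <- function(sequence, positive_positions = integer(),
                                       flank = 21, accession = NA_character_) {
  ks <- which(strsplit(sequence, "")[[1]] == "K")
  ks <- sort(setdiff(ks, as.integer(positive_positions)))
  w <- vapply(ks, function(p) extract_window(sequence, p, flank, strict_k = TRUE,
                                             accession = accession), character(1))
  khib_windows(as.character(w), rep("negative", length(ks)),
               rep(accession, length(ks)), ks, flank)
}

#' Write windows as FASTA
#'
#' Record ids are `accession_position_label`.
#'
#' @param windows A `khib_windows` data frame.
#' @param path Output file.
#' @export
write_windows_fasta <- function(windows, path) {
  ids <- paste(windows$accession, windows$position, windows$label, sep = "_")
  x <- Biostrings::AAStringSet(windows$window)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write windows as TSV
#' @inheritParams write_windows_fasta
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(as.data.frame(windows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read windows from TSV written by [write_windows_tsv()]
#' @param path Input file.
#' @return A `khib_windows` data frame.
#' @export
read_windows_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  khib_windows(x$window, x$label, x$accession, x$position)
}
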