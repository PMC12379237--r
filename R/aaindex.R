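#' Load an AAindex-style property table
#'
#' Reads a delimited table with one row per property scale: a column `index`
#' naming the scale followed by 20 columns (one per standard amino acid)
#' giving its value for that residue. This is the tabular equivalent of an
#' AAindex1 flat-file entry, so users can supply any scale set of their
#' choice.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (scales x 20 residues) with scale row names and
#'   residue column names.
#' @export
load_aaindex <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "index" || !all(AA20 %in% names(x))) {
    stop("AAindex table needs an 'index' column plus the 20 residue columns")
  }
  m <- as.matrix(x[, AA20])
  rownames(m) <- x$index
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("scale '%s' has no value for residue %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  m
}

#' The default 20-scale AAindex property table
#'
#' Twenty established published scales covering hydrophobicity
#' (Kyte-Doolittle, Hopp-Woods, Eisenberg, Fauchere-Pliska), steric
#' properties (Zamyatnin volume, Zimmerman bulkiness, accessible surface
#' area), electrostatics (Grantham polarity, net charge, isoelectric point,
#' Charton polarizability), electronic structure (EIIP), conformational
#' propensities (Chou-Fasman helix/sheet/turn, Bhaskaran-Ponnuswamy
#' flexibility), burial (Janin transfer energy), refractivity, residue mass
#' and Dayhoff relative mutability.
#'
#' @return A 20 x 20 numeric matrix (scales x residues).
#' @export
default_aaindex <- function() {
  load_aaindex(system.file("extdata", "aaindex_default20.tsv",
                           package = "khibkit", mustWork = TRUE))
}

#' Position-specific AAindex encoding of peptide windows
#'
#' Maps every position of a fixed-length window to the values of each
#' property scale for the residue at that position, in position-major order
#' (position 1 scale 1..k, position 2 scale 1..k, ...). Padding positions
#' (`"X"`) contribute 0 for every scale. With the default 20-scale table and
#' 43-residue windows the encoding has 860 dimensions.
#'
#' @param windows Character vector of equal-length window strings or a
#'   `khib_windows` data frame.
#' @param table Property matrix from [default_aaindex()] or
#'   [load_aaindex()].
#' @return Numeric matrix (windows x `L * nrow(table)`).
#' @export
aaindex_encode <- function(windows, table = default_aaindex()) {
  if (inherits(windows, "khib_windows")) windows <- windows$window
  if (length(unique(nchar(windows))) != 1L) stop("windows have mixed lengths")
  L <- nchar(windows[1])
  k <- nrow(table)
  # lookup matrix with a zero column for padding
  lut <- cbind(table, `X` = 0)
  chars <- do.call(rbind, strsplit(windows, ""))
  unknown <- setdiff(unique(as.vector(chars)), colnames(lut))
  if (length(unknown)) {
    stop("residue(s) missing from every scale of the table: ",
         paste(unknown, collapse = ", "))
  }
  out <- matrix(0, nrow = length(windows), ncol = L * k)
  for (p in seq_len(L)) {
    out[, ((p - 1L) * k + 1L):(p * k)] <- t(lut[, chars[, p], drop = FALSE])
  }
  colnames(out) <- paste0("p", rep(seq_len(L), each = k), ".",
                          rep(rownames(table), L))
  out
}
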