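#' Default three-group physicochemical partitions for CTD descriptors
#'
#' Seven attributes, each partitioning the 20 standard amino acids into three
#' disjoint groups: hydrophobicity (polar / neutral / hydrophobic), normalized
#' van der Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity and solvent accessibility — the canonical Dubchak-style
#' partitions used throughout the CTD literature.
#'
#' @return A named list of attributes; each element is a list of three
#'   character vectors (`g1`, `g2`, `g3`) jointly covering the 20 letters.
#' @export
ctd_groupings <- function() {
  g <- list(
    hydrophobicity = list(g1 = c("R", "K", "E", "D", "Q", "N"),
                          g2 = c("G", "A", "S", "T", "P", "H", "Y"),
                          g3 = c("C", "L", "V", "I", "M", "F", "W")),
    vdw_volume = list(g1 = c("G", "A", "S", "C", "T", "P", "D"),
                      g2 = c("N", "V", "E", "Q", "I", "L"),
                      g3 = c("M", "H", "K", "F", "R", "Y", "W")),
    polarity = list(g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
                    g2 = c("P", "A", "T", "G", "S"),
                    g3 = c("H", "Q", "R", "K", "N", "E", "D")),
    polarizability = list(g1 = c("G", "A", "S", "D", "T"),
                          g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
                          g3 = c("K", "M", "H", "F", "R", "Y", "W")),
    charge = list(g1 = c("K", "R"),
                  g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M",
                         "F", "P", "S", "T", "W", "Y", "V"),
                  g3 = c("D", "E")),
    secondary_structure = list(g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
                               g2 = c("V", "I", "Y", "C", "W", "F", "T"),
                               g3 = c("G", "N", "P", "S", "D")),
    solvent_accessibility = list(g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
                                 g2 = c("R", "K", "Q", "E", "N", "D"),
                                 g3 = c("M", "P", "S", "T", "H", "Y"))
  )
  for (nm in names(g)) validate_grouping(g[[nm]], nm)
  g
}

validate_grouping <- function(grouping, name = "grouping") {
  if (length(grouping) != 3L) stop(name, ": exactly 3 groups required")
  all_aa <- sort(unlist(grouping, use.names = FALSE))
  if (!identical(all_aa, sort(AA20))) {
    stop(name, ": groups must partition the 20 standard amino acids")
  }
  invisible(grouping)
}

# Residues of a window as a character vector with padding removed.
strip_pad <- function(window) {
  ch <- strsplit(window, "")[[1]]
  ch[ch != PAD]
}

# Map residues to group indices 1/2/3 for one grouping.
group_index <- function(residues, grouping) {
  idx <- integer(length(residues))
  for (i in 1:3) idx[residues %in% grouping[[i]]] <- i
  if (any(idx == 0L)) stop("residue not covered by grouping: ",
                           paste(unique(residues[idx == 0L]), collapse = ", "))
  idx
}

#' CTD composition descriptor
#'
#' Fraction of residues in each of the three groups, over the non-padding
#' residues of the window. The three values sum to 1.
#'
#' @param window Peptide window string (may contain `"X"` padding).
#' @param grouping One attribute from [ctd_groupings()].
#' @return Numeric vector of 3 values in \[0, 1\].
#' @export
ctd_composition <- function(window, grouping) {
  validate_grouping(grouping)
  res <- strip_pad(window)
  if (length(res) == 0L) stop("window is all padding")
  idx <- group_index(res, grouping)
  tabulate(idx, 3L) / length(res)
}

#' CTD transition descriptor
#'
#' Frequency of adjacent residue pairs whose members fall in two different
#' groups, divided by the number of adjacent pairs (`L' - 1` over the
#' non-padding residues). `mode = "symmetric"` (the feature default) counts
#' unordered pairs and returns the three values for pairs 1-2, 1-3, 2-3;
#' `mode = "directional"` counts only ordered transitions `from -> to` and
#' returns that single value.
#'
#' @inheritParams ctd_composition
#' @param mode `"symmetric"` or `"directional"`.
#' @param from,to Group indices (1..3) for directional mode.
#' @return Numeric vector of 3 values (symmetric) or 1 value (directional).
#' @export
ctd_transition <- function(window, grouping, mode = c("symmetric", "directional"),
                           from = 1L, to = 2L) {
  mode <- match.arg(mode)
  validate_grouping(grouping)
  res <- strip_pad(window)
  if (length(res) < 2L) stop("need at least 2 non-padding residues")
  idx <- group_index(res, grouping)
  a <- idx[-length(idx)]
  b <- idx[-1L]
  denom <- length(res) - 1L
  if (mode == "directional") {
    stopifnot(from %in% 1:3, to %in% 1:3)
    return(sum(a == from & b == to) / denom)
  }
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- apply(pairs, 1L, function(p) {
    sum((a == p[1] & b == p[2]) | (a == p[2] & b == p[1])) / denom
  })
  stats::setNames(out, c("t12", "t13", "t23"))
}

# Round-half-up: 1.75 -> 2, 3.5 -> 4, 5.25 -> 5.
round_half_up <- function(x) floor(x + 0.5)

#' CTD distribution descriptor
#'
#' For each group, the relative sequence positions (percent of the
#' non-padding length) of the first, 25 %, 50 %, 75 % and last occurrences of
#' that group. The p-th percentile occurrence index is
#' `round_half_up(p * n)` clamped to `[1, n]`, where `n` is the group's
#' occurrence count; an absent group yields five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 15 values in \[0, 100\] (3 groups x 5
#'   percentiles).
#' @export
ctd_distribution <- function(window, grouping) {
  validate_grouping(grouping)
  res <- strip_pad(window)
  if (length(res) == 0L) stop("window is all padding")
  idx <- group_index(res, grouping)
  L <- length(res)
  probs <- c(0, 0.25, 0.5, 0.75, 1)  # 0 stands for "first occurrence"
  out <- numeric(0)
  for (g in 1:3) {
    pos <- which(idx == g)
    n <- length(pos)
    if (n == 0L) {
      out <- c(out, rep(0, 5))
    } else {
      occ <- pmax(1L, pmin(n, round_half_up(probs * n)))
      occ[1] <- 1L
      out <- c(out, pos[occ] / L * 100)
    }
  }
  stats::setNames(out, paste0("g", rep(1:3, each = 5), "_",
                              rep(c("first", "p25", "p50", "p75", "last"), 3)))
}

#' Full CTD encoding of peptide windows
#'
#' Concatenates composition (7 x 3 = 21), symmetric transition (7 x 3 = 21)
#' and distribution (7 x 15 = 105) descriptors over the seven attribute
#' groupings, for a fixed total of 147 features per window. The encoding is
#' invariant to the amount of terminal padding.
#'
#' @param windows Character vector of window strings or a `khib_windows`
#'   data frame.
#' @param groupings List of exactly 7 attribute groupings
#'   (default [ctd_groupings()]).
#' @return Numeric matrix (windows x 147) with descriptive column names.
#' @export
ctd_encode <- function(windows, groupings = ctd_groupings()) {
  if (inherits(windows, "khib_windows")) windows <- windows$window
  if (length(groupings) != 7L) stop("exactly 7 groupings required, got ",
                                    length(groupings))
  gnames <- names(groupings)
  if (is.null(gnames)) gnames <- paste0("attr", seq_along(groupings))
  enc1 <- function(w) {
    comp <- unlist(lapply(groupings, function(g) ctd_composition(w, g)))
    tran <- unlist(lapply(groupings, function(g) ctd_transition(w, g)))
    dist <- unlist(lapply(groupings, function(g) ctd_distribution(w, g)))
    c(comp, tran, dist)
  }
  m <- t(vapply(windows, enc1, numeric(147L), USE.NAMES = FALSE))
  colnames(m) <- c(
    paste0("C.", rep(gnames, each = 3), ".g", rep(1:3, 7)),
    paste0("T.", rep(gnames, each = 3), ".", rep(c("t12", "t13", "t23"), 7)),
    paste0("D.", rep(gnames, each = 15), ".",
           rep(paste0("g", rep(1:3, each = 5), ".",
                      rep(c("first", "p25", "p50", "p75", "last"), 3)), 7))
  )
  m
}
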