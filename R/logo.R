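#' Two-sample sequence-logo position statistics
#'
#' Compares per-position residue frequencies between positive and negative
#' window sets. For every (position, residue) cell the 0/1 occurrence
#' indicators of the two groups are compared with a Welch two-sample t-test
#' (default) or a two-proportion z-test; the report carries the frequency
#' difference in percent (positive minus negative), the p-value and an
#' enriched / depleted / ns flag at level `alpha`. The central position is
#' excluded (it is the modified lysine by construction), and padding
#' (`"X"`) entries are excluded from both numerator and denominator. No
#' multiple-testing correction is applied.
#'
#' @param pos_windows,neg_windows Character vectors of equal-length window
#'   strings or `khib_windows` data frames (at least 2 windows per group).
#' @param alpha Significance threshold (default 0.05).
#' @param test `"welch"` (t-test on indicators) or `"zprop"`
#'   (two-proportion z); the two agree asymptotically.
#' @return A data frame of class `khib_logo` with columns `offset`
#'   (-flank..+flank, centre excluded), `residue`, `freq_pos`, `freq_neg`,
#'   `diff` (percent), `p`, `flag`.
#' @export
two_sample_logo <- function(pos_windows, neg_windows, alpha = 0.05,
                            test = c("welch", "zprop")) {
  test <- match.arg(test)
  if (inherits(pos_windows, "khib_windows")) pos_windows <- pos_windows$window
  if (inherits(neg_windows, "khib_windows")) neg_windows <- neg_windows$window
  if (length(pos_windows) < 2L || length(neg_windows) < 2L) {
    stop("need at least 2 windows per group")
  }
  L <- unique(nchar(c(pos_windows, neg_windows)))
  if (length(L) != 1L) stop("positive and negative windows differ in length")
  if (L %% 2 == 0) stop("windows must have odd length")
  flank <- (L - 1L) / 2L
  cp <- do.call(rbind, strsplit(pos_windows, ""))
  cn <- do.call(rbind, strsplit(neg_windows, ""))

  out <- vector("list", (L - 1L) * 20L)
  i <- 0L
  for (col in seq_len(L)) {
    offset <- col - flank - 1L
    if (offset == 0L) next
    p_res <- cp[, col]
    n_res <- cn[, col]
    p_use <- p_res != PAD
    n_use <- n_res != PAD
    np <- sum(p_use)
    nn <- sum(n_use)
    for (aa in AA20) {
      i <- i + 1L
      xp <- as.numeric(p_res[p_use] == aa)
      xn <- as.numeric(n_res[n_use] == aa)
      fp <- mean(xp)
      fn <- mean(xn)
      p_val <- if (np < 2L || nn < 2L) NA_real_
        else if (test == "welch") welch_p(xp, xn)
        else zprop_p(sum(xp), np, sum(xn), nn)
      d <- 100 * (fp - fn)
      flag <- if (!is.na(p_val) && p_val <= alpha && d > 0) "enriched"
        else if (!is.na(p_val) && p_val <= alpha && d < 0) "depleted"
        else "ns"
      out[[i]] <- data.frame(offset = offset, residue = aa, freq_pos = fp,
                             freq_neg = fn, diff = d, p = p_val, flag = flag,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "flank") <- flank
  class(res) <- c("khib_logo", "data.frame")
  res
}

# Welch two-sample t-test p-value on raw vectors; two identical constant
# groups give p = 1, a zero-variance difference in means gives p = 0.
welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  dm <- mean(x) - mean(y)
  if (se2 == 0) return(if (dm == 0) 1 else 0)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(dm / sqrt(se2)), df)
}

# Two-proportion z-test (pooled variance), two-sided.
zprop_p <- function(k1, n1, k2, n2) {
  p_hat <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
  if (se == 0) return(if (k1 / n1 == k2 / n2) 1 else 0)
  2 * stats::pnorm(-abs((k1 / n1 - k2 / n2) / se))
}

#' Logo report as a position x residue matrix
#'
#' @param logo A `khib_logo` report.
#' @param value Which column to spread (`"diff"`, `"p"`, `"freq_pos"`,
#'   `"freq_neg"`).
#' @return Numeric matrix (offsets x 20 residues).
#' @export
logo_matrix <- function(logo, value = "diff") {
  stopifnot(value %in% c("diff", "p", "freq_pos", "freq_neg"))
  offs <- sort(unique(logo$offset))
  m <- matrix(NA_real_, length(offs), 20,
              dimnames = list(offs, AA20))
  m[cbind(match(logo$offset, offs), match(logo$residue, AA20))] <- logo[[value]]
  m
}
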