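#' Position-specific enrichment effects for a species preset
#'
#' Encodes the qualitative motif story around modified lysines as planted
#' frequency deltas: upstream lysine (K) enrichment whose maximum matches the
#' printed species-level maxima (human 14.5 %, parasite 13.5 %, plant
#' 12.7 %), glutamate (E) enrichment and proline (P) depletion in all
#' presets, with parasite-specific alanine (A) enrichment and serine (S)
#' depletion and plant-specific arginine (R) depletion. Each effect takes its
#' maximum at |offset| = 1 and decays linearly to ~0 at |offset| = flank (an
#' explicit modelling choice). The `"null"` preset plants nothing.
#'
#' @param preset One of `"human"`, `"parasite"`, `"plant"`, `"null"`.
#' @param flank Residues per side (default 21).
#' @return Data frame with columns `offset` (non-zero), `residue`, `delta`.
#' @export
preset_effects <- function(preset = c("human", "parasite", "plant", "null"),
                           flank = 21) {
  preset <- match.arg(preset)
  decay <- function(offsets, max_delta) {
    data.frame(offset = offsets,
               delta = max_delta * (flank - abs(offsets) + 1) / flank)
  }
  eff <- function(residue, offsets, max_delta) {
    cbind(decay(offsets, max_delta), residue = residue)
  }
  up <- -(1:flank)
  r10 <- min(10L, flank)                 # secondary effects span +-10 offsets,
  both10 <- setdiff(-r10:r10, 0)         # clipped for narrow windows
  out <- switch(preset,
    null = data.frame(offset = integer(), residue = character(),
                      delta = numeric()),
    human = rbind(eff("K", up, 0.145),
                  eff("E", both10, 0.080),
                  eff("P", both10, -0.035)),
    parasite = rbind(eff("K", up, 0.135),
                     eff("E", both10, 0.040),
                     eff("A", both10, 0.060),
                     eff("S", both10, -0.040),
                     eff("P", both10, -0.035)),
    plant = rbind(eff("K", up, 0.127),
                  eff("E", both10, 0.090),
                  eff("R", both10, -0.035),
                  eff("P", both10, -0.035)))
  out[c("offset", "residue", "delta")]
}

#' Configuration for the synthetic window generator
#'
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param flank Residues per side (default 21, i.e. 43-residue windows).
#' @param background Residue frequency vector over the 20 standard letters
#'   (default uniform 1/20).
#' @param effects Data frame of planted `(offset, residue, delta)` effects;
#'   defaults to [preset_effects()] of `preset`.
#' @param preset Species preset (default `"null"`).
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pos, n_neg, flank = 21, background = NULL,
                             effects = NULL,
                             preset = c("null", "human", "parasite", "plant"),
                             seed = 42) {
  preset <- match.arg(preset)
  if (is.null(background)) background <- stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(length(background) == 20, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  if (is.null(names(background))) names(background) <- AA20
  if (is.null(effects)) effects <- preset_effects(preset, flank)
  stopifnot(all(effects$offset != 0), all(abs(effects$offset) <= flank),
            all(effects$residue %in% AA20))
  cfg <- structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                        flank = as.integer(flank), background = background,
                        effects = effects, preset = preset,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  # validate that every per-position distribution stays valid
  invisible(position_distributions(cfg))
  cfg
}

# Per-position residue distributions for positive windows: apply the deltas
# at each offset and renormalize by scaling the untouched residues, erroring
# if any frequency would go negative.
position_distributions <- function(cfg) {
  L <- 2L * cfg$flank + 1L
  out <- matrix(rep(cfg$background, L), nrow = L, byrow = TRUE,
                dimnames = list(NULL, AA20))
  for (off in unique(cfg$effects$offset)) {
    rows <- cfg$effects[cfg$effects$offset == off, ]
    p <- cfg$background
    p[rows$residue] <- p[rows$residue] + rows$delta
    if (any(p < 0)) {
      stop(sprintf("effect at offset %d drives a residue frequency below 0", off))
    }
    listed <- names(p) %in% rows$residue
    rest <- 1 - sum(p[listed])
    if (rest < 0) stop(sprintf("effects at offset %d sum above 1", off))
    p[!listed] <- p[!listed] * rest / sum(p[!listed])
    out[off + cfg$flank + 1L, ] <- p
  }
  out
}

#' Generate labelled synthetic peptide windows
#'
#' Negative windows are drawn i.i.d. from the background at every position;
#' positive windows are drawn from the background with the configured
#' per-(offset, residue) deltas applied. The central residue is always K for
#' both classes. Fully reproducible given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `khib_windows` data frame with `n_pos + n_neg` rows (positives
#'   first) and synthetic accessions.
#' @export
generate_windows <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  L <- 2L * config$flank + 1L
  centre <- config$flank + 1L
  pos_dist <- position_distributions(config)

  draw <- function(n, dist) {
    m <- matrix("", n, L)
    for (p in seq_len(L)) {
      m[, p] <- if (p == centre) "K"
        else sample(AA20, n, replace = TRUE, prob = dist[p, ])
    }
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  bg_dist <- matrix(rep(config$background, L), nrow = L, byrow = TRUE)
  pos <- draw(config$n_pos, pos_dist)
  neg <- draw(config$n_neg, bg_dist)
  khib_windows(c(pos, neg),
               c(rep("positive", config$n_pos), rep("negative", config$n_neg)),
               accession = sprintf("synth%05d", seq_len(config$n_pos + config$n_neg)),
               position = rep(centre, config$n_pos + config$n_neg),
               flank = config$flank)
}

#' Generate a synthetic proteome with implanted modification sites
#'
#' Random background proteins with positive-site peptide contexts implanted
#' at recorded lysine positions; every other lysine is an implicit negative.
#' Implant positions keep the full flank inside the protein and do not
#' overlap, so extracting a window at a recorded site reproduces the
#' implanted context exactly.
#'
#' @param config A [synthetic_config()] (its `n_pos` is ignored; site count
#'   is `n_proteins * sites_per_protein`).
#' @param n_proteins Number of proteins.
#' @param protein_length Length of each protein (must be at least
#'   `2 * flank + 1`).
#' @param sites_per_protein Implanted positive sites per protein.
#' @return A list with `proteins` (data frame), `sites` (positive rows
#'   only), and `windows` (the implanted positive `khib_windows`).
#' @export
generate_proteome <- function(config, n_proteins, protein_length,
                              sites_per_protein = 3) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- 2L * config$flank + 1L
  if (protein_length < L) stop("protein_length must be at least ", L)
  n_sites <- n_proteins * sites_per_protein
  site_cfg <- synthetic_config(n_sites, 0, flank = config$flank,
                               background = config$background,
                               effects = config$effects, seed = config$seed)
  contexts <- generate_windows(site_cfg)$window[seq_len(n_sites)]

  set.seed(config$seed + 1L)
  # non-overlapping implant centres with full flanks inside the protein
  slot_starts <- seq(1L, protein_length - L + 1L, by = L)
  if (length(slot_starts) < sites_per_protein) {
    stop("protein_length too short for ", sites_per_protein, " non-overlapping sites")
  }
  prot_rows <- vector("list", n_proteins)
  site_rows <- vector("list", n_proteins)
  k <- 0L
  for (i in seq_len(n_proteins)) {
    seq_chars <- sample(AA20, protein_length, replace = TRUE,
                        prob = config$background)
    starts <- sort(sample(slot_starts, sites_per_protein))
    positions <- integer(sites_per_protein)
    for (s in seq_len(sites_per_protein)) {
      k <- k + 1L
      ctx <- strsplit(contexts[k], "")[[1]]
      seq_chars[starts[s]:(starts[s] + L - 1L)] <- ctx
      positions[s] <- starts[s] + config$flank
    }
    acc <- sprintf("synthP%04d", i)
    prot_rows[[i]] <- data.frame(accession = acc,
                                 sequence = paste(seq_chars, collapse = ""),
                                 stringsAsFactors = FALSE)
    site_rows[[i]] <- data.frame(accession = acc, position = positions,
                                 label = "positive", stringsAsFactors = FALSE)
  }
  prot <- do.call(rbind, prot_rows)
  sites <- do.call(rbind, site_rows)
  windows <- khib_windows(contexts, rep("positive", n_sites),
                          accession = rep(prot$accession, each = sites_per_protein),
                          position = sites$position, flank = config$flank)
  list(proteins = prot, sites = sites, windows = windows)
}
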