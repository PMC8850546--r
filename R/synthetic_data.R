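#' Configuration for the synthetic annotated-proteome generator
#'
#' Describes a proteome with planted phosphosite signal. Sequences are drawn
#' i.i.d. with serines planted at `serine_rate` and the remaining mass
#' spread over the other 19 standard residues according to `background`
#' (uniform by default). A fraction of serines is designated positive; their
#' flanks receive two kinds of planted signal:
#'
#' * positional enrichment — at each configured offset the residue is set to
#'   the configured letter with exactly the configured probability
#'   (otherwise drawn uniformly from the other 19 letters), so the empirical
#'   frequency of the enriched residue in positive windows converges to
#'   `prob`. The defaults mimic simple kinase-like motifs (arginine at -3,
#'   proline at +1, leucine at +4 at probability 0.35, against a 0.05
#'   uniform background).
#' * pair composition — with the configured probability, one k-spaced
#'   ordered residue pair is written at a random in-window offset, signal
#'   visible to the pair-composition encoder but only weakly to positional
#'   encoders.
#'
#' Defaults are sized so the fused random-forest 5-fold CV AUC lands around
#' 0.9 on the generated corpus.
#'
#' @param n_proteins number of proteins (default 300).
#' @param length_range integer min/max of the uniform protein length
#'   distribution (default 200-600).
#' @param serine_rate per-position probability of planting a serine
#'   (default 0.08).
#' @param frac_positive fraction of serines designated phosphorylated
#'   (default 0.10).
#' @param background probability vector over the 20 standard residues used
#'   for non-serine positions (default uniform; the `S` entry is ignored
#'   and its mass redistributed).
#' @param positional data.frame `offset`, `residue`, `prob` of positional
#'   enrichments in positive windows; `NULL` for none.
#' @param pairs data.frame `k`, `pair` (two-letter string), `prob` of
#'   k-spaced pair injections in positive windows; `NULL` for none.
#' @param w window half-width the offsets must respect (default 12).
#' @param seed integer RNG seed (default 1).
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_proteins = 300L,
                             length_range = c(200L, 600L),
                             serine_rate = 0.08,
                             frac_positive = 0.10,
                             background = NULL,
                             positional = default_positional(),
                             pairs = default_pairs(),
                             w = 12L,
                             seed = 1L) {
  stopifnot(n_proteins >= 1L, length(length_range) == 2L,
            length_range[1L] >= 1L, length_range[2L] >= length_range[1L],
            serine_rate > 0, serine_rate < 1,
            frac_positive >= 0, frac_positive <= 1, w >= 1L)
  if (is.null(background)) background <- rep(1 / 20, 20L)
  stopifnot(length(background) == 20L, all(background >= 0))
  if (!is.null(positional) && nrow(positional)) {
    stopifnot(all(c("offset", "residue", "prob") %in% names(positional)))
    if (any(positional$offset == 0L) || any(abs(positional$offset) > w)) {
      stop("positional offsets must be non-zero and within +/- w")
    }
    if (any(positional$prob < 0 | positional$prob > 1)) {
      stop("positional probabilities must be in [0, 1]")
    }
    if (!all(positional$residue %in% .aa20)) {
      stop("positional residues must be standard amino acids")
    }
    tot <- tapply(positional$prob, positional$offset, sum)
    if (any(tot > 1)) {
      stop("positional probabilities at one offset must not sum above 1")
    }
  }
  if (!is.null(pairs) && nrow(pairs)) {
    stopifnot(all(c("k", "pair", "prob") %in% names(pairs)))
    if (any(nchar(pairs$pair) != 2L)) stop("pairs must be two-letter strings")
    if (any(pairs$prob < 0 | pairs$prob > 1)) {
      stop("pair probabilities must be in [0, 1]")
    }
    if (any(pairs$k < 0L) || any(pairs$k > 2L * w - 1L)) {
      stop("pair gaps must fit inside the window flanks")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 serine_rate = serine_rate, frac_positive = frac_positive,
                 background = background / sum(background),
                 positional = positional, pairs = pairs,
                 w = as.integer(w), seed = as.integer(seed)),
            class = "generator_config")
}

default_positional <- function() {
  data.frame(offset = c(-3L, 1L, 4L), residue = c("R", "P", "L"),
             prob = c(0.35, 0.35, 0.35), stringsAsFactors = FALSE)
}

default_pairs <- function() {
  data.frame(k = c(1L, 3L), pair = c("KE", "GD"), prob = c(0.75, 0.75),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated proteome with planted phosphosite signal
#'
#' Fully deterministic per config seed. Positive serines receive the
#' configured positional and pair-composition signal in their flanks (pair
#' injections are written first so that positional enrichments, whose
#' frequencies are checked for convergence, take precedence on overlap);
#' negatives are pure background. Planting never overwrites a designated
#' positive serine center, and the serine inventory is recomputed after
#' planting so the site table always matches the emitted sequences.
#'
#' @param cfg a [generator_config()].
#' @return list with `proteins` (list of [annotated_protein()]) and `truth`
#'   (data.frame `protein_id`, `position`, `label` for every serine site).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  bg <- cfg$background
  bg19 <- bg[-match("S", .aa20)]
  bg19 <- bg19 / sum(bg19)
  letters19 <- .aa20[.aa20 != "S"]
  with_seed(cfg$seed, {
    proteins <- vector("list", cfg$n_proteins)
    truth <- vector("list", cfg$n_proteins)
    for (i in seq_len(cfg$n_proteins)) {
      len <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
      is_ser <- stats::runif(len) < cfg$serine_rate
      chars <- character(len)
      chars[is_ser] <- "S"
      chars[!is_ser] <- sample(letters19, sum(!is_ser), replace = TRUE,
                               prob = bg19)
      ser_pos <- which(is_ser)
      pos_sites <- ser_pos[stats::runif(length(ser_pos)) < cfg$frac_positive]
      protected <- pos_sites
      for (p in pos_sites) {
        # pair injections first; positional enrichment wins on overlap
        if (!is.null(cfg$pairs) && nrow(cfg$pairs)) {
          for (r in seq_len(nrow(cfg$pairs))) {
            if (stats::runif(1) >= cfg$pairs$prob[r]) next
            k <- cfg$pairs$k[r]
            offs <- setdiff(-cfg$w:(cfg$w - k - 1L), c(0L, -(k + 1L)))
            offs <- offs[p + offs >= 1L & p + offs + k + 1L <= len]
            offs <- offs[!(p + offs) %in% protected &
                           !(p + offs + k + 1L) %in% protected]
            if (!length(offs)) next
            o <- if (length(offs) == 1L) offs else sample(offs, 1L)
            ab <- strsplit(cfg$pairs$pair[r], "", fixed = TRUE)[[1]]
            chars[p + o] <- ab[1L]
            chars[p + o + k + 1L] <- ab[2L]
          }
        }
        if (!is.null(cfg$positional) && nrow(cfg$positional)) {
          for (r in seq_len(nrow(cfg$positional))) {
            q <- p + cfg$positional$offset[r]
            if (q < 1L || q > len || q %in% protected) next
            chars[q] <- if (stats::runif(1) < cfg$positional$prob[r]) {
              cfg$positional$residue[r]
            } else {
              sample(setdiff(.aa20, cfg$positional$residue[r]), 1L)
            }
          }
        }
      }
      ser_all <- which(chars == "S")       # recompute after planting
      id <- sprintf("SYNP%04d", i)
      proteins[[i]] <- annotated_protein(id, paste(chars, collapse = ""),
                                         pos_sites)
      truth[[i]] <- data.frame(
        protein_id = id, position = ser_all,
        label = as.integer(ser_all %in% pos_sites),
        stringsAsFactors = FALSE)
    }
    names(proteins) <- vapply(proteins, `[[`, "", "id")
    list(proteins = proteins, truth = do.call(rbind, truth))
  })
}

#' A null generator configuration (no planted signal)
#'
#' Convenience wrapper: same geometry as [generator_config()] but with no
#' positional or pair enrichment, so positive and negative flank
#' distributions are identical and any downstream classifier should sit at
#' chance.
#'
#' @param ... arguments forwarded to [generator_config()].
#' @return a `generator_config` with empty enrichment specs.
#' @export
null_config <- function(...) {
  generator_config(positional = NULL, pairs = NULL, ...)
}
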