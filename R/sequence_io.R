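#' Construct an annotated protein
#'
#' Bundles a protein sequence with its labeled serine positions. Positive
#' sites are experimentally annotated phosphoserines; by convention every
#' serine not listed as positive is a negative (non-phosphorylated) candidate
#' site. An explicit negative-site list, when given, overrides that
#' convention.
#'
#' @param id protein identifier.
#' @param sequence amino-acid sequence (single string, upper case).
#' @param positive_sites integer vector of 1-based positions of
#'   phosphorylated serines. Every listed position must hold an `S`.
#' @param negative_sites optional integer vector of 1-based positions of
#'   explicitly negative serines; if `NULL` (default) negatives are derived
#'   as all unlisted serines.
#' @return an object of class `annotated_protein`.
#' @export
annotated_protein <- function(id, sequence, positive_sites = integer(),
                              negative_sites = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  positive_sites <- sort(unique(as.integer(positive_sites)))
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- positive_sites[positive_sites < 1L | positive_sites > n]
  if (length(bad)) {
    stop(sprintf("protein '%s': site position %d outside sequence [1, %d]",
                 id, bad[1L], n))
  }
  not_s <- positive_sites[chars[positive_sites] != "S"]
  if (length(not_s)) {
    stop(sprintf(
      "protein '%s': residue at position %d is '%s', expected 'S'",
      id, not_s[1L], chars[not_s[1L]]))
  }
  if (!is.null(negative_sites)) {
    negative_sites <- sort(unique(as.integer(negative_sites)))
    bad <- negative_sites[negative_sites < 1L | negative_sites > n]
    if (length(bad)) {
      stop(sprintf("protein '%s': site position %d outside sequence [1, %d]",
                   id, bad[1L], n))
    }
    not_s <- negative_sites[chars[negative_sites] != "S"]
    if (length(not_s)) {
      stop(sprintf(
        "protein '%s': residue at position %d is '%s', expected 'S'",
        id, not_s[1L], chars[not_s[1L]]))
    }
  }
  structure(list(id = id, sequence = sequence,
                 positive_sites = positive_sites,
                 negative_sites = negative_sites),
            class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  cat(sprintf("annotated_protein '%s': %d aa, %d positive site(s)\n",
              x$id, nchar(x$sequence), length(x$positive_sites)))
  invisible(x)
}

negative_candidates <- function(protein) {
  if (!is.null(protein$negative_sites)) return(protein$negative_sites)
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  setdiff(which(chars == "S"), protein$positive_sites)
}

#' Read proteins and site annotations
#'
#' Reads a multi-record FASTA of protein sequences and a TSV site table with
#' header columns `protein_id`, `position` (1-based) and `label` (1 =
#' phosphorylated, 0 = explicit negative), and returns validated
#' [annotated_protein()] objects. Proteins without any table entry keep an
#' empty positive set (all their serines become derived negatives). If a
#' protein has any label-0 row, its negatives are exactly the listed ones;
#' otherwise negatives are derived as all unlisted serines.
#'
#' @param fasta path to a FASTA file.
#' @param sites path to the TSV site table, or `NULL` for no annotations.
#' @return named list of `annotated_protein` objects, in FASTA order.
#' @export
read_proteins <- function(fasta, sites = NULL) {
  aas <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- unname(as.character(aas))
  tab <- if (is.null(sites)) NULL else read_site_table(sites)
  if (!is.null(tab)) {
    unknown <- setdiff(unique(tab$protein_id), ids)
    if (length(unknown)) {
      stop(sprintf("site table references unknown protein '%s'", unknown[1L]))
    }
  }
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    pos <- integer()
    neg <- NULL
    if (!is.null(tab)) {
      rows <- tab[tab$protein_id == ids[i], , drop = FALSE]
      pos <- rows$position[rows$label == 1L]
      if (any(rows$label == 0L)) neg <- rows$position[rows$label == 0L]
    }
    out[[i]] <- annotated_protein(ids[i], seqs[i], pos, neg)
  }
  names(out) <- ids
  out
}

#' Read a site annotation table
#'
#' @param path TSV file with header `protein_id`, `position`, `label`.
#' @return data.frame with those three columns (`label` integer 0/1).
#' @export
read_site_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab))) {
    stop("site table must have columns: ", paste(need, collapse = ", "))
  }
  tab$position <- as.integer(tab$position)
  tab$label <- as.integer(tab$label)
  if (!all(tab$label %in% c(0L, 1L))) stop("site labels must be 0 or 1")
  tab[need]
}

#' Write proteins and their site annotations
#'
#' @param proteins list of [annotated_protein()] objects.
#' @param fasta output FASTA path.
#' @param sites output TSV site table path (positives as label 1 and, for
#'   proteins with an explicit negative list, those negatives as label 0).
#' @return invisibly, the input list.
#' @export
write_proteome <- function(proteins, fasta, sites) {
  aas <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "sequence"))
  names(aas) <- vapply(proteins, `[[`, "", "id")
  Biostrings::writeXStringSet(aas, fasta)
  rows <- lapply(proteins, function(p) {
    pos <- data.frame(
      protein_id = rep(p$id, length(p$positive_sites)),
      position = p$positive_sites,
      label = rep(1L, length(p$positive_sites)))
    if (!is.null(p$negative_sites)) {
      pos <- rbind(pos, data.frame(
        protein_id = rep(p$id, length(p$negative_sites)),
        position = p$negative_sites,
        label = rep(0L, length(p$negative_sites))))
    }
    pos
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    tab <- data.frame(protein_id = character(), position = integer(),
                      label = integer())
  }
  utils::write.table(tab, sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(proteins)
}

#' Extract labeled peptide windows around every serine site
#'
#' For each annotated protein, one window is produced per serine site
#' (positive and negative): the 2w+1-mer centered on the serine, padded with
#' the gap symbol `O` where the window extends past a terminus, so every
#' peptide has exactly length 2w+1. Windows containing non-standard residues
#' (B, J, U, X, Z) are excluded with a warning.
#'
#' @param proteins list of [annotated_protein()] objects.
#' @param w half-width of the window; the full window size is 2w+1
#'   (default `w = 12`, i.e. 25-mers).
#' @return a `window_set`: data.frame with columns `protein_id`,
#'   `center_pos`, `peptide`, `label` (factor negative/positive), carrying
#'   attribute `w`. `n_windows()` reports the class counts.
#' @export
extract_windows <- function(proteins, w = 12L) {
  w <- as.integer(w)
  stopifnot(w >= 1L)
  if (inherits(proteins, "annotated_protein")) proteins <- list(proteins)
  rows <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    p <- proteins[[i]]
    sites <- c(p$positive_sites, negative_candidates(p))
    if (!length(sites)) next
    labs <- rep(c("positive", "negative"),
                c(length(p$positive_sites), length(sites) -
                    length(p$positive_sites)))
    peps <- vapply(sites, function(pos) window_peptide(p$sequence, pos, w),
                   character(1L))
    rows[[i]] <- data.frame(protein_id = p$id, center_pos = sites,
                            peptide = peps, label = labs,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) stop("no serine sites found in input")
  bad <- grepl(paste0("[", paste(.aa_nonstandard, collapse = ""), "]"),
               df$peptide)
  if (any(bad)) {
    warning(sprintf(
      "excluded %d window(s) containing non-standard residues", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  new_window_set(df, w)
}

window_peptide <- function(sequence, pos, w) {
  n <- nchar(sequence)
  if (pos < 1L || pos > n) {
    stop(sprintf("site position %d outside sequence [1, %d]", pos, n))
  }
  if (substr(sequence, pos, pos) != "S") {
    stop(sprintf("residue at position %d is '%s', expected 'S'",
                 pos, substr(sequence, pos, pos)))
  }
  left <- max(1L, pos - w)
  right <- min(n, pos + w)
  paste0(strrep("O", w - (pos - left)),
         substr(sequence, left, right),
         strrep("O", w - (right - pos)))
}

new_window_set <- function(df, w) {
  df$label <- factor(df$label, levels = c("negative", "positive"))
  rownames(df) <- NULL
  structure(df, class = c("window_set", "data.frame"), w = as.integer(w))
}

#' Class counts of a window set
#'
#' @param ws a `window_set`.
#' @return named integer vector `c(n1 = <positives>, n2 = <negatives>)`.
#' @export
n_windows <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  c(n1 = sum(ws$label == "positive"), n2 = sum(ws$label == "negative"))
}

#' @export
print.window_set <- function(x, ...) {
  n <- n_windows(x)
  cat(sprintf("window_set: %d windows (%d positive, %d negative), w = %d\n",
              nrow(x), n[["n1"]], n[["n2"]], attr(x, "w")))
  invisible(x)
}

subset_windows <- function(ws, idx) {
  new_window_set(as.data.frame(ws)[idx, , drop = FALSE], attr(ws, "w"))
}

#' Ratio-controlled negative subsampling
#'
#' Keeps all positive windows and a uniform random subsample (without
#' replacement) of `ratio * n1` negative windows, giving a training set with
#' a controlled 1:`ratio` positive:negative balance.
#'
#' @param ws a `window_set`.
#' @param ratio integer negatives-per-positive ratio (1, 2, 3, ...).
#' @param seed integer RNG seed; the draw is deterministic per seed.
#' @return a `window_set` with `n1` positives and exactly `ratio * n1`
#'   negatives, in original row order.
#' @export
subsample_ratio <- function(ws, ratio, seed) {
  stopifnot(inherits(ws, "window_set"))
  ratio <- as.integer(ratio)
  stopifnot(ratio >= 1L)
  n <- n_windows(ws)
  need <- ratio * n[["n1"]]
  if (n[["n2"]] < need) {
    stop(sprintf("need %d negative windows for ratio 1:%d but only %d present",
                 need, ratio, n[["n2"]]))
  }
  neg_idx <- which(ws$label == "negative")
  keep_neg <- with_seed(seed, sample(neg_idx, need))
  subset_windows(ws, sort(c(which(ws$label == "positive"), keep_neg)))
}

#' Protein-level train/test split
#'
#' Splits proteins (not windows) into training and test sets so that no
#' protein contributes windows to both sides.
#'
#' @param proteins list of [annotated_protein()] objects.
#' @param test_fraction fraction of proteins assigned to the test set
#'   (0 < f < 1); the test count is `floor(n * test_fraction)`, clamped so
#'   both sides are non-empty.
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`, each a protein list.
#' @export
split_proteins <- function(proteins, test_fraction, seed) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(proteins)
  if (n < 2L) stop("need at least 2 proteins to split")
  n_test <- min(n - 1L, max(1L, as.integer(floor(n * test_fraction))))
  test_idx <- with_seed(seed, sample.int(n, n_test))
  list(train = proteins[-test_idx], test = proteins[test_idx])
}

#' Remove byte-identical duplicate sequences
#'
#' Keeps the first occurrence of each distinct sequence, preserving order.
#' This is a trivial exact-duplicate filter only; similarity-based redundancy
#' reduction (e.g. clustering at 30% identity) is an upstream concern.
#'
#' @param proteins list of [annotated_protein()] objects.
#' @return the deduplicated list.
#' @export
dedup_exact <- function(proteins) {
  proteins[!duplicated(vapply(proteins, `[[`, "", "sequence"))]
}

#' Write / read a peptide window file
#'
#' Plain-text exchange format: one window per line, peptide then a
#' tab-separated 0/1 label, with a `# w=<half-width>` header line.
#'
#' @param ws a `window_set`.
#' @param path file path.
#' @return `write_windows()` returns the input invisibly; `read_windows()`
#'   returns a `window_set` (with synthetic protein ids/positions when the
#'   file carries none).
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# w=%d", attr(ws, "w")), con)
  writeLines(paste0(ws$peptide, "\t",
                    as.integer(ws$label == "positive")), con)
  invisible(ws)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  w <- NA_integer_
  m <- regmatches(lines[hdr], regexpr("w=\\d+", lines[hdr]))
  if (length(m)) w <- as.integer(sub("w=", "", m[[1L]]))
  lines <- lines[!hdr & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pep <- vapply(parts, `[`, "", 1L)
  lab <- as.integer(vapply(parts, `[`, "", 2L))
  if (is.na(w)) w <- (nchar(pep[1L]) - 1L) %/% 2L
  if (any(nchar(pep) != 2L * w + 1L)) {
    stop(sprintf("all peptides must have length %d", 2L * w + 1L))
  }
  if (any(substr(pep, w + 1L, w + 1L) != "S")) {
    stop("every window must be centered on 'S'")
  }
  df <- data.frame(protein_id = sprintf("win%05d", seq_along(pep)),
                   center_pos = w + 1L, peptide = pep,
                   label = ifelse(lab == 1L, "positive", "negative"),
                   stringsAsFactors = FALSE)
  new_window_set(df, w)
}
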