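#' Composition of k-spaced amino acid pairs (CKSAAP)
#'
#' For each gap k in 0..kmax and each ordered pair (a, b) over the 21-letter
#' alphabet (20 residues plus the gap symbol `O`), counts the positions i
#' with `peptide[i] == a` and `peptide[i + k + 1] == b`, normalized by the
#' number of k-spaced pairs in a length-L window, `L - k - 1`. With that
#' normalization each per-k block of 441 features sums to exactly 1. For the
#' default 25-mer and kmax = 5 the vector has 441 * 6 = 2646 features, named
#' `"k<gap>|<ab>"` in k-major order with pairs ordered lexicographically over
#' the alphabet `ACDEFGHIKLMNPQRSTVWYO`.
#'
#' @param peptide window peptide string over the 21-letter alphabet.
#' @param kmax maximum gap (default 5).
#' @return named numeric vector of length `441 * (kmax + 1)`.
#' @export
encode_cksaap <- function(peptide, kmax = 5L) {
  kmax <- as.integer(kmax)
  ints <- peptide_ints(peptide)
  L <- length(ints)
  if (L < kmax + 2L) {
    stop(sprintf("peptide length %d too short for kmax = %d (need >= %d)",
                 L, kmax, kmax + 2L))
  }
  out <- numeric(441L * (kmax + 1L))
  for (k in 0:kmax) {
    a <- ints[seq_len(L - k - 1L)]
    b <- ints[seq.int(k + 2L, L)]
    counts <- tabulate((a - 1L) * 21L + b, nbins = 441L)
    out[(k * 441L + 1L):((k + 1L) * 441L)] <- counts / (L - k - 1L)
  }
  names(out) <- cksaap_names(kmax)
  out
}

cksaap_names <- function(kmax) {
  pairs <- paste0(rep(.aa21, each = 21L), rep(.aa21, times = 21L))
  as.vector(vapply(0:kmax, function(k) paste0("k", k, "|", pairs),
                   character(441L)))
}

#' Positional one-hot (binary) encoding
#'
#' Each of the 2w flanking positions (the invariant central serine is
#' skipped) contributes a 21-long one-hot block in alphabet order
#' `ACDEFGHIKLMNPQRSTVWYO`, positions ordered left to right. For a 25-mer
#' the vector has 21 * 24 = 504 features, named `"p<offset>|<aa>"` with
#' offsets -w..-1, +1..+w relative to the central serine.
#'
#' @param peptide window peptide string (odd length, centered on `S`).
#' @return named numeric 0/1 vector of length `21 * (length - 1)`.
#' @export
encode_binary <- function(peptide) {
  ints <- peptide_ints(peptide)
  w <- check_center(ints)
  flank <- ints[-(w + 1L)]
  out <- numeric(21L * length(flank))
  out[(seq_along(flank) - 1L) * 21L + flank] <- 1
  names(out) <- binary_names(w)
  out
}

binary_names <- function(w) {
  offs <- c(-w:-1, 1:w)
  paste0("p", rep(offs, each = 21L), "|", rep(.aa21, times = 2L * w))
}

#' Amino acid composition (AAC) encoding
#'
#' Relative frequency of each of the 20 standard residues among the 2w
#' flanking positions; the central serine is not counted and the gap symbol
#' `O` is excluded from both numerator and denominator. If every flank
#' position is `O` the vector is all zero (with a warning).
#'
#' @param peptide window peptide string (odd length, centered on `S`).
#' @return named numeric vector of length 20 (order `ACDEFGHIKLMNPQRSTVWY`),
#'   summing to 1 unless all flanks are gaps.
#' @export
encode_aac <- function(peptide) {
  ints <- peptide_ints(peptide)
  w <- check_center(ints)
  flank <- ints[-(w + 1L)]
  counts <- tabulate(flank[flank <= 20L], nbins = 20L)
  denom <- sum(counts)
  out <- if (denom == 0L) {
    warning("window flanks are all gap symbols; returning zero AAC vector")
    numeric(20L)
  } else {
    counts / denom
  }
  names(out) <- paste0("aac|", .aa20)
  out
}

peptide_ints <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  ints <- match(chars, .aa21)
  if (anyNA(ints)) {
    stop(sprintf("invalid residue '%s' in peptide", chars[which(is.na(ints))[1L]]))
  }
  ints
}

check_center <- function(ints) {
  L <- length(ints)
  if (L %% 2L == 0L) stop("window length must be odd (2w+1)")
  w <- (L - 1L) %/% 2L
  if (ints[w + 1L] != match("S", .aa21)) {
    stop("window center must be 'S'")
  }
  w
}

#' Encode a window set as a feature matrix
#'
#' Applies one encoder to every window, preserving window order and labels.
#'
#' @param ws a `window_set`.
#' @param scheme one of `"CKSAAP"`, `"BINARY"`, `"AAC"`.
#' @param kmax maximum gap for the CKSAAP scheme (ignored otherwise).
#' @return a `feature_matrix`: list with elements `x` (dense numeric matrix,
#'   named columns), `labels` (factor, aligned to rows), `scheme` and
#'   `params`.
#' @export
encode_matrix <- function(ws, scheme = c("CKSAAP", "BINARY", "AAC"),
                          kmax = 5L) {
  stopifnot(inherits(ws, "window_set"))
  scheme <- match.arg(scheme)
  w <- attr(ws, "w")
  enc <- switch(scheme,
                CKSAAP = function(p) encode_cksaap(p, kmax = kmax),
                BINARY = encode_binary,
                AAC = encode_aac)
  template <- enc(ws$peptide[1L])
  x <- matrix(0, nrow = nrow(ws), ncol = length(template),
              dimnames = list(NULL, names(template)))
  x[1L, ] <- template
  if (nrow(ws) > 1L) {
    for (i in 2:nrow(ws)) {
      x[i, ] <- tryCatch(enc(ws$peptide[i]), error = function(e) {
        stop(sprintf("window %d (%s:%d): %s", i, ws$protein_id[i],
                     ws$center_pos[i], conditionMessage(e)), call. = FALSE)
      })
    }
  }
  new_feature_matrix(x, ws$label, scheme,
                     params = list(w = w, kmax = if (scheme == "CKSAAP") kmax))
}

new_feature_matrix <- function(x, labels, scheme, params) {
  structure(list(x = x, labels = labels, scheme = scheme, params = params),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d windows x %d features\n",
              x$scheme, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Write a feature matrix as TSV
#'
#' Named feature columns plus a `label` column; a `#` header line records the
#' scheme and encoder parameters.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  prm <- paste(names(fm$params),
               vapply(fm$params, function(v) paste(v, collapse = ","), ""),
               sep = "=", collapse = " ")
  writeLines(sprintf("# scheme=%s %s", fm$scheme, prm), con)
  df <- as.data.frame(fm$x, check.names = FALSE)
  df$label <- as.integer(fm$labels == "positive")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fm)
}
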