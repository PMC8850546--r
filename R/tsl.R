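#' Two-sample logo enrichment statistics
#'
#' For every flank offset j and residue r (21 letters including the gap
#' symbol `O`), compares the frequency of r at offset j between the
#' positive and negative window groups, testing the null hypothesis that the
#' per-window 0/1 indicator "residue at offset j equals r" has the same
#' distribution in both groups. Cells with p below `alpha` are marked
#' `enriched` (more frequent in positives) or `depleted`; all others `ns`.
#' The central offset 0 is always `S` in both groups by construction, hence
#' always `ns`.
#'
#' Methods: `"binomial"` is a two-proportion test on counts versus group
#' sizes (normal approximation on the pooled proportion); `"ttest"` is a
#' Welch two-sample t-test on the 0/1 indicators — less exact for rare
#' residues but faster in spirit. A residue absent from both groups at a
#' position gives `p = 1`.
#'
#' @param ws a `window_set` with both classes present.
#' @param alpha per-cell significance level (default 0.05; no
#'   multiple-testing correction is applied).
#' @param method `"binomial"` (default) or `"ttest"`.
#' @param mask_gap if `TRUE`, drop gap-symbol (`O`) rows from the output
#'   (the gap mainly encodes terminal proximity).
#' @return a `tsl_result` data.frame with one row per (offset, residue):
#'   counts and frequencies per group, the frequency difference
#'   (positive - negative), `p`, and `direction` in
#'   `enriched`/`depleted`/`ns`; attributes `alpha`, `method`, `n_pos`,
#'   `n_neg`, `w`.
#' @export
tsl_test <- function(ws, alpha = 0.05, method = c("binomial", "ttest"),
                     mask_gap = FALSE) {
  stopifnot(inherits(ws, "window_set"), alpha > 0, alpha < 1)
  method <- match.arg(method)
  y <- ws$label == "positive"
  n1 <- sum(y); n2 <- sum(!y)
  if (n1 == 0L || n2 == 0L) stop("both window groups must be non-empty")
  w <- attr(ws, "w")
  L <- 2L * w + 1L
  mat <- matrix(unlist(strsplit(ws$peptide, "", fixed = TRUE), use.names = FALSE),
                nrow = nrow(ws), ncol = L, byrow = TRUE)
  offsets <- -w:w
  cells <- expand.grid(residue = .aa21, offset = offsets,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  c1 <- integer(nrow(cells)); c2 <- integer(nrow(cells))
  for (j in seq_len(L)) {
    col_pos <- factor(mat[y, j], levels = .aa21)
    col_neg <- factor(mat[!y, j], levels = .aa21)
    idx <- (j - 1L) * 21L + seq_len(21L)
    c1[idx] <- tabulate(col_pos, 21L)
    c2[idx] <- tabulate(col_neg, 21L)
  }
  p1 <- c1 / n1
  p2 <- c2 / n2
  p <- switch(method,
    binomial = {
      phat <- (c1 + c2) / (n1 + n2)
      se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
      z <- ifelse(se > 0, (p1 - p2) / se, 0)
      ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
    },
    ttest = {
      v1 <- p1 * (1 - p1) * n1 / max(n1 - 1L, 1L)
      v2 <- p2 * (1 - p2) * n2 / max(n2 - 1L, 1L)
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- ifelse(se > 0,
                   (v1 / n1 + v2 / n2)^2 /
                     ((v1 / n1)^2 / max(n1 - 1L, 1L) +
                        (v2 / n2)^2 / max(n2 - 1L, 1L)),
                   1)
      ifelse(se > 0, 2 * stats::pt(-abs((p1 - p2) / se), df),
             ifelse(p1 == p2, 1, 0))
    })
  p[c1 + c2 == 0L] <- 1
  direction <- ifelse(p < alpha & p1 > p2, "enriched",
                      ifelse(p < alpha & p1 < p2, "depleted", "ns"))
  res <- data.frame(offset = cells$offset, residue = cells$residue,
                    count_pos = c1, count_neg = c2,
                    freq_pos = p1, freq_neg = p2, diff = p1 - p2,
                    p = p, direction = direction,
                    stringsAsFactors = FALSE)
  if (mask_gap) res <- res[res$residue != "O", , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("tsl_result", "data.frame"), alpha = alpha,
            method = method, n_pos = n1, n_neg = n2, w = w)
}

#' Logo matrix from a two-sample-logo result
#'
#' Residues x offsets matrix of frequency differences (positive - negative),
#' zeroed where the cell is not significant at the result's alpha;
#' consumable by standard sequence-logo rendering tools.
#'
#' @param res a `tsl_result`.
#' @param significant_only zero out non-significant cells (default `TRUE`).
#' @return numeric matrix, rownames residues, colnames offsets.
#' @export
tsl_logo_matrix <- function(res, significant_only = TRUE) {
  stopifnot(inherits(res, "tsl_result"))
  residues <- unique(res$residue)
  offsets <- sort(unique(res$offset))
  m <- matrix(0, nrow = length(residues), ncol = length(offsets),
              dimnames = list(residues, as.character(offsets)))
  vals <- res$diff
  if (significant_only) vals[res$direction == "ns"] <- 0
  m[cbind(match(res$residue, residues),
          match(as.character(res$offset), colnames(m)))] <- vals
  m
}

#' Write a two-sample-logo result (and its logo matrix) as TSV
#'
#' @param res a `tsl_result`.
#' @param path output path for the per-cell table.
#' @param logo_path optional output path for the [tsl_logo_matrix()] TSV.
#' @return the input, invisibly.
#' @export
write_tsl <- function(res, path, logo_path = NULL) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(logo_path)) {
    m <- tsl_logo_matrix(res)
    utils::write.table(cbind(residue = rownames(m), as.data.frame(m)),
                       logo_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(res)
}
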