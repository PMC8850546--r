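#' Two-group Kruskal-Wallis statistic for a single feature
#'
#' Rank-based test of distributional equality between the positive and
#' negative window groups, used here as a per-feature ranking score rather
#' than an inference procedure. Uses mid-ranks for ties with the standard
#' tie correction; the p-value comes from the chi-square approximation with
#' `groups - 1` degrees of freedom (1 df for the two-group case). A feature
#' constant across all windows carries no rank information and returns
#' `H = 0, p = 1`.
#'
#' @param values numeric feature values, one per window.
#' @param labels group labels (two non-empty groups).
#' @return named numeric vector `c(H = , p = )`.
#' @export
kw_statistic <- function(values, labels) {
  g <- factor(labels)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  N <- length(values)
  stopifnot(length(labels) == N)
  r <- rank(values)
  n_i <- tabulate(g)
  R_i <- as.vector(rowsum(r, g))
  H0 <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  tt <- rle(sort(values))$lengths
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr <= 0) return(c(H = 0, p = 1))
  H <- max(H0 / corr, 0)
  c(H = H, p = stats::pchisq(H, df = nlevels(g) - 1L, lower.tail = FALSE))
}

#' Rank all features of a matrix by the Kruskal-Wallis statistic
#'
#' Vectorized over columns; equivalent per column to [kw_statistic()].
#' Ranking is by H descending, ties broken by original column index
#' ascending, so the order is fully deterministic.
#'
#' @param fm a `feature_matrix`, or a plain numeric matrix if `labels` is
#'   given.
#' @param labels group labels (ignored when `fm` is a `feature_matrix`).
#' @return a `feature_ranking`: data.frame with columns `name`, `H`, `p`,
#'   `rank` (1 = highest H), row order following the original columns.
#' @export
rank_features <- function(fm, labels = NULL) {
  if (inherits(fm, "feature_matrix")) {
    x <- fm$x
    labels <- fm$labels
  } else {
    x <- fm
  }
  g <- droplevels(factor(labels))
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  N <- nrow(x)
  n_i <- tabulate(g)
  rk <- apply(x, 2L, rank)
  S <- rowsum(rk, g)                      # group rank sums per column
  H0 <- 12 / (N * (N + 1)) * colSums(S^2 / n_i) - 3 * (N + 1)
  tie_sum <- apply(x, 2L, function(v) {
    tt <- rle(sort(v))$lengths
    sum(tt^3 - tt)
  })
  corr <- 1 - tie_sum / (N^3 - N)
  H <- ifelse(corr <= 0, 0, pmax(H0 / corr, 0))
  p <- ifelse(corr <= 0, 1,
              stats::pchisq(H, df = nlevels(g) - 1L, lower.tail = FALSE))
  ord <- order(-H, seq_along(H))
  rnk <- integer(length(H))
  rnk[ord] <- seq_along(H)
  structure(data.frame(name = colnames(x), H = H, p = p, rank = rnk,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

#' Retain the top-N features by Kruskal-Wallis rank
#'
#' Returns the n top-ranked columns, kept in their original column order so
#' encoder feature layout is preserved, together with the full ranking.
#'
#' @param fm a `feature_matrix`.
#' @param n number of features to keep (1 <= n <= ncol).
#' @param ranking optional precomputed [rank_features()] result for `fm`.
#' @return list with elements `fm` (reduced `feature_matrix`) and `ranking`
#'   (full `feature_ranking`).
#' @export
select_top_n <- function(fm, n, ranking = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- as.integer(n)
  p <- ncol(fm$x)
  if (n < 1L || n > p) {
    stop(sprintf("n must be in [1, %d], got %d", p, n))
  }
  if (is.null(ranking)) ranking <- rank_features(fm)
  keep <- sort(which(ranking$rank <= n))
  red <- new_feature_matrix(fm$x[, keep, drop = FALSE], fm$labels,
                            fm$scheme, fm$params)
  list(fm = red, ranking = ranking)
}

#' Write a feature ranking as TSV
#'
#' @param ranking a `feature_ranking`.
#' @param path output path.
#' @return the input, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ranking)
}
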