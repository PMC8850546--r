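# shared fixtures and independent oracles, all built in code at test time

aa20 <- phosfuse::aa_alphabet(gap = FALSE)
aa21 <- phosfuse::aa_alphabet(gap = TRUE)

# random window peptide: S center, flanks i.i.d. over the given letters
rand_peptide <- function(w = 12L, letters = aa21) {
  flank <- function() paste(sample(letters, w, replace = TRUE), collapse = "")
  paste0(flank(), "S", flank())
}

# build a window_set directly from peptides (bypasses FASTA plumbing)
make_window_set <- function(peptides_pos, peptides_neg, w = 12L) {
  df <- data.frame(
    protein_id = sprintf("fix%05d", seq_len(length(peptides_pos) +
                                              length(peptides_neg))),
    center_pos = w + 1L,
    peptide = c(peptides_pos, peptides_neg),
    label = rep(c("positive", "negative"),
                c(length(peptides_pos), length(peptides_neg))),
    stringsAsFactors = FALSE)
  phosfuse:::new_window_set(df, w)
}

random_window_set <- function(n_pos, n_neg, w = 12L, seed = 1L,
                              letters = aa20) {
  set.seed(seed)
  make_window_set(replicate(n_pos, rand_peptide(w, letters)),
                  replicate(n_neg, rand_peptide(w, letters)), w)
}

# brute-force CKSAAP oracle: explicit double loop over position pairs
cksaap_brute <- function(peptide, kmax = 5L) {
  chars <- strsplit(peptide, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (k in 0:kmax) {
    block <- matrix(0, 21, 21, dimnames = list(aa21, aa21))
    for (i in seq_len(L)) {
      j <- i + k + 1L
      if (j > L) next
      block[chars[i], chars[j]] <- block[chars[i], chars[j]] + 1
    }
    v <- as.vector(t(block)) / (L - k - 1)
    names(v) <- paste0("k", k, "|", rep(aa21, each = 21),
                       rep(aa21, times = 21))
    out <- c(out, v)
  }
  out
}

# pairwise Mann-Whitney AUC oracle
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == "positive" | labels == TRUE | labels == 1]
  neg <- scores[!(labels == "positive" | labels == TRUE | labels == 1)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# minimal protein list: identical short sequences with one serine, no sites
dummy_proteins <- function(n) {
  lapply(seq_len(n), function(i) {
    phosfuse::annotated_protein(sprintf("dummy%04d", i), "ASA")
  })
}

# perfectly separable two-feature toy matrix for backend tests
toy_separable_fm <- function(n = 50L, jitter = 0.01, seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(1 + stats::rnorm(2 * n, sd = jitter), ncol = 2),
             matrix(0 + stats::rnorm(2 * n, sd = jitter), ncol = 2))
  colnames(x) <- c("f1", "f2")
  labels <- factor(rep(c("positive", "negative"), each = n),
                   levels = c("negative", "positive"))
  phosfuse:::new_feature_matrix(x, labels, "CKSAAP", list(w = 12L))
}
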