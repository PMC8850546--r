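test_that("windows near a terminus are padded with 'O' to full length", {
  p <- annotated_protein("P1", "MSAAA", positive_sites = 2L)
  ws <- extract_windows(p, w = 12L)
  expect_equal(nrow(ws), 1L)
  expect_equal(ws$peptide, paste0(strrep("O", 11), "MSAAA", strrep("O", 9)))
  expect_equal(nchar(ws$peptide), 25L)
})

test_that("one window per serine; unlisted serines become negatives", {
  # 30-residue protein with serines at 5, 12, 20, 28; only 12 is positive
  seqc <- rep("A", 30)
  seqc[c(5, 12, 20, 28)] <- "S"
  p <- annotated_protein("P1", paste(seqc, collapse = ""),
                         positive_sites = 12L)
  ws <- extract_windows(p, w = 12L)
  expect_equal(unname(n_windows(ws)), c(1L, 3L))
  expect_setequal(ws$center_pos, c(5, 12, 20, 28))
  expect_equal(ws$center_pos[ws$label == "positive"], 12L)
})

test_that("every extracted window has length 2w+1 and central serine", {
  sim <- generate_proteome(generator_config(n_proteins = 30, seed = 5))
  for (w in c(5L, 12L)) {
    ws <- extract_windows(sim$proteins, w = w)
    expect_true(all(nchar(ws$peptide) == 2L * w + 1L))
    expect_true(all(substr(ws$peptide, w + 1L, w + 1L) == "S"))
    # 'O' only as contiguous prefix/suffix
    expect_true(all(grepl("^O*[^O]+O*$", ws$peptide)))
  }
})

test_that("stripping the padding recovers the site in the source protein", {
  sim <- generate_proteome(generator_config(n_proteins = 10, seed = 9))
  ws <- extract_windows(sim$proteins, w = 12L)
  idx <- sample(nrow(ws), 50)
  for (i in idx) {
    core <- gsub("O", "", ws$peptide[i])
    n_left_pad <- nchar(sub("O*$", "", ws$peptide[i])) - nchar(core) # leading O count
    center_in_core <- 12L + 1L - n_left_pad
    seqs <- sim$proteins[[ws$protein_id[i]]]$sequence
    hit <- regexpr(core, seqs, fixed = TRUE)
    expect_true(hit > 0)
    # the window core occurs at the expected coordinates around the center
    expect_equal(substr(seqs, ws$center_pos[i], ws$center_pos[i]), "S")
    expect_equal(substr(seqs, ws$center_pos[i] - (center_in_core - 1L),
                        ws$center_pos[i] + nchar(core) - center_in_core),
                 core)
  }
})

test_that("site validation fails loudly on bad annotations", {
  expect_error(annotated_protein("PX", "MSAAA", positive_sites = 3L),
               "position 3.*'A'.*expected 'S'")
  expect_error(annotated_protein("PX", "MSAAA", positive_sites = 99L),
               "outside sequence")
  expect_error(extract_windows(list(), w = 12), "no serine")
})

test_that("windows with non-standard residues are excluded with a warning", {
  p1 <- annotated_protein("P1", "AAAAXAAAAAAASAAAAAAAAAAAAAA",
                          positive_sites = 13L)
  p2 <- annotated_protein("P2", paste0(strrep("A", 19), "S", strrep("A", 20)),
                          positive_sites = 20L)
  expect_warning(ws <- extract_windows(list(p1, p2), w = 12L),
                 "non-standard")
  expect_equal(ws$protein_id, "P2")
})

test_that("ratio subsampling keeps all positives and ratio x n1 negatives", {
  ws <- random_window_set(10, 100, seed = 3)
  out <- subsample_ratio(ws, 3, seed = 1)
  expect_equal(unname(n_windows(out)), c(10L, 30L))
  # deterministic per seed, generally different across seeds
  out2 <- subsample_ratio(ws, 3, seed = 1)
  expect_identical(out$peptide, out2$peptide)
  out3 <- subsample_ratio(ws, 3, seed = 2)
  expect_equal(unname(n_windows(out3)), c(10L, 30L))
  expect_false(identical(out$peptide, out3$peptide))
  # ratio 1 with n2 == n1 is the identity on the window multiset
  ws11 <- random_window_set(8, 8, seed = 4)
  expect_identical(as.data.frame(subsample_ratio(ws11, 1, seed = 5)),
                   as.data.frame(ws11))
  expect_error(subsample_ratio(ws, 11, seed = 1), "need 110 negative")
})

test_that("protein-level split matches the 90/10 arithmetic and partitions", {
  prots <- dummy_proteins(766)
  sp <- split_proteins(prots, test_fraction = 0.10, seed = 1)
  expect_length(sp$train, 690)
  expect_length(sp$test, 76)
  ids <- function(x) vapply(x, `[[`, "", "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(prots))
  # reproducible membership per seed
  sp2 <- split_proteins(prots, test_fraction = 0.10, seed = 1)
  expect_identical(ids(sp$test), ids(sp2$test))
  # 2 proteins at 0.5 -> 1/1; fewer than 2 is an error
  sp3 <- split_proteins(dummy_proteins(2), 0.5, seed = 1)
  expect_length(sp3$train, 1)
  expect_length(sp3$test, 1)
  expect_error(split_proteins(dummy_proteins(1), 0.5, seed = 1),
               "at least 2")
})

test_that("exact-duplicate filtering keeps first occurrences in order", {
  a <- annotated_protein("A", "ASAAA")
  b <- annotated_protein("B", "ASAAA")
  c1 <- annotated_protein("C", "MSAAA", positive_sites = 2L)
  d <- annotated_protein("D", "ASAAA")
  e <- annotated_protein("E", "MSMMM", positive_sites = 2L)
  out <- dedup_exact(list(a, b, c1, d, e))
  expect_equal(vapply(out, `[[`, "", "id"), c("A", "C", "E"))
  expect_identical(dedup_exact(list(a, c1)), list(a, c1))
})

test_that("FASTA + site table round trip preserves annotations", {
  sim <- generate_proteome(generator_config(n_proteins = 8, seed = 2))
  fa <- tempfile(fileext = ".fasta")
  st <- tempfile(fileext = ".tsv")
  write_proteome(sim$proteins, fa, st)
  back <- read_proteins(fa, st)
  expect_equal(names(back), names(sim$proteins))
  for (id in names(back)) {
    expect_equal(back[[id]]$sequence, sim$proteins[[id]]$sequence)
    expect_equal(back[[id]]$positive_sites,
                 sim$proteins[[id]]$positive_sites)
  }
  expect_error(read_site_table({
    f <- tempfile()
    writeLines(c("protein_id\tposition", "X\t3"), f)
    f
  }), "must have columns")
})

test_that("window file round trip preserves peptides, labels and w", {
  ws <- random_window_set(5, 10, seed = 6)
  f <- tempfile(fileext = ".txt")
  write_windows(ws, f)
  back <- read_windows(f)
  expect_equal(attr(back, "w"), attr(ws, "w"))
  expect_equal(back$peptide, ws$peptide)
  expect_equal(as.character(back$label), as.character(ws$label))
})
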