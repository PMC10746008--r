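test_that("FASTA round trip preserves records and normalizes U to T", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a site info", "ACGUacgu-N", ">b", "ACGTACGTTT"), tmp)
  x <- read_fasta(tmp, aligned = TRUE)
  expect_equal(nrow(x), 2L)
  expect_equal(x$id, c("a", "b"))
  expect_equal(x$header[1], "a site info")
  expect_equal(x$seq[1], "ACGTACGT-N")

  out <- tempfile(fileext = ".fasta")
  write_fasta(x, out)
  y <- read_fasta(out, aligned = TRUE)
  expect_equal(y$seq, x$seq)
  expect_equal(y$header, x$header)
})

test_that("read_fasta rejects ragged alignments and empty files", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGTT"), tmp)
  expect_error(read_fasta(tmp, aligned = TRUE), "unequal length")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("hamming differences honor pairwise deletion and match the naive oracle", {
  expect_equal(hamming_differences("ACGT-", "ACGA-"),
               list(n_diff = 1L, n_compared = 4L))
  # identity
  expect_equal(hamming_differences("ACGT", "ACGT")$n_diff, 0L)
  # ambiguity columns are dropped under pairwise deletion
  h <- hamming_differences("ACGTN", "ACGAR")
  expect_equal(h$n_compared, 4L)
  # strict mode refuses ambiguity
  expect_error(hamming_differences("ACGN", "ACGT", policy = "strict"),
               "strict")
  expect_error(hamming_differences("ACG", "ACGT"), "unequal")

  set.seed(41)
  for (i in 1:10) {
    a <- random_seq(200, c("A", "C", "G", "T", "-", "N"))
    b <- random_seq(200, c("A", "C", "G", "T", "-", "N"))
    expect_equal(hamming_differences(a, b), naive_hamming(a, b))
  }
})

test_that("pairwise identity complements the p-distance", {
  # one difference over 741 comparable sites
  a <- strrep("A", 741)
  b <- paste0(strrep("A", 740), "C")
  expect_equal(pairwise_identity(a, b), 1 - 1 / 741)
  set.seed(7)
  x <- random_seq(300); y <- random_seq(300)
  h <- naive_hamming(x, y)
  expect_equal(pairwise_identity(x, y) + h$n_diff / h$n_compared, 1)
})

test_that("Jukes-Cantor correction matches the closed form and its properties", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.01), -0.75 * log(1 - 0.04 / 3), tolerance = 1e-12)
  expect_equal(jc_distance(0.01), 0.0100672652491, tolerance = 1e-10)
  expect_equal(jc_distance(0.10), 0.1073256327305, tolerance = 1e-10)
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(diff(d) > 0))          # strictly increasing
  expect_true(all(diff(diff(d)) > 0))    # convex
  expect_true(all(d[-1] > p[-1]))        # d > p away from zero
  expect_warning(ds <- jc_distance(0.8, saturated = Inf), "saturation")
  expect_identical(ds, Inf)
})

test_that("distance matrices are symmetric, zero-diagonal, and oracle-exact", {
  aln <- make_aln(c("ACGTACGTAC", "ACGTACGTAT", "ACGTACGTAC", "TCGTACGAAC"))
  dm <- distance_matrix(aln, "p_distance")
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
  for (i in 1:3) for (j in (i + 1):4) {
    h <- naive_hamming(aln$seq[i], aln$seq[j])
    expect_equal(dm$d[i, j], h$n_diff / h$n_compared)
  }
  # identical records give the zero matrix
  dm0 <- distance_matrix(make_aln(rep("ACGTACGT", 3)), "p_distance")
  expect_true(all(dm0$d == 0))
  # JC correction dominates the p-distance entrywise (below saturation)
  set.seed(5)
  base <- random_seq(120)
  mutated <- vapply(1:6, function(i) {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(120, 25)
    ch[pos] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  aln2 <- make_aln(mutated)
  p <- distance_matrix(aln2, "p_distance")$d
  jc <- distance_matrix(aln2, "jc_corrected")$d
  expect_true(all(jc >= p))
})

test_that("group divergence reproduces brute-force within/among summaries", {
  set.seed(13)
  aln <- make_aln(replicate(8, random_seq(150)))
  groups <- tibble::tibble(id = aln$id, group = rep(c("g1", "g2"), each = 4))
  gd <- group_divergence(aln, groups)
  dm <- distance_matrix(aln, "p_distance")$d * 100
  within1 <- dm[1:4, 1:4][upper.tri(diag(4))]
  among <- as.vector(dm[1:4, 5:8])
  expect_equal(gd$min_pct[gd$group_a == "g1" & gd$group_b == "g1"],
               min(within1))
  expect_equal(gd$max_pct[gd$group_a == "g1" & gd$group_b == "g2"],
               max(among))
  expect_equal(gd$n_pairs[gd$group_a == "g1" & gd$group_b == "g2"], 16L)

  # identical sequences in a group give (0, 0); one-group partition spans the
  # global off-diagonal range
  aln3 <- make_aln(c(rep("ACGTACGT", 2), "ACGAACGT"))
  gd3 <- group_divergence(aln3, setNames(c("x", "x", "x"), aln3$id))
  expect_equal(gd3$min_pct, min(distance_matrix(aln3, "p_distance")$d[
    upper.tri(diag(3))] * 100))
  # singleton groups are omitted
  expect_message(
    gd4 <- group_divergence(aln3, setNames(c("x", "x", "y"), aln3$id)),
    "singleton")
  expect_false(any(gd4$group_a == "y" & gd4$group_b == "y"))
})

test_that("clone tallies count copies, order deterministically, and conserve records", {
  lib <- simulate_clone_library(c(A = 10L, B = 10L, L = 3L), singletons = 0L,
                                L = 100L, seed = 2)
  tal <- clone_tally(lib)
  expect_equal(tal$count, c(10L, 10L, 3L))
  expect_equal(attr(tal, "n_singletons"), 0L)
  expect_equal(sum(tal$count), nrow(lib))

  # all-distinct input gives n singletons
  distinct <- make_aln(c("AAAA", "AAAC", "AACC", "ACCC"))
  td <- clone_tally(distinct)
  expect_equal(attr(td, "n_singletons"), 4L)

  # random multiset matches a brute-force counter; gaps are ignored
  set.seed(3)
  base <- replicate(5, random_seq(30))
  counts <- sample(1:6, 5, replace = TRUE)
  recs <- make_aln(sample(rep(base, counts)))
  recs$seq[1] <- paste0(substr(recs$seq[1], 1, 10), "-",
                        substr(recs$seq[1], 11, 30))
  tt <- clone_tally(recs)
  expect_equal(sum(tt$count), nrow(recs))
  expect_equal(sort(tt$count),
               sort(as.integer(table(gsub("-", "", recs$seq)))))
})

test_that("dilution density bound is exact arithmetic", {
  expect_equal(dilution_density_bound(5e-7, 0.1), 2e7)
  expect_equal(dilution_density_bound(1, 1), 1)
  expect_equal(dilution_density_bound(1e-3, 1), 1e3)
  expect_error(dilution_density_bound(0, 1), "range")
  expect_error(dilution_density_bound(0.5, 0), "range")
})
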