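# fixtures built in code; no binary data

make_aln <- function(seqs, ids = sprintf("s%02d", seq_along(seqs))) {
  tibble::tibble(id = ids, seq = toupper(seqs), header = ids,
                 site_id = NA_character_, source = "synthetic")
}

random_seq <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# independent brute-force pairwise comparison (naive loop oracle)
naive_hamming <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  plain <- c("A", "C", "G", "T")
  keep <- ca %in% plain & cb %in% plain
  list(n_diff = sum(ca[keep] != cb[keep]), n_compared = sum(keep))
}

# naive restriction-site oracle: fixed-width site scan
naive_digest <- function(seq, site, cut) {
  seq <- toupper(seq)
  n <- nchar(seq)
  w <- nchar(site)
  starts <- which(vapply(seq_len(n - w + 1L),
                         function(i) substr(seq, i, i + w - 1L) == site,
                         logical(1)))
  cuts <- sort(unique(starts - 1L + cut))
  cuts <- cuts[cuts > 0 & cuts < n]
  sort(diff(c(0L, cuts, n)))
}

# sliding-window primer-match oracle with IUPAC semantics
naive_primer_hits <- function(primer, template, max_mm) {
  expand <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  p <- strsplit(toupper(primer), "")[[1]]
  t <- strsplit(toupper(template), "")[[1]]
  out <- NULL
  for (i in seq_len(length(t) - length(p) + 1L)) {
    mm <- 0L
    for (k in seq_along(p)) {
      if (!length(intersect(expand[[p[k]]], expand[[t[i + k - 1L]]])))
        mm <- mm + 1L
    }
    if (mm <= max_mm) out <- rbind(out, c(pos = i - 1L, mm = mm))
  }
  out
}
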