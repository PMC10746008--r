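test_that("primer matching follows IUPAC semantics and the sliding-window oracle", {
  # R = {A, G}: both templates match with 0 mismatches
  expect_equal(match_primer("ART", "AAT")$mismatches, 0L)
  expect_equal(match_primer("ART", "AGT")$mismatches, 0L)

  # a verbatim primer is always reported at its position
  tmpl <- paste0("TTTTT", "GGGGGTTAAATCCATGTG", "AAAAA")
  hits <- match_primer("GGGGGTTAAATCCATGTG", tmpl)
  expect_true(any(hits$position == 5L & hits$strand == "+"))

  # reverse strand: the reverse complement is found as a minus-strand hit
  rc <- reverse_complement("GGGGGTTAAATCCATGTG")
  hits_rc <- match_primer("GGGGGTTAAATCCATGTG", paste0("AC", rc, "CA"))
  expect_true(any(hits_rc$strand == "-" & hits_rc$position == 2L))

  # random primer/template agree with the brute-force oracle on both strands
  set.seed(11)
  for (i in 1:5) {
    primer <- random_seq(8)
    template <- random_seq(300)
    got <- match_primer(primer, template, max_mismatches = 2L)
    plus <- naive_primer_hits(primer, template, 2L)
    minus <- naive_primer_hits(reverse_complement(primer), template, 2L)
    expect_equal(got$position[got$strand == "+"],
                 if (is.null(plus)) integer(0) else as.integer(plus[, "pos"]))
    expect_equal(got$mismatches[got$strand == "-"],
                 if (is.null(minus)) integer(0) else
                   as.integer(minus[, "mm"]))
  }

  expect_message(none <- match_primer("ACGTACGTACGT", "ACG"), "longer")
  expect_equal(nrow(none), 0L)
})

test_that("in-silico PCR pairs oriented hits and reports exact coordinates", {
  fwd <- "GATTACAGATTACAGATT"          # 18 nt
  rev_site <- "CCGGTTAACCGGTTAAC"      # 17 nt, on the plus strand
  rev <- reverse_complement(rev_site)  # primer as synthesized (binds minus)
  template <- paste0("TTTTT", fwd,
                     "ACACACACACACACACA", rev_site,
                     "TTT")
  hits <- in_silico_pcr(fwd, rev, template)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$fwd_start, 5L)
  expect_equal(hits$rev_end, 5L + 18L + 17L + 17L)
  expect_equal(hits$length, 52L)
  expect_equal(nchar(hits$amplicon_seq), hits$length)
  expect_equal(hits$length, hits$rev_end - hits$fwd_start)

  # same-strand hits only: no product
  both_fwd <- paste0(fwd, "AAAA", fwd)
  expect_equal(nrow(in_silico_pcr(fwd, fwd, both_fwd)), 0L)

  # template identical to the amplicon: full-length product
  amp <- hits$amplicon_seq
  again <- in_silico_pcr(fwd, rev, amp)
  expect_equal(again$length, nchar(amp))
})

test_that("restriction digestion matches forced examples and the naive oracle", {
  expect_equal(digest("AACCGGTT", "MspI"), c(3L, 5L))
  expect_equal(digest("TTGCGCAA", "HhaI"), c(3L, 5L))
  expect_error(digest("ACGT", "EcoRI"), "unknown enzyme")

  set.seed(23)
  for (i in 1:8) {
    s <- random_seq(500)
    expect_equal(digest(s, "MspI"), naive_digest(s, "CCGG", 1L))
    expect_equal(digest(s, "HhaI"), naive_digest(s, "GCGC", 3L))
  }
  # fragment lengths always sum to the template length
  for (i in 1:8) {
    s <- random_seq(200, c("C", "G"))  # site-rich
    expect_equal(sum(digest(s, "MspI")), 200L)
  }
})

test_that("the bundled primer table carries the screening primers verbatim", {
  p <- primer_set()
  expect_setequal(p$name, c("27F", "1492R", "GS.619F", "GS.1144R",
                            "GSB600F", "1392R"))
  expect_equal(p$seq[p$name == "GSB600F"], "GGGGGTTAAATCCATGTG")
  expect_equal(p$seq[p$name == "GS.1144R"], "CAGTTCARTTAGAGTCC")
})

test_that("RFLP typing groups by tolerance with transitive closure", {
  mk <- function(id, msp, hha) {
    tibble::tibble(sequence_id = id, enzyme = c("MspI", "HhaI"),
                   fragments = list(sort(msp), sort(hha)))
  }
  profs <- dplyr::bind_rows(
    mk("a", c(100, 200), c(50, 250)),
    mk("b", c(104, 200), c(50, 250)),  # within 5% of a
    mk("c", c(108, 200), c(50, 250)),  # beyond 5% of a, within 5% of b
    mk("d", c(300), c(150, 150))       # different fragment count
  )
  ty <- rflp_type_assign(profs, size_tolerance = 0.05, abs_floor = 0)
  t_of <- setNames(ty$rflp_type, ty$sequence_id)
  expect_equal(t_of[["a"]], t_of[["b"]])
  # transitive closure: c joins a's type through b (|108-104| <= 0.05*108,
  # although |108-100| > 0.05*108)
  expect_equal(t_of[["b"]], t_of[["c"]])
  expect_false(t_of[["a"]] == t_of[["d"]])

  # tolerance zero groups iff identical
  ty0 <- rflp_type_assign(profs, size_tolerance = 0)
  expect_equal(length(unique(ty0$rflp_type)), 4L)
  ty_same <- rflp_type_assign(dplyr::bind_rows(mk("x", c(10, 20), c(5, 25)),
                                               mk("y", c(10, 20), c(5, 25))),
                              size_tolerance = 0)
  expect_equal(length(unique(ty_same$rflp_type)), 1L)

  # inconsistent enzyme sets are rejected
  bad <- dplyr::bind_rows(mk("a", c(1, 2), c(1, 2))[1, ],
                          mk("b", c(1, 2), c(1, 2)))
  expect_error(rflp_type_assign(bad), "inconsistent")
})

test_that("full RFLP typing pipeline separates divergent amplicons", {
  set.seed(9)
  s1 <- random_seq(600)
  aln <- make_aln(c(s1, s1, random_seq(600)))
  profs <- rflp_profile(aln)
  expect_true(all(vapply(seq_len(nrow(profs)), function(i)
    sum(profs$fragments[[i]]) == 600L, logical(1))))
  ty <- rflp_type_assign(profs, size_tolerance = 0)
  expect_equal(ty$rflp_type[1], ty$rflp_type[2])
})
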