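# Fragment-based average nucleotide identity between two genomes.
#
# The query genome is chopped into consecutive non-overlapping fragments
# (1020 nt by default, the fragment-based convention); each fragment is
# mapped onto the reference with a k-mer-seeded banded aligner on both
# strands; fragments matching at >= 70% identity over >= 70% of their length
# are retained; one-way ANI is the mean identity of retained fragments and
# two-way ANI is the mean of the two directions.

#' ANI settings
#'
#' @param frag_len fragment length in nt (>= 100).
#' @param min_identity identity threshold (percent) for retaining a fragment.
#' @param min_coverage minimum aligned fraction of the fragment.
#' @param k seed k-mer length.
#' @param step spacing of fragment k-mers probed against the reference index.
#' @param band_frac alignment band half-width as a fraction of fragment
#'   length.
#' @param max_diags candidate diagonals aligned per strand.
#' @return a list of settings.
#' @export
ani_settings <- function(frag_len = 1020L, min_identity = 70,
                         min_coverage = 0.7, k = 15L, step = 5L,
                         band_frac = 0.05, max_diags = 3L) {
  if (frag_len < 100L) stop("frag_len must be >= 100", call. = FALSE)
  list(frag_len = as.integer(frag_len), min_identity = min_identity,
       min_coverage = min_coverage, k = as.integer(k), step = as.integer(step),
       band_frac = band_frac, max_diags = as.integer(max_diags))
}

genome_as_records <- function(genome) {
  if (is.data.frame(genome)) return(toupper(degap(genome$seq)))
  toupper(degap(as.character(genome)))
}

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `frag_len` nt per record (fragments never span
#' record boundaries); the terminal remainder shorter than `frag_len` is
#' discarded.
#'
#' @param genome a sequence tibble ([read_fasta()]) or character vector of
#'   record sequences.
#' @param frag_len fragment length (>= 100 nt).
#' @return a character vector of fragments.
#' @export
fragment_genome <- function(genome, frag_len = 1020L) {
  if (frag_len < 100L) stop("frag_len must be >= 100", call. = FALSE)
  recs <- genome_as_records(genome)
  frags <- unlist(lapply(recs, function(s) {
    n <- nchar(s) %/% frag_len
    if (n == 0L) return(character(0))
    starts <- (seq_len(n) - 1L) * frag_len + 1L
    substring(s, starts, starts + frag_len - 1L)
  }))
  if (!length(frags)) message("genome shorter than one fragment; no fragments")
  frags
}

#' Map a fragment onto a reference genome
#'
#' Finds the best local match of the fragment on either strand of the
#' reference: k-mer seeds vote on candidate diagonals, which are then scored
#' with a banded alignment (fragment global, reference local).
#'
#' @param fragment a fragment string.
#' @param reference reference genome (sequence tibble or character vector of
#'   records; records are indexed jointly).
#' @param settings an [ani_settings()] list.
#' @return a tibble with `identity` (percent of fragment positions matching)
#'   and `aligned_fraction`.
#' @export
map_fragment <- function(fragment, reference, settings = ani_settings()) {
  ref <- paste(genome_as_records(reference), collapse = strrep("N", 50))
  m <- cpp_ani_map(fragment, ref, settings$k, settings$step,
                   settings$band_frac, settings$max_diags)
  tibble::tibble(identity = m[, 1], aligned_fraction = m[, 2])
}

ani_oneway <- function(query, reference, settings) {
  frags <- fragment_genome(query, settings$frag_len)
  if (!length(frags))
    return(list(ani = NA_real_, used = 0L, total = 0L))
  ref <- paste(genome_as_records(reference), collapse = strrep("N", 50))
  m <- cpp_ani_map(frags, ref, settings$k, settings$step, settings$band_frac,
                   settings$max_diags)
  keep <- m[, 1] >= settings$min_identity & m[, 2] >= settings$min_coverage
  if (!any(keep)) {
    warning("no fragments retained in one direction: ANI undefined",
            call. = FALSE)
    return(list(ani = NA_real_, used = 0L, total = length(frags)))
  }
  list(ani = mean(m[keep, 1]), used = sum(keep), total = length(frags))
}

#' Two-way average nucleotide identity between two genomes
#'
#' @param genome_a,genome_b sequence tibbles or character vectors of genome
#'   records.
#' @param settings an [ani_settings()] list.
#' @return an `ani_result`: tibble with `ani_qr` (a vs b), `ani_rq` (b vs
#'   a), `two_way`, `fragments_total_qr`, `fragments_used_qr`,
#'   `fragments_total_rq`, `fragments_used_rq`.
#' @export
ani_twoway <- function(genome_a, genome_b, settings = ani_settings()) {
  qr <- ani_oneway(genome_a, genome_b, settings)
  rq <- ani_oneway(genome_b, genome_a, settings)
  out <- tibble::tibble(
    ani_qr = qr$ani, ani_rq = rq$ani,
    two_way = mean(c(qr$ani, rq$ani)),
    fragments_total_qr = qr$total, fragments_used_qr = qr$used,
    fragments_total_rq = rq$total, fragments_used_rq = rq$used
  )
  class(out) <- c("ani_result", class(out))
  out
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf(
    "<ani_result> two-way ANI = %.2f%% (a->b %.2f%% on %d/%d fragments; b->a %.2f%% on %d/%d)\n",
    x$two_way, x$ani_qr, x$fragments_used_qr, x$fragments_total_qr,
    x$ani_rq, x$fragments_used_rq, x$fragments_total_rq))
  invisible(x)
}
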