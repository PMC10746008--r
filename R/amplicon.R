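# In-silico primer matching, PCR, restriction digestion and RFLP typing.
#
# Coordinates are 0-based half-open throughout; reverse-strand primer hits
# are reported in plus-strand coordinates.

#' Bundled PCR primer set
#'
#' The 16S rRNA primers used for screening green sulfur bacteria:
#' eubacterial 27F, universal 1492R and 1392R, and the GSB-targeted GS.619F,
#' GS.1144R and GSB600F.
#'
#' @return a tibble with `name`, `specificity`, `seq` (5'->3'), `role`.
#' @export
primer_set <- function() {
  path <- system.file("extdata", "primers.tsv", package = "ecotypesim",
                      mustWork = TRUE)
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

primer_seq <- function(primer) {
  if (is.character(primer) && length(primer) == 1L) return(toupper(primer))
  if (is.data.frame(primer) && nrow(primer) == 1L && "seq" %in% names(primer))
    return(toupper(primer$seq))
  stop("primer must be a single IUPAC string or a one-row primer table",
       call. = FALSE)
}

# mismatch counts of `primer` against every window of `template` (plus strand)
window_mismatches <- function(primer, template) {
  pm <- iupac_mask(primer)
  tm <- iupac_mask(template)
  np <- length(pm); nt <- length(tm)
  if (np > nt) return(integer(0))
  n_win <- nt - np + 1L
  mism <- integer(n_win)
  # one pass per primer position; bitwAnd is vectorized over windows
  for (k in seq_len(np)) {
    mism <- mism + as.integer(bitwAnd(pm[k], tm[k:(k + n_win - 1L)]) == 0L)
  }
  mism
}

#' Match a primer against a template sequence
#'
#' Scans the plus strand with the primer and the minus strand with its
#' reverse complement. IUPAC codes in primer and template match when their
#' base sets intersect. Mismatch counting is positionally uniform (no 3'-end
#' weighting).
#'
#' @param primer an IUPAC primer string (5'->3') or one row of
#'   [primer_set()].
#' @param template a template sequence string (gaps are removed) or one row
#'   of a sequence tibble.
#' @param max_mismatches maximum mismatches per hit.
#' @return a tibble with `position` (0-based window start on the plus
#'   strand), `strand` (`"+"`/`"-"`), and `mismatches`, sorted by position.
#' @export
match_primer <- function(primer, template, max_mismatches = 0L) {
  p <- primer_seq(primer)
  tmpl <- if (is.data.frame(template)) template$seq[1] else template
  tmpl <- degap(toupper(tmpl))
  if (nchar(p) > nchar(tmpl)) {
    message("primer longer than template; no hits")
    return(tibble::tibble(position = integer(0), strand = character(0),
                          mismatches = integer(0)))
  }
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") p else reverse_complement(p)
    mism <- window_mismatches(q, tmpl)
    sel <- which(mism <= max_mismatches)
    if (length(sel))
      hits[[strand]] <- tibble::tibble(position = sel - 1L, strand = strand,
                                       mismatches = mism[sel])
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L)
    return(tibble::tibble(position = integer(0), strand = character(0),
                          mismatches = integer(0)))
  dplyr::arrange(out, .data$position, .data$strand)
}

#' In-silico PCR with a primer pair
#'
#' The forward primer is matched on the plus strand and the reverse primer
#' (given 5'->3' as synthesized, i.e. binding the minus strand) is matched as
#' its reverse complement downstream on the plus strand. Every compatible
#' pair of hits with product length at most `max_len` yields one amplicon;
#' the amplicon includes both primer footprints.
#'
#' @param fwd,rev primer strings or single rows of [primer_set()].
#' @param template template sequence (string or one-row sequence tibble).
#' @param max_mismatches maximum mismatches per primer.
#' @param max_len maximum product length (nt).
#' @return a tibble with `template_id`, `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end` (0-based half-open, plus strand), `length`, `amplicon_seq`,
#'   `fwd_mismatches`, `rev_mismatches`.
#' @export
in_silico_pcr <- function(fwd, rev, template, max_mismatches = 0L,
                          max_len = Inf) {
  tmpl_id <- if (is.data.frame(template)) template$id[1] else NA_character_
  tmpl <- if (is.data.frame(template)) template$seq[1] else template
  tmpl <- degap(toupper(tmpl))
  fwd_len <- nchar(primer_seq(fwd))
  rev_len <- nchar(primer_seq(rev))
  fh <- dplyr::filter(match_primer(fwd, tmpl, max_mismatches),
                      .data$strand == "+")
  rh <- dplyr::filter(match_primer(rev, tmpl, max_mismatches),
                      .data$strand == "-")
  empty <- tibble::tibble(
    template_id = character(0), fwd_start = integer(0), fwd_end = integer(0),
    rev_start = integer(0), rev_end = integer(0), length = integer(0),
    amplicon_seq = character(0), fwd_mismatches = integer(0),
    rev_mismatches = integer(0))
  if (nrow(fh) == 0L || nrow(rh) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(fh))) {
    for (j in seq_len(nrow(rh))) {
      fs <- fh$position[i]
      re <- rh$position[j] + rev_len
      len <- re - fs
      if (fs >= re || len > max_len) next
      out[[length(out) + 1L]] <- tibble::tibble(
        template_id = tmpl_id,
        fwd_start = fs, fwd_end = fs + fwd_len,
        rev_start = rh$position[j], rev_end = re,
        length = len,
        amplicon_seq = substr(tmpl, fs + 1L, re),
        fwd_mismatches = fh$mismatches[i],
        rev_mismatches = rh$mismatches[j])
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

# built-in restriction enzymes: recognition site and cut offset (bases after
# which the cut falls, counted from the site start on the plus strand)
RESTRICTION_ENZYMES <- list(
  MspI = list(site = "CCGG", cut = 1L), # C^CGG
  HhaI = list(site = "GCGC", cut = 3L)  # GCG^C
)

#' Restriction digest of a linear sequence
#'
#' Cuts at every occurrence of the recognition site (overlapping occurrences
#' each cut; sites are scanned left to right on the plus strand -- both
#' built-in enzymes are palindromic, so strand choice is immaterial).
#'
#' @param template a sequence string (gaps removed) or one-row sequence
#'   tibble.
#' @param enzyme `"MspI"` or `"HhaI"`.
#' @return sorted ascending fragment lengths (nt); they sum to the template
#'   length.
#' @export
digest <- function(template, enzyme) {
  tmpl <- if (is.data.frame(template)) template$seq[1] else template
  tmpl <- degap(toupper(tmpl))
  enz <- RESTRICTION_ENZYMES[[enzyme]]
  if (is.null(enz))
    stop("unknown enzyme '", enzyme, "'; available: ",
         paste(names(RESTRICTION_ENZYMES), collapse = ", "), call. = FALSE)
  n <- nchar(tmpl)
  # overlapping matches via lookahead
  m <- gregexpr(paste0("(?=", enz$site, ")"), tmpl, perl = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer(0) else as.integer(m)
  cuts <- sort(unique(starts - 1L + enz$cut))   # 0-based cut positions
  cuts <- cuts[cuts > 0L & cuts < n]
  bounds <- c(0L, cuts, n)
  frags <- diff(bounds)
  stopifnot(sum(frags) == n)
  sort(frags)
}

#' RFLP profile of a sequence for a set of enzymes
#'
#' @param x a sequence tibble.
#' @param enzymes enzyme names (default both built-ins).
#' @return a tibble with `sequence_id`, `enzyme`, and a list-column
#'   `fragments` of sorted fragment lengths.
#' @export
rflp_profile <- function(x, enzymes = c("MspI", "HhaI")) {
  validate_seq_tbl(x)
  tidyr::expand_grid(sequence_id = x$id, enzyme = enzymes) |>
    dplyr::left_join(dplyr::select(x, sequence_id = "id", "seq"),
                     by = "sequence_id") |>
    dplyr::mutate(fragments = purrr::map2(.data$seq, .data$enzyme, digest)) |>
    dplyr::select("sequence_id", "enzyme", "fragments")
}

#' Group RFLP profiles into gel-resolvable types
#'
#' Two profiles are directly equivalent when, for every enzyme, they have the
#' same fragment count and each size-ordered fragment pair differs by at most
#' the tolerance (relative, with an absolute floor mimicking gel resolution).
#' Types are the transitive closure of this relation, numbered by first
#' occurrence.
#'
#' @param profiles output of [rflp_profile()] (same enzyme set for all
#'   sequences).
#' @param size_tolerance relative fragment-size tolerance (default 0.05).
#' @param abs_floor absolute size tolerance floor in nt (default 4; ignored
#'   when `size_tolerance` is 0, so tolerance 0 means exact equality).
#' @return a tibble with `sequence_id` and integer `rflp_type`.
#' @export
rflp_type_assign <- function(profiles, size_tolerance = 0.05, abs_floor = 4) {
  ids <- unique(profiles$sequence_id)
  enz_sets <- tapply(profiles$enzyme, profiles$sequence_id,
                     function(e) paste(sort(e), collapse = "/"))
  if (length(unique(enz_sets)) != 1L)
    stop("profiles were digested with inconsistent enzyme sets", call. = FALSE)
  frag_of <- function(id) {
    rows <- profiles[profiles$sequence_id == id, ]
    setNames(rows$fragments, rows$enzyme)
  }
  cache <- lapply(ids, frag_of)
  names(cache) <- ids
  equivalent <- function(fa, fb) {
    for (e in names(fa)) {
      a <- fa[[e]]; b <- fb[[e]]
      if (length(a) != length(b)) return(FALSE)
      tol <- if (size_tolerance == 0) 0 else
        pmax(size_tolerance * pmax(a, b), abs_floor)
      if (any(abs(a - b) > tol)) return(FALSE)
    }
    TRUE
  }
  # union-find over profiles
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (equivalent(cache[[i]], cache[[j]]))
        parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  type_id <- match(roots, unique(roots))
  tibble::tibble(sequence_id = ids, rflp_type = type_id)
}
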