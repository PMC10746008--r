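# Sequence input/output, pairwise distances and clone tallies.
#
# Sequence collections are plain tibbles with columns:
#   id     - unique label (first whitespace-delimited token of the header)
#   seq    - nucleotide string (U normalized to T on ingest, uppercase)
#   header - the full FASTA description line
#   site_id, source - optional metadata carried alongside

new_seq_tbl <- function(id, seq, header = id, site_id = NA_character_,
                        source = NA_character_) {
  tibble::tibble(id = id, seq = toupper(seq), header = header,
                 site_id = site_id, source = source)
}

validate_seq_tbl <- function(x, aligned = FALSE) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x)))
    stop("expected a sequence table with columns `id` and `seq`", call. = FALSE)
  if (nrow(x) == 0L) stop("empty sequence collection", call. = FALSE)
  if (any(!nzchar(x$id)) || anyNA(x$id))
    stop("sequence ids must be nonempty", call. = FALSE)
  if (anyDuplicated(x$id))
    stop("duplicate sequence id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(x$seq))) stop("empty sequence(s) present", call. = FALSE)
  if (aligned && length(unique(nchar(x$seq))) != 1L)
    stop("alignment has records of unequal length", call. = FALSE)
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Reads nucleotide FASTA. `U`/`u` is normalized to `T` on ingest and
#' sequences are stored uppercase. The record id is the first
#' whitespace-delimited token of the description line; the full line is kept
#' in the `header` column.
#'
#' @param path path to a FASTA file.
#' @param aligned if `TRUE`, require all records to have equal length and
#'   treat the result as an alignment.
#' @return a tibble with columns `id`, `seq`, `header`, `site_id`, `source`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  out <- new_seq_tbl(id = ids, seq = unname(seqs), header = headers)
  validate_seq_tbl(out, aligned = aligned)
  out
}

#' Write sequences to a FASTA file
#'
#' @param x a sequence tibble (see [read_fasta()]).
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  validate_seq_tbl(x)
  headers <- if ("header" %in% names(x)) x$header else x$id
  set <- Biostrings::BStringSet(setNames(x$seq, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# columns retained for comparison under each policy
comparable_mask <- function(a, b, policy) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  plain <- c("A", "C", "G", "T")
  if (policy == "strict") {
    bad <- setdiff(unique(c(ca, cb)), plain)
    if (length(bad))
      stop("strict policy: ambiguous or gap symbol(s) present: ",
           paste(bad, collapse = ", "), call. = FALSE)
    return(rep(TRUE, length(ca)))
  }
  ca %in% plain & cb %in% plain
}

#' Count nucleotide differences between two aligned sequences
#'
#' Under the default `pairwise_deletion` policy, columns in which either
#' sequence carries a gap (`-`, `.`) or an IUPAC ambiguity code are excluded;
#' differences are counted over the retained columns only. Under `strict`,
#' any non-ACGT symbol is an error.
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @param policy `"pairwise_deletion"` (default) or `"strict"`.
#' @return a list with `n_diff` and `n_compared`.
#' @export
hamming_differences <- function(a, b,
                                policy = c("pairwise_deletion", "strict")) {
  policy <- match.arg(policy)
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  keep <- comparable_mask(a, b, policy)
  n_compared <- sum(keep)
  if (n_compared == 0L)
    stop("degenerate comparison: no comparable columns", call. = FALSE)
  ca <- strsplit(a, "")[[1]][keep]
  cb <- strsplit(b, "")[[1]][keep]
  list(n_diff = sum(ca != cb), n_compared = n_compared)
}

#' Pairwise sequence identity
#'
#' Identity is `1 - n_diff / n_compared` under the chosen comparison policy.
#'
#' @inheritParams hamming_differences
#' @return identity as a proportion in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b,
                              policy = c("pairwise_deletion", "strict")) {
  h <- hamming_differences(a, b, policy = match.arg(policy))
  1 - h$n_diff / h$n_compared
}

#' Jukes-Cantor distance correction
#'
#' Maps an observed proportion of differing sites `p` to the expected number
#' of substitutions per site, `d = -(3/4) log(1 - (4/3) p)`. The correction
#' is monotone and convex, with `d >= p` and equality only at zero.
#'
#' @param p observed p-distance(s) in `[0, 0.75)`.
#' @param saturated value returned (with a warning) where `p >= 0.75`.
#' @return corrected distance(s).
#' @export
jc_distance <- function(p, saturated = Inf) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be nonnegative", call. = FALSE)
  sat <- !is.na(p) & p >= 0.75
  if (any(sat))
    warning("p-distance at or beyond the Jukes-Cantor saturation bound 0.75; ",
            "returning `saturated` value", call. = FALSE)
  out <- p # preserves shape (vector or matrix)
  out[] <- saturated
  out[is.na(p)] <- NA_real_
  ok <- !is.na(p) & !sat
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln an aligned sequence tibble (equal-length `seq` column).
#' @param kind `"p_distance"` (proportion of differing comparable sites),
#'   `"jc_corrected"` (Jukes-Cantor corrected), or `"identity"`
#'   (`1 - p_distance`).
#' @param policy comparison policy, see [hamming_differences()].
#' @param saturated value substituted for Jukes-Cantor-saturated pairs.
#' @return a `dist_matrix` object: list of `ids`, symmetric matrix `d`, and
#'   `kind`.
#' @export
distance_matrix <- function(aln,
                            kind = c("p_distance", "jc_corrected", "identity"),
                            policy = c("pairwise_deletion", "strict"),
                            saturated = Inf) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  validate_seq_tbl(aln, aligned = TRUE)
  if (nrow(aln) < 2L) stop("need at least two sequences", call. = FALSE)
  seqs <- toupper(aln$seq)
  if (policy == "strict") {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad))
      stop("strict policy: non-ACGT symbols in: ",
           paste(aln$id[bad], collapse = ", "), call. = FALSE)
  }
  cnt <- cpp_pdist_counts(seqs)
  ncomp <- cnt$ncomp
  diag(ncomp) <- NA_integer_
  degen <- which(ncomp == 0L, arr.ind = TRUE)
  if (nrow(degen)) {
    i <- degen[1, 1]; j <- degen[1, 2]
    stop("degenerate comparison (no comparable columns) between ",
         aln$id[i], " and ", aln$id[j], call. = FALSE)
  }
  p <- cnt$ndiff / cnt$ncomp
  diag(p) <- 0
  d <- switch(kind,
    p_distance = p,
    identity = 1 - p,
    jc_corrected = {
      m <- jc_distance(p, saturated = saturated)
      diag(m) <- 0
      m
    })
  dimnames(d) <- list(aln$id, aln$id)
  structure(list(ids = aln$id, d = d, kind = kind), class = "dist_matrix")
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$d

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> ", length(x$ids), " sequences, kind = ", x$kind, "\n",
      sep = "")
  print(head(round(x$d, 4), 6L))
  invisible(x)
}

#' @rdname distance_matrix
#' @param x a `dist_matrix`.
#' @param ... unused.
#' @export
tidy.dist_matrix <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    id_a = x$ids[idx[, 1]], id_b = x$ids[idx[, 2]],
    value = x$d[idx], kind = x$kind
  )
}

#' Within- and among-group sequence divergence
#'
#' For every pair of groups (and within each group) reports the minimum and
#' maximum percent divergence (`100 * p_distance`) over all sequence pairs.
#' Within-group summaries for singleton groups are omitted with a message.
#'
#' @param aln an aligned sequence tibble.
#' @param groups a data frame with columns `id` and `group`, or a named
#'   character vector mapping sequence id to group.
#' @param policy comparison policy, see [hamming_differences()].
#' @return a tibble with `group_a`, `group_b`, `min_pct`, `max_pct`,
#'   `n_pairs`.
#' @export
group_divergence <- function(aln, groups,
                             policy = c("pairwise_deletion", "strict")) {
  policy <- match.arg(policy)
  validate_seq_tbl(aln, aligned = TRUE)
  if (is.data.frame(groups)) {
    stopifnot(all(c("id", "group") %in% names(groups)))
    map <- setNames(as.character(groups$group), groups$id)
  } else {
    map <- groups
  }
  missing <- setdiff(aln$id, names(map))
  if (length(missing))
    stop("no group assignment for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- unname(map[aln$id])
  dm <- distance_matrix(aln, kind = "p_distance", policy = policy)
  pct <- 100 * dm$d
  glev <- unique(g)
  out <- list()
  for (ia in seq_along(glev)) {
    for (ib in ia:length(glev)) {
      sel_a <- which(g == glev[ia])
      sel_b <- which(g == glev[ib])
      if (ia == ib) {
        if (length(sel_a) < 2L) {
          message("singleton group '", glev[ia],
                  "': no within-group summary")
          next
        }
        pairs <- t(utils::combn(sel_a, 2L))
      } else {
        pairs <- as.matrix(expand.grid(sel_a, sel_b))
      }
      vals <- pct[cbind(pairs[, 1], pairs[, 2])]
      out[[length(out) + 1L]] <- tibble::tibble(
        group_a = glev[ia], group_b = glev[ib],
        min_pct = min(vals), max_pct = max(vals), n_pairs = nrow(pairs)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Tally identical clones in a sequence collection
#'
#' Two records are the same clone when their degapped, uppercased sequences
#' are identical. Tallies are sorted by descending copy number, ties broken
#' by order of first occurrence. The number of singleton sequences is
#' attached as attribute `n_singletons`.
#'
#' @param records a sequence tibble.
#' @return a tibble with `sequence`, `representative` (first id seen), and
#'   `count`; attribute `n_singletons` gives the singleton count.
#' @export
clone_tally <- function(records) {
  validate_seq_tbl(records)
  key <- toupper(degap(records$seq))
  first <- !duplicated(key)
  lev <- key[first]
  counts <- as.integer(table(factor(key, levels = lev)))
  ord <- order(-counts, seq_along(counts))
  out <- tibble::tibble(
    sequence = lev[ord],
    representative = records$id[first][ord],
    count = counts[ord]
  )
  stopifnot(sum(out$count) == nrow(records))
  attr(out, "n_singletons") <- sum(out$count == 1L)
  out
}

#' Lower bound on cell density from a dilution-to-extinction series
#'
#' If the highest dilution that still yields growth is `d` and the inoculum
#' volume is `v` mL, the source must have contained at least `1 / (d * v)`
#' cells per mL.
#'
#' @param highest_positive_dilution dilution factor in `(0, 1]`.
#' @param inoculum_volume_ml inoculum volume in mL (default 0.1 mL).
#' @return lower bound in cells per mL.
#' @export
dilution_density_bound <- function(highest_positive_dilution,
                                   inoculum_volume_ml = 0.1) {
  check_scalar_number(highest_positive_dilution, "dilution", lower = 0,
                      upper = 1, strict_lower = TRUE)
  check_scalar_number(inoculum_volume_ml, "inoculum volume", lower = 0,
                      strict_lower = TRUE)
  1 / (highest_positive_dilution * inoculum_volume_ml)
}
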