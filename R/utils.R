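# shared helpers

# IUPAC nucleotide codes as base-set bitmasks (A=1, C=2, G=4, T=8)
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

iupac_mask <- function(x) {
  m <- unname(IUPAC_MASK[strsplit(toupper(x), "")[[1]]])
  if (anyNA(m)) {
    bad <- setdiff(unique(strsplit(toupper(x), "")[[1]]), names(IUPAC_MASK))
    stop("non-IUPAC symbol(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param x a nucleotide string (IUPAC codes allowed).
#' @return the reverse complement as a string.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(strsplit(toupper(x), "")[[1]])
  out <- IUPAC_COMPLEMENT[ch]
  if (anyNA(out)) stop("cannot complement symbol(s): ",
                       paste(unique(ch[is.na(out)]), collapse = ", "),
                       call. = FALSE)
  paste(out, collapse = "")
}

degap <- function(x) gsub("[-.]", "", x)

# derive a reproducible substream seed from (seed, i); kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 9973) %% 2147483647) + 1L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(force(code))
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number", call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(name, " out of range", call. = FALSE)
  invisible(x)
}
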