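# Clade-by-environment association: eta-squared (between-group fraction of
# the total sum of squares) with a permutation null obtained by relabeling
# group assignments.

eta_squared <- function(values, groups) {
  mu <- mean(values)
  ss_total <- sum((values - mu)^2)
  if (ss_total <= 0)
    stop("zero total variance: association statistic undefined", call. = FALSE)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ss_between <- sum(gn * (gm - mu)^2)
  ss_between / ss_total
}

#' Test association between ecotype assignment and an environmental variable
#'
#' Computes eta-squared (`SS_between / SS_total`) of the variable across
#' groups and a permutation p-value under random relabeling of the group
#' assignments, with the add-one estimator
#' `p = (1 + #[eta2_perm >= eta2_obs]) / (1 + n_permutations)` (never exactly
#' zero).
#'
#' @param data a data frame with one row per sequence, containing the
#'   grouping column and the environmental variable.
#' @param variable name of the numeric environmental column (e.g.
#'   `"temperature"`).
#' @param group name of the grouping column (default `"ecotype"`).
#' @param n_permutations number of relabelings (default 999).
#' @param seed optional integer seed.
#' @return an `assoc_result` tibble: `variable`, `eta_squared`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
clade_env_association <- function(data, variable, group = "ecotype",
                                  n_permutations = 999L, seed = NULL) {
  stopifnot(is.data.frame(data), variable %in% names(data),
            group %in% names(data))
  values <- data[[variable]]
  groups <- as.factor(data[[group]])
  if (anyNA(values) || anyNA(groups))
    stop("missing metadata for some sequences", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least two groups", call. = FALSE)
  obs <- eta_squared(values, groups)
  # permuting the values against fixed labels is equivalent to relabeling;
  # group sizes, the grand mean and SS_total are permutation-invariant
  g <- as.integer(groups)
  gn <- tabulate(g)
  gn <- gn[gn > 0]
  glev <- sort(unique(g))
  gidx <- match(g, glev)
  mu <- mean(values)
  ss_total <- sum((values - mu)^2)
  n <- length(values)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    v <- values[sample.int(n)]
    gm <- rowsum(v, gidx, reorder = TRUE) / gn
    sum(gn * (gm - mu)^2) / ss_total
  }, numeric(1)))
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_permutations)
  out <- tibble::tibble(variable = variable, eta_squared = obs, p_value = p,
                        n_permutations = as.integer(n_permutations),
                        seed = if (is.null(seed)) NA_integer_ else
                          as.integer(seed))
  class(out) <- c("assoc_result", class(out))
  out
}
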