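# Monte-Carlo simulator of the Stable Ecotype Model and the match-fraction
# likelihood of a parameter triple against an observed binning curve.
#
# The model has three parameters: the ecotype formation rate (omega), the
# periodic selection rate (sigma), both per ecotype per unit branch length
# (expected substitutions/site), and the number of ecotypes (npop). Backward
# in time, periodic selection coalesces all lineages of an ecotype; an
# ecotype formation event, viewed backward, merges one ecotype into another.

#' Stable Ecotype Model parameters
#'
#' @param omega ecotype formation rate (events per ecotype per unit branch
#'   length, substitutions/site); `>= 0`.
#' @param sigma periodic selection rate (same units); `>= 0`.
#' @param npop number of ecotype (or geotype) populations; integer `>= 1`.
#' @return a `sem_params` object.
#' @export
sem_params <- function(omega, sigma, npop) {
  check_scalar_number(omega, "omega", lower = 0)
  check_scalar_number(sigma, "sigma", lower = 0)
  check_scalar_number(npop, "npop", lower = 1)
  structure(list(omega = omega, sigma = sigma, npop = as.integer(round(npop))),
            class = "sem_params")
}

#' @export
print.sem_params <- function(x, ...) {
  cat(sprintf("<sem_params> omega = %g, sigma = %g, npop = %d\n",
              x$omega, x$sigma, x$npop))
  invisible(x)
}

#' Match rule for comparing simulated and observed binning curves
#'
#' A replicate matches the observation when, at every criterion, the
#' observed bin count lies within a multiplicative band around the simulated
#' count, rounded outward to integers:
#' `floor(sim / tolerance) <= obs <= ceiling(sim * tolerance)`.
#'
#' @param tolerance multiplicative band, `>= 1` (1 = exact equality).
#' @param criteria identity criterion grid shared with the observed curve.
#' @return a `match_rule` object.
#' @export
match_rule <- function(tolerance = 1.1, criteria = binning_criteria()) {
  check_scalar_number(tolerance, "tolerance", lower = 1)
  structure(list(tolerance = tolerance, criteria = criteria),
            class = "match_rule")
}

curve_matches <- function(sim_bins, obs_bins, tolerance) {
  if (is.infinite(tolerance)) return(TRUE)
  lo <- floor(sim_bins / tolerance)
  hi <- ceiling(sim_bins * tolerance)
  all(obs_bins >= lo & obs_bins <= hi)
}

#' Simulate one replicate of the Stable Ecotype Model
#'
#' Backward in time, `n` sampled lineages are assigned uniformly to `npop`
#' ecotypes (conditioned on no ecotype being empty); each ecotype holding at
#' least two lineages suffers periodic selection at rate `sigma` (all its
#' lineages coalesce), and each ecotype merges into another at rate `omega`
#' while at least two ecotypes remain. The process stops at `depth`, where
#' remaining lineages join at the root. A random root sequence of length `L`
#' then evolves down the genealogy under Jukes-Cantor, with per-branch
#' substitution probability `(3/4)(1 - exp(-4 b / 3))`.
#'
#' @param params a [sem_params()] triple.
#' @param n sample size (number of leaves), `>= 2`.
#' @param depth total backward time to the root, in substitutions/site.
#' @param L sequence length (nt).
#' @param criteria identity criterion grid for the replicate's binning curve.
#' @param seed optional integer seed (bit-reproducible given the seed).
#' @param full if `FALSE`, return only the binning curve (fast path).
#' @return a `sem_replicate`: list with `curve` (a `binning_curve`), and if
#'   `full`, `genealogy` (an [ape::phylo] ultrametric tree, branch lengths in
#'   substitutions/site) and `alignment` (a sequence tibble).
#' @export
simulate_replicate <- function(params, n, depth, L,
                               criteria = binning_criteria(), seed = NULL,
                               full = TRUE) {
  stopifnot(inherits(params, "sem_params"))
  check_scalar_number(n, "n", lower = 2)
  check_scalar_number(depth, "depth", lower = 0, strict_lower = TRUE)
  check_scalar_number(L, "L", lower = 1)
  res <- with_seed(seed, cpp_sim_replicate(params$omega, params$sigma,
                                           params$npop, as.integer(n), depth,
                                           as.integer(L), criteria, full))
  curve <- new_binning_curve(criteria, res$bins)
  if (!full)
    return(structure(list(curve = curve, params = params, seed = seed),
                     class = "sem_replicate"))
  ids <- sprintf("t%d", seq_len(n))
  tree <- genealogy_to_phylo(res$parent, res$time, res$n_leaves, res$root, ids)
  aln <- new_seq_tbl(id = ids, seq = res$alignment, source = "synthetic")
  structure(list(curve = curve, genealogy = tree, alignment = aln,
                 params = params, seed = seed),
            class = "sem_replicate")
}

# convert parent/time arrays (1-based, leaves first) into an ape phylo
genealogy_to_phylo <- function(parent, time, n_leaves, root, tip_labels) {
  n_nodes <- length(parent)
  # splice out unary internal nodes other than the root (a stretched root
  # chain can produce them); ape expects internal nodes of degree >= 2
  child_count <- tabulate(parent[!is.na(parent)], nbins = n_nodes)
  eff_parent <- parent
  repeat {
    unary <- which(seq_len(n_nodes) > n_leaves & child_count == 1 &
                     seq_len(n_nodes) != root)
    if (!length(unary)) break
    u <- unary[1]
    kids <- which(!is.na(eff_parent) & eff_parent == u)
    eff_parent[kids] <- eff_parent[u]
    eff_parent[u] <- NA_integer_
    child_count <- tabulate(eff_parent[!is.na(eff_parent)], nbins = n_nodes)
    child_count[u] <- 0L
  }
  live <- sort(unique(c(seq_len(n_leaves), root,
                        eff_parent[!is.na(eff_parent)])))
  internal <- setdiff(live, seq_len(n_leaves))
  # ape numbering: tips 1..n, root n+1, other internals follow
  internal <- c(root, setdiff(internal, root))
  newid <- integer(n_nodes)
  newid[seq_len(n_leaves)] <- seq_len(n_leaves)
  newid[internal] <- n_leaves + seq_along(internal)
  edges <- NULL
  lens <- NULL
  for (v in live) {
    p <- eff_parent[v]
    if (is.na(p) || v == root) next
    edges <- rbind(edges, c(newid[p], newid[v]))
    lens <- c(lens, max(0, time[p] - time[v]))
  }
  tr <- list(edge = edges, edge.length = lens, tip.label = tip_labels,
             Nnode = length(internal))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Match-fraction likelihood of Stable-Ecotype-Model parameters
#'
#' Estimates the probability that the model, at the given parameters,
#' reproduces the observed binning curve: the fraction of `R` Monte-Carlo
#' replicates whose curve matches the observation at every criterion under
#' the [match_rule()] band. Replicate `i` uses a substream derived from
#' `(seed, i)`, so increasing `R` never reshuffles earlier replicates.
#'
#' @param params a [sem_params()] triple.
#' @param observed the observed `binning_curve` (on `rule$criteria`).
#' @param rule a [match_rule()].
#' @param R number of Monte-Carlo replicates.
#' @param n,depth,L simulation conditions, see [simulate_replicate()].
#' @param seed integer seed for the replicate substreams.
#' @return the matched fraction, in `[0, 1]`.
#' @export
likelihood_estimate <- function(params, observed, rule = match_rule(),
                                R = 100L, n, depth, L, seed = 1L) {
  stopifnot(inherits(params, "sem_params"), inherits(rule, "match_rule"))
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  if (nrow(observed) != length(rule$criteria) ||
      any(abs(observed$criterion - rule$criteria) > 1e-9))
    stop("observed curve is not on the match rule's criterion grid",
         call. = FALSE)
  obs <- observed$n_bins
  matched <- 0L
  for (i in seq_len(R)) {
    rep_i <- with_seed(derive_seed(seed, i),
                       cpp_sim_replicate(params$omega, params$sigma,
                                         params$npop, as.integer(n), depth,
                                         as.integer(L), rule$criteria, FALSE))
    if (curve_matches(rep_i$bins, obs, rule$tolerance)) matched <- matched + 1L
  }
  matched / R
}
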