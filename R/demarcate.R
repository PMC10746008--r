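# Recursive ecotype demarcation: walk a rooted tree depth-first and
# demarcate every maximal clade whose maximum-likelihood ecotype number,
# with formation and periodic-selection rates held at the global fit,
# equals one.

#' Control settings for demarcation
#'
#' Per-clade likelihoods compare small integer cluster counts, where a
#' multiplicative band rounded outward to integers cannot distinguish one
#' ecotype from two; the per-clade match is therefore exact
#' (`tolerance = 1`) by default, and the full-identity criterion (the
#' distinct-sequence count, pure microheterogeneity already absorbed by the
#' globally fitted rates) is excluded from the per-clade grid.
#'
#' @param R Monte-Carlo replicates per clade likelihood evaluation.
#' @param tolerance match-rule band (see [match_rule()]).
#' @param criteria identity criterion grid for per-clade binning curves.
#' @param npop_cap largest ecotype count scanned per clade.
#' @param min_depth floor on a clade's coalescent depth, in expected
#'   substitutions per site, used when a clade's sequences are (nearly)
#'   identical; default half an expected substitution over the alignment.
#' @param seed integer seed.
#' @return a list of settings.
#' @export
demarcate_control <- function(R = 100L, tolerance = 1.0,
                              criteria = binning_criteria()[-1L],
                              npop_cap = 12L,
                              min_depth = NULL, seed = 1L) {
  list(R = R, tolerance = tolerance, criteria = criteria,
       npop_cap = npop_cap, min_depth = min_depth, seed = seed)
}

# maximum-likelihood ecotype count for one clade's sequences
clade_ml_npop <- function(sub_aln, omega, sigma, control, node_tag) {
  n <- nrow(sub_aln)
  dm_p <- distance_matrix(sub_aln, kind = "p_distance")
  obs <- binning_curve(dm_p, criteria = control$criteria)
  jc <- jc_distance(pmin(dm_p$d, 0.7499))
  L <- nchar(sub_aln$seq[1])
  min_depth <- control$min_depth %||% (0.5 / L)
  depth <- max(max(jc) / 2, min_depth)
  rule <- match_rule(control$tolerance, control$criteria)
  cap <- min(n, control$npop_cap)
  liks <- vapply(seq_len(cap), function(np) {
    likelihood_estimate(sem_params(omega, sigma, np), obs, rule,
                        R = control$R, n = n, depth = depth, L = L,
                        seed = derive_seed(control$seed, node_tag * 131L + np))
  }, numeric(1))
  if (all(liks <= 0)) return(list(npop = NA_integer_, likelihood = 0))
  # ties resolve toward fewer ecotypes; Monte-Carlo estimates within two
  # binomial standard errors of the maximum count as tied
  lmax <- max(liks)
  margin <- 2 * sqrt(lmax * (1 - lmax) / control$R)
  npop_hat <- which(liks > 0 & liks >= lmax - margin)[1L]
  list(npop = npop_hat, likelihood = liks[npop_hat])
}

#' Recursively demarcate putative ecotypes on a rooted tree
#'
#' Depth-first from the root: for a node with leaf set `S`, the likelihood
#' of the clade's own binning curve is evaluated at `npop = 1..min(|S|,
#' npop_cap)` with the formation and periodic-selection rates fixed at the
#' global fit. If the maximum-likelihood ecotype number is one, `S` is
#' demarcated as a single putative ecotype and the walk does not descend;
#' otherwise it recurses into the children. Singletons are demarcated as
#' such.
#'
#' @param tree a rooted [ape::phylo] tree whose tip labels are alignment
#'   ids.
#' @param aln the aligned sequence tibble.
#' @param global_fit a `sem_fit` from [fit_parameters()], or a
#'   [sem_params()] triple.
#' @param control a [demarcate_control()] list.
#' @return a `demarcation` object: `assignments` (tibble `id`, `ecotype`),
#'   `clades` (tibble `node`, `n_members`, `ml_npop`, `members` list-col).
#' @export
demarcate <- function(tree, aln, global_fit, control = demarcate_control()) {
  stopifnot(inherits(tree, "phylo"))
  validate_seq_tbl(aln, aligned = TRUE)
  missing <- setdiff(tree$tip.label, aln$id)
  if (length(missing))
    stop("tree leaves absent from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- if (inherits(global_fit, "sem_fit")) global_fit$best else global_fit
  stopifnot(inherits(params, "sem_params"))

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children_of <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  tips_of <- function(v) {
    if (v <= ntip) return(v)
    unlist(phangorn::Descendants(tree, v, type = "tips"))
  }

  clades <- list()
  walk <- function(v) {
    tip_idx <- tips_of(v)
    ids <- tree$tip.label[tip_idx]
    if (length(ids) == 1L) {
      clades[[length(clades) + 1L]] <<- list(node = v, members = ids,
                                             ml_npop = 1L)
      return(invisible())
    }
    sub <- aln[match(ids, aln$id), , drop = FALSE]
    ml <- clade_ml_npop(sub, params$omega, params$sigma, control,
                        node_tag = as.integer(v))
    if (!is.na(ml$npop) && ml$npop == 1L) {
      clades[[length(clades) + 1L]] <<- list(node = v, members = ids,
                                             ml_npop = 1L)
      return(invisible())
    }
    for (ch in children_of(v)) walk(ch)
    invisible()
  }
  walk(root)

  assignments <- dplyr::bind_rows(lapply(seq_along(clades), function(i) {
    tibble::tibble(id = clades[[i]]$members,
                   ecotype = sprintf("E%02d", i))
  }))
  # partition invariants
  stopifnot(setequal(assignments$id, tree$tip.label),
            !anyDuplicated(assignments$id))
  clade_tbl <- tibble::tibble(
    node = vapply(clades, function(x) as.integer(x$node), integer(1)),
    ecotype = sprintf("E%02d", seq_along(clades)),
    n_members = vapply(clades, function(x) length(x$members), integer(1)),
    ml_npop = vapply(clades, function(x) as.integer(x$ml_npop), integer(1)),
    members = lapply(clades, function(x) x$members)
  )
  structure(list(assignments = assignments, clades = clade_tbl,
                 params = params, control = control),
            class = "demarcation")
}

#' @export
print.demarcation <- function(x, ...) {
  cat("<demarcation> ", nrow(x$clades), " putative ecotypes over ",
      nrow(x$assignments), " sequences\n", sep = "")
  print(dplyr::select(x$clades, "ecotype", "n_members", "ml_npop"))
  invisible(x)
}

#' @rdname demarcate
#' @param x a `demarcation`.
#' @param ... unused.
#' @export
tidy.demarcation <- function(x, ...) x$assignments

#' @rdname demarcate
#' @export
glance.demarcation <- function(x, ...) {
  tibble::tibble(n_ecotypes = nrow(x$clades),
                 n_sequences = nrow(x$assignments),
                 largest = max(x$clades$n_members),
                 singletons = sum(x$clades$n_members == 1L))
}

#' Plot demarcated ecotype sizes
#'
#' @param object a `demarcation`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.demarcation <- function(object, ...) {
  df <- object$clades
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ecotype, y = .data$n_members)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "putative ecotype", y = "members") +
    ggplot2::theme_minimal()
}

#' Write a demarcation report as TSV
#'
#' Columns: `sequence_id`, `ecotype_id`, `clade_node`, `ml_npop`.
#'
#' @param x a `demarcation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_demarcation <- function(x, path) {
  df <- dplyr::left_join(
    dplyr::rename(x$assignments, sequence_id = "id", ecotype_id = "ecotype"),
    dplyr::select(x$clades, ecotype_id = "ecotype", clade_node = "node",
                  "ml_npop"),
    by = "ecotype_id")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
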