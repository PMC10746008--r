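# Binning curves: sequence cluster counts as a function of the identity
# criterion, via complete-linkage agglomeration. The curve is the summary
# statistic the Stable Ecotype Model simulator is fitted against.

#' Default identity criterion grid
#'
#' Brackets the 0-5\% divergence range typical of within-genus 16S surveys.
#'
#' @return a strictly descending numeric vector of identity criteria.
#' @export
binning_criteria <- function() {
  c(1.000, 0.995, 0.99, 0.98, 0.97, 0.96, 0.95, 0.90, 0.85, 0.80)
}

dm_as_distance <- function(dm) {
  if (!inherits(dm, "dist_matrix"))
    stop("expected a dist_matrix (see distance_matrix())", call. = FALSE)
  if (!dm$kind %in% c("p_distance", "identity"))
    stop("binning operates on observed relatedness: kind must be ",
         "p_distance or identity", call. = FALSE)
  if (dm$kind == "identity") 1 - dm$d else dm$d
}

#' Number of sequence clusters at an identity criterion
#'
#' Complete linkage: a cluster is a maximal set in which every pair of
#' members has identity at least the criterion. Agglomeration is
#' deterministic (ties merge the lexicographically smallest pair first).
#'
#' @param dm a `dist_matrix` of kind `p_distance` or `identity`.
#' @param criterion identity threshold in `(0, 1]`.
#' @param linkage `"complete"` (default) or `"single"` (for sensitivity
#'   analysis).
#' @return the number of clusters.
#' @export
bin_at_criterion <- function(dm, criterion, linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  check_scalar_number(criterion, "criterion", lower = 0, upper = 1,
                      strict_lower = TRUE)
  d <- dm_as_distance(dm)
  n <- nrow(d)
  h <- 1 - criterion + 1e-12
  if (linkage == "complete") {
    heights <- cpp_complete_linkage_heights(d)
    return(n - sum(heights <= h))
  }
  # single linkage: connected components of the graph {d <= h}
  adj <- d <= h
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  max(comp)
}

#' Binning curve of a distance matrix
#'
#' Applies [bin_at_criterion()] over a strictly descending grid of identity
#' criteria. The cluster count is non-increasing as the criterion decreases;
#' at criterion 1 it equals the number of distinct sequences.
#'
#' @inheritParams bin_at_criterion
#' @param criteria strictly descending identity thresholds.
#' @return a tibble of class `binning_curve` with columns `criterion` and
#'   `n_bins`.
#' @export
binning_curve <- function(dm, criteria = binning_criteria(),
                          linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  if (length(criteria) < 1L || any(diff(criteria) >= 0))
    stop("criteria must be strictly descending", call. = FALSE)
  if (any(criteria <= 0 | criteria > 1))
    stop("criteria must lie in (0, 1]", call. = FALSE)
  d <- dm_as_distance(dm)
  n <- nrow(d)
  if (linkage == "complete") {
    heights <- cpp_complete_linkage_heights(d)
    n_bins <- vapply(criteria, function(cr) {
      n - sum(heights <= 1 - cr + 1e-12)
    }, integer(1))
  } else {
    n_bins <- vapply(criteria, function(cr) {
      bin_at_criterion(dm, cr, linkage = "single")
    }, integer(1))
  }
  if (any(diff(n_bins) > 0))
    stop("internal error: binning curve not monotone") # nocov
  new_binning_curve(criteria, n_bins)
}

new_binning_curve <- function(criteria, n_bins) {
  out <- tibble::tibble(criterion = as.numeric(criteria),
                        n_bins = as.integer(n_bins))
  class(out) <- c("binning_curve", class(out))
  out
}

#' @export
print.binning_curve <- function(x, ...) {
  cat("<binning_curve> ", nrow(x), " criteria, ",
      x$n_bins[1], " -> ", x$n_bins[nrow(x)], " bins\n", sep = "")
  NextMethod()
}

#' Plot a binning curve
#'
#' @param object a `binning_curve`.
#' @param ... further curves to overlay, named.
#' @return a ggplot.
#' @export
autoplot.binning_curve <- function(object, ...) {
  extra <- list(...)
  df <- dplyr::mutate(tibble::as_tibble(object), curve = "observed")
  if (length(extra)) {
    nm <- names(extra)
    for (i in seq_along(extra))
      df <- dplyr::bind_rows(df, dplyr::mutate(tibble::as_tibble(extra[[i]]),
                                               curve = nm[i]))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$n_bins,
                                   colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "identity criterion", y = "number of sequence bins",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize / read a binning curve as two-column TSV
#'
#' @param curve a `binning_curve`.
#' @param path output path.
#' @return `path` (write) or a `binning_curve` (read).
#' @export
write_binning_curve <- function(curve, path) {
  write.table(as.data.frame(curve)[, c("criterion", "n_bins")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binning_curve
#' @export
read_binning_curve <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  new_binning_curve(df$criterion, df$n_bins)
}
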