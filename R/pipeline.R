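# End-to-end pipeline: distances -> binning -> fit -> demarcate -> envassoc,
# with a validated configuration, stage-tagged logging to stderr, and a
# machine-readable run manifest.

PIPELINE_KEYS <- list(
  input = c("alignment", "tree", "metadata"),
  params = c("criteria", "tolerance", "R", "restarts", "maxit",
             "n_permutations", "env_variable", "npop_cap", "demarc_R"),
  top = c("input", "params", "seed", "outdir")
)

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a path to a JSON file) with keys
#' `input` (paths: `alignment` required; `tree`, `metadata` optional),
#' `params` (stage parameters), `seed`, and `outdir`. Unknown keys are
#' rejected; all problems are reported at once.
#'
#' @param config a named list or path to a JSON config file.
#' @return the validated config list, with defaults filled.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  problems <- character(0)
  unknown <- setdiff(names(config), PIPELINE_KEYS$top)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(config$input$alignment))
    problems <- c(problems, "input$alignment is required")
  unknown_in <- setdiff(names(config$input), PIPELINE_KEYS$input)
  if (length(unknown_in))
    problems <- c(problems, paste0("unknown input key(s): ",
                                   paste(unknown_in, collapse = ", ")))
  unknown_par <- setdiff(names(config$params), PIPELINE_KEYS$params)
  if (length(unknown_par))
    problems <- c(problems, paste0("unknown params key(s): ",
                                   paste(unknown_par, collapse = ", ")))
  for (f in unlist(config$input)) {
    if (!is.null(f) && !file.exists(f))
      problems <- c(problems, paste0("missing input file: ", f))
  }
  if (is.null(config$outdir))
    problems <- c(problems, "outdir is required")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  defaults <- list(criteria = binning_criteria(), tolerance = 1.1,
                   R = 200L, restarts = 2L, maxit = 60L,
                   n_permutations = 999L, env_variable = "temperature",
                   npop_cap = 12L, demarc_R = 100L)
  config$params <- utils::modifyList(defaults, config$params %||% list())
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full demarcation pipeline
#'
#' Executes distances -> binning -> fit -> demarcate -> envassoc in order,
#' writing every stage artifact plus a manifest (JSON) listing artifacts,
#' parameters, seeds and the package version. Identical seeds give
#' byte-identical outputs.
#'
#' @param config a config list or JSON path, see [pipeline_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  art <- list()
  stage_records <- list()

  log_stage("distances", "reading alignment ", cfg$input$alignment)
  aln <- read_fasta(cfg$input$alignment, aligned = TRUE)
  dm_p <- distance_matrix(aln, kind = "p_distance")
  dm_jc <- distance_matrix(aln, kind = "jc_corrected")
  art$distances <- file.path(cfg$outdir, "distances.tsv")
  write.table(tidy(dm_jc), art$distances, sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_records$distances <- list(n_sequences = nrow(aln),
                                  artifact = art$distances)

  log_stage("binning", "computing binning curve")
  curve <- binning_curve(dm_p, criteria = p$criteria)
  art$binning <- file.path(cfg$outdir, "binning_curve.tsv")
  write_binning_curve(curve, art$binning)
  stage_records$binning <- list(criteria = p$criteria, artifact = art$binning)

  log_stage("fit", "fitting Stable Ecotype Model (R = ", p$R, ")")
  depth <- max(max(dm_jc$d) / 2, 0.5 / nchar(aln$seq[1]))
  rule <- match_rule(p$tolerance, p$criteria)
  fit <- fit_parameters(curve, n = nrow(aln), depth = depth,
                        L = nchar(aln$seq[1]), rule = rule, R = p$R,
                        restarts = p$restarts, seed = cfg$seed,
                        maxit = p$maxit)
  art$fit <- file.path(cfg$outdir, "fit.json")
  jsonlite::write_json(list(
    omega = fit$best$omega, sigma = fit$best$sigma, npop = fit$best$npop,
    likelihood = fit$likelihood, evaluations = fit$evaluations,
    seed = fit$seed, depth = depth), art$fit, auto_unbox = TRUE, digits = NA)
  stage_records$fit <- list(npop = fit$best$npop,
                            likelihood = fit$likelihood, artifact = art$fit)

  log_stage("demarcate", "recursive clade demarcation")
  tree <- if (!is.null(cfg$input$tree)) {
    parse_newick(paste(readLines(cfg$input$tree, warn = FALSE),
                       collapse = ""))
  } else {
    nj_tree(dm_jc)
  }
  dem <- demarcate(tree, aln, fit,
                   control = demarcate_control(
                     R = p$demarc_R, tolerance = p$tolerance,
                     criteria = p$criteria, npop_cap = p$npop_cap,
                     seed = derive_seed(cfg$seed, 17L)))
  art$demarcation <- file.path(cfg$outdir, "demarcation.tsv")
  write_demarcation(dem, art$demarcation)
  stage_records$demarcate <- list(n_ecotypes = nrow(dem$clades),
                                  artifact = art$demarcation)

  if (!is.null(cfg$input$metadata)) {
    log_stage("envassoc", "testing clade-by-environment association")
    meta <- tibble::as_tibble(read.table(cfg$input$metadata, header = TRUE,
                                         sep = "\t",
                                         stringsAsFactors = FALSE))
    # demarcated groups drive the test; any grouping column in the metadata
    # (e.g. generator ground truth) is set aside
    joined <- dplyr::inner_join(dem$assignments,
                                dplyr::select(meta,
                                              -dplyr::any_of("ecotype")),
                                by = "id")
    if (length(unique(joined$ecotype)) < 2L) {
      log_stage("envassoc",
                "fewer than two demarcated groups; association not testable")
      stage_records$envassoc <- list(skipped = TRUE,
                                     reason = "fewer than two groups")
    } else {
      assoc <- clade_env_association(joined, p$env_variable,
                                     group = "ecotype",
                                     n_permutations = p$n_permutations,
                                     seed = derive_seed(cfg$seed, 23L))
      art$envassoc <- file.path(cfg$outdir, "envassoc.tsv")
      write.table(as.data.frame(assoc), art$envassoc, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      stage_records$envassoc <- list(variable = p$env_variable,
                                     p_value = assoc$p_value,
                                     artifact = art$envassoc)
    }
  } else {
    log_stage("envassoc", "no metadata supplied; stage skipped")
    stage_records$envassoc <- list(skipped = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecotypesim")),
    seed = cfg$seed,
    params = p,
    inputs = cfg$input,
    artifacts = art,
    stages = stage_records
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done", "manifest written to ", manifest_path)
  invisible(manifest)
}
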