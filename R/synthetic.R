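# Seed-deterministic synthetic-data generators with recorded ground truth:
# ecotype-structured alignments, genome pairs at controlled divergence,
# clone libraries with copy-number structure, and environmentally patterned
# site metadata.

random_dna <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- sample(alt, 1L)
  }
  paste(ch, collapse = "")
}

#' Configuration for the ecotype-structured alignment generator
#'
#' Defaults emulate the divergence regime of within-genus 16S hot-spring
#' surveys: tight clusters (microheterogeneity of a few nt) separated by
#' several percent divergence, with environmentally patterned site metadata.
#'
#' @param n_ecotypes number of ground-truth ecotypes.
#' @param seqs_per_ecotype sequences per ecotype.
#' @param L alignment length (nt).
#' @param within_div maximum within-ecotype divergence (proportion).
#' @param between_div minimum between-ecotype divergence (proportion);
#'   must exceed `within_div`.
#' @param env_profile per-ecotype environmental profile: a tibble with
#'   `ecotype`, `temperature_mean`, `temperature_sd`, `ph_mean`, `ph_sd`;
#'   defaults to ecotypes spread over 40-52 degC and pH 5.4-6.8 with small
#'   spreads.
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_ecotypes = 4L, seqs_per_ecotype = 10L, L = 750L,
                         within_div = 0.003, between_div = 0.03,
                         env_profile = NULL, seed = 1L) {
  stopifnot(n_ecotypes >= 1L, seqs_per_ecotype >= 1L, L >= 1L)
  if (within_div >= between_div)
    stop("within_div must be smaller than between_div", call. = FALSE)
  if (is.null(env_profile)) {
    k <- n_ecotypes
    env_profile <- tibble::tibble(
      ecotype = sprintf("E%02d", seq_len(k)),
      temperature_mean = seq(40, 52, length.out = max(k, 2))[seq_len(k)],
      temperature_sd = 0.8,
      ph_mean = seq(5.4, 6.8, length.out = max(k, 2))[seq_len(k)],
      ph_sd = 0.1
    )
  }
  list(n_ecotypes = as.integer(n_ecotypes),
       seqs_per_ecotype = as.integer(seqs_per_ecotype), L = as.integer(L),
       within_div = within_div, between_div = between_div,
       env_profile = env_profile, seed = as.integer(seed))
}

#' Generate an ecotype-structured alignment with known labels
#'
#' Each ecotype receives a disjoint block of diagnostic positions mutated
#' away from a common ancestor, guaranteeing at least `between_div`
#' divergence between ecotypes; individual sequences then acquire up to
#' `within_div * L / 2` private mutations at non-diagnostic positions
#' (microheterogeneity). Realized divergences are verified against the
#' configured bounds (`min between >= 0.8 * between_div`,
#' `max within <= 1.2 * within_div`) and the draw is repeated up to
#' `max_retries` times before failing.
#'
#' @param cfg a [synth_config()].
#' @param max_retries bound on regeneration attempts.
#' @return a list with `alignment` (sequence tibble) and `truth` (tibble
#'   `id`, `ecotype`).
#' @export
simulate_ecotype_alignment <- function(cfg, max_retries = 20L) {
  k <- cfg$n_ecotypes; m <- cfg$seqs_per_ecotype; L <- cfg$L
  block <- ceiling(cfg$between_div * L / 2)
  if (k * block > L * 0.8)
    stop("alignment too short for ", k, " ecotypes at between_div = ",
         cfg$between_div, call. = FALSE)
  max_mut <- floor(cfg$within_div * L / 2)
  with_seed(cfg$seed, {
    for (attempt in seq_len(max_retries)) {
      root <- random_dna(L)
      block_pos <- split(seq_len(k * block),
                         rep(seq_len(k), each = block))
      free_pos <- setdiff(seq_len(L), seq_len(k * block))
      ancestors <- vapply(seq_len(k), function(e) {
        if (k == 1L) root else mutate_at(root, block_pos[[e]])
      }, character(1))
      ids <- character(0); seqs <- character(0); eco <- character(0)
      for (e in seq_len(k)) {
        for (s in seq_len(m)) {
          nmut <- if (max_mut > 0L) sample(0:max_mut, 1L) else 0L
          pos <- if (nmut > 0L) sample(free_pos, nmut) else integer(0)
          ids <- c(ids, sprintf("E%02d_s%02d", e, s))
          seqs <- c(seqs, mutate_at(ancestors[e], pos))
          eco <- c(eco, sprintf("E%02d", e))
        }
      }
      aln <- new_seq_tbl(id = ids, seq = seqs, site_id = eco,
                         source = "synthetic")
      truth <- tibble::tibble(id = ids, ecotype = eco)
      if (k * m >= 2L) {
        dm <- distance_matrix(aln, kind = "p_distance")
        same <- outer(eco, eco, "==")
        diag(same) <- NA
        within_max <- if (any(same, na.rm = TRUE))
          max(dm$d[which(same)]) else 0
        between_min <- if (any(!same, na.rm = TRUE))
          min(dm$d[which(!same)]) else Inf
        ok_within <- within_max <= cfg$within_div * 1.2 + 1e-12
        ok_between <- k == 1L || between_min >= cfg$between_div * 0.8 - 1e-12
        if (!ok_within || !ok_between) {
          if (attempt == max_retries)
            stop("generation infeasible after ", max_retries, " attempts: ",
                 if (!ok_within) "within-ecotype divergence bound violated"
                 else "between-ecotype divergence bound violated",
                 call. = FALSE)
          next
        }
      }
      return(list(alignment = aln, truth = truth))
    }
  })
}

#' Generate a genome pair at a controlled substitution divergence
#'
#' `genome_b` is `genome_a` with i.i.d. substitutions at expected proportion
#' `divergence` (each substituted site switches to one of the three other
#' bases uniformly, the Jukes-Cantor transition distribution).
#'
#' @param length genome length in nt.
#' @param divergence expected substitution proportion in `[0, 0.75)`.
#' @param seed integer seed.
#' @return a list with `genome_a`, `genome_b`, and `n_substitutions`
#'   (realized count).
#' @export
simulate_genome_pair <- function(length, divergence, seed = 1L) {
  check_scalar_number(divergence, "divergence", lower = 0, upper = 0.7499)
  with_seed(seed, {
    a <- random_dna(length)
    hit <- which(runif(length) < divergence)
    b <- mutate_at(a, hit)
    list(genome_a = a, genome_b = b, n_substitutions = length(hit))
  })
}

#' Generate a clone library with a prescribed copy-number structure
#'
#' Emits a multiset of sequence records that [clone_tally()] inverts
#' exactly: the first variant is the base sequence, later variants carry
#' mutations at the given (or default, pairwise-distinct) positions, and
#' each singleton carries a private mutation.
#'
#' @param tally_spec copies per variant: an integer vector (optionally
#'   named), or a tibble with `variant` and `copies` (and optionally a
#'   `positions` list-column of mutation positions per variant).
#' @param singletons number of additional unique singleton sequences.
#' @param L sequence length (nt).
#' @param seed integer seed.
#' @return a sequence tibble of `sum(copies) + singletons` records.
#' @export
simulate_clone_library <- function(tally_spec, singletons = 0L, L = 741L,
                                   seed = 1L) {
  if (is.data.frame(tally_spec)) {
    copies <- tally_spec$copies
    variants <- tally_spec$variant
    positions <- tally_spec$positions %||% NULL
  } else {
    copies <- as.integer(tally_spec)
    variants <- names(tally_spec) %||% sprintf("V%02d", seq_along(copies))
    if (is.null(names(tally_spec)))
      variants <- sprintf("V%02d", seq_along(copies))
    positions <- NULL
  }
  nv <- length(copies)
  stopifnot(all(copies >= 1L), nv >= 1L)
  if (is.null(positions)) {
    # default: variant i differs from the base at positions {1..i-1 offsets}
    positions <- c(list(integer(0)),
                   lapply(seq_len(nv - 1L), function(i) i))
  }
  need <- nv - 1L + singletons
  if (need >= L) stop("L too short for the requested variant structure",
                      call. = FALSE)
  with_seed(seed, {
    base <- random_dna(L)
    var_seqs <- vapply(seq_len(nv), function(i) {
      mutate_at(base, positions[[i]])
    }, character(1))
    single_seqs <- vapply(seq_len(singletons), function(i) {
      mutate_at(base, nv - 1L + i)
    }, character(1))
    ids <- c(unlist(lapply(seq_len(nv), function(i)
      sprintf("%s_c%02d", variants[i], seq_len(copies[i])))),
      if (singletons > 0L) sprintf("S%02d", seq_len(singletons)))
    seqs <- c(rep(var_seqs, copies),
              if (singletons > 0L) single_seqs)
    new_seq_tbl(id = ids, seq = seqs, source = "synthetic")
  })
}

#' Generate environmentally patterned site metadata
#'
#' Draws a temperature and pH for every sequence from its ecotype's profile
#' (independent normal draws at the stated spreads).
#'
#' @param assignments a tibble with `id` and `ecotype`.
#' @param env_profile per-ecotype profile (see [synth_config()]).
#' @param seed integer seed.
#' @return a tibble with `id`, `ecotype`, `site_id`, `temperature`, `ph`.
#' @export
simulate_site_metadata <- function(assignments, env_profile, seed = 1L) {
  stopifnot(all(c("id", "ecotype") %in% names(assignments)))
  missing <- setdiff(assignments$ecotype, env_profile$ecotype)
  if (length(missing))
    stop("no environmental profile for ecotype(s): ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  df <- dplyr::left_join(assignments, env_profile, by = "ecotype")
  with_seed(seed, {
    tibble::tibble(
      id = df$id,
      ecotype = df$ecotype,
      site_id = paste0("site_", df$ecotype),
      temperature = stats::rnorm(nrow(df), df$temperature_mean,
                                 df$temperature_sd),
      ph = stats::rnorm(nrow(df), df$ph_mean, df$ph_sd)
    )
  })
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits an ecotype-structured alignment (FASTA), its ground-truth labels
#' and site metadata (TSV), a neighbor-joining tree (newick), and a genome
#' pair (FASTA) into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param cfg a [synth_config()].
#' @param genome_length,genome_divergence settings for the genome pair.
#' @return invisibly, a character vector of the files written.
#' @export
write_synthetic_fixtures <- function(dir, cfg = synth_config(),
                                     genome_length = 50000L,
                                     genome_divergence = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_ecotype_alignment(cfg)
  meta <- simulate_site_metadata(sim$truth, cfg$env_profile,
                                 seed = derive_seed(cfg$seed, 2L))
  gp <- simulate_genome_pair(genome_length, genome_divergence,
                             seed = derive_seed(cfg$seed, 3L))
  files <- c(
    alignment = file.path(dir, "alignment.fasta"),
    truth = file.path(dir, "truth.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "nj_tree.nwk"),
    genomes = file.path(dir, "genome_pair.fasta")
  )
  write_fasta(sim$alignment, files["alignment"])
  write.table(sim$truth, files["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(meta, files["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  dm <- distance_matrix(sim$alignment, kind = "jc_corrected")
  writeLines(write_newick(nj_tree(dm)), files["tree"])
  write_fasta(new_seq_tbl(id = c("genome_a", "genome_b"),
                          seq = c(gp$genome_a, gp$genome_b),
                          source = "synthetic"),
              files["genomes"])
  invisible(files)
}
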