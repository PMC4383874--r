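# Run an expression with a private, seeded RNG stream; the caller's
# RNG state is left untouched so generators are pure functions of their
# config.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the planted-module expression simulator
#'
#' Defines a GEO-like corpus for one organism: a set of experiments
#' whose samples express planted co-regulated gene modules through a
#' latent-factor model, with redundant (near-duplicate) arrays, genes
#' measured by several probes, and a mix of single- and dual-channel
#' platforms.
#'
#' @param n_genes total genes.
#' @param n_modules number of planted co-regulated modules.
#' @param module_size genes per module (`n_modules * module_size` must
#'   not exceed `n_genes`; remaining genes are unregulated background).
#' @param n_experiments number of experiments.
#' @param samples_per_experiment samples per experiment (before duplication).
#' @param noise_sd standard deviation of the per-gene and per-probe
#'   measurement noise, relative to unit module-activity variance.
#' @param duplicate_array_rate probability that a sample is emitted
#'   twice (the redundancy the pruning step must remove).
#' @param duplicate_noise_sd noise added to the duplicate copy.
#' @param probes_per_gene_max genes are measured by 1..this many probes.
#' @param channel_mix fraction of experiments on single-channel platforms.
#' @param organism_id organism label.
#' @param seed RNG seed; the whole dataset is a pure function of the config.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200L, n_modules = 20L,
                              module_size = 10L, n_experiments = 12L,
                              samples_per_experiment = 8L, noise_sd = 0.5,
                              duplicate_array_rate = 0.1,
                              duplicate_noise_sd = 0.01,
                              probes_per_gene_max = 2L, channel_mix = 0.5,
                              organism_id = "org1", seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_experiments = as.integer(n_experiments),
              samples_per_experiment = as.integer(samples_per_experiment),
              noise_sd = noise_sd,
              duplicate_array_rate = duplicate_array_rate,
              duplicate_noise_sd = duplicate_noise_sd,
              probes_per_gene_max = as.integer(probes_per_gene_max),
              channel_mix = channel_mix,
              organism_id = as.character(organism_id),
              seed = as.integer(seed))
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("module_size * n_modules exceeds n_genes")
  if (any(c(cfg$n_genes, cfg$n_modules, cfg$module_size, cfg$n_experiments,
            cfg$samples_per_experiment, cfg$probes_per_gene_max) < 1L))
    stop("all counts must be >= 1")
  if (cfg$duplicate_array_rate < 0 || cfg$duplicate_array_rate > 1 ||
      cfg$channel_mix < 0 || cfg$channel_mix > 1)
    stop("rates must lie in [0, 1]")
  structure(cfg, class = "simulation_config")
}

#' Simulate a GEO-like expression corpus with planted modules
#'
#' Latent-factor generative model: per sample, each module draws one
#' activity ~ Normal(0, 1); a gene's underlying signal is its module's
#' activity (loading 1 for members, 0 for background genes) plus
#' Normal(0, `noise_sd`) gene noise. Each probe of a gene adds
#' independent Normal(0, `noise_sd`) probe noise. Dual-channel
#' experiments report these values directly as log-ratios;
#' single-channel experiments report positive intensities
#' `2^signal`, so the pipeline's log2 step inverts the transformation.
#' With probability `duplicate_array_rate` a sample column is emitted a
#' second time with Normal(0, `duplicate_noise_sd`) perturbation - the
#' redundant twin the Hobohm-2 step is meant to prune. The planted
#' modules double as the gold-standard pathways, so benchmark truth is
#' known by construction.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_dataset`: list with `experiments` (list of
#'   [expression_matrix()]), `probe_map`, `gold` ([gold_standard()]),
#'   `truth` (named vector gene -> module or `NA`), and `config`.
#' @export
simulate_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    module <- rep(NA_character_, config$n_genes)
    idx <- seq_len(config$n_modules * config$module_size)
    module[idx] <- rep(sprintf("M%02d", seq_len(config$n_modules)),
                       each = config$module_size)
    names(module) <- genes

    n_probes <- sample.int(config$probes_per_gene_max, config$n_genes,
                           replace = TRUE)
    probe_ids <- unlist(lapply(seq_along(genes), function(i)
      paste0(genes[i], "_p", seq_len(n_probes[i]))))
    map <- probe_map(probe_ids, rep(genes, n_probes))
    gene_of_probe <- map

    channels <- ifelse(stats::runif(config$n_experiments) < config$channel_mix,
                       "single", "dual")
    experiments <- vector("list", config$n_experiments)
    for (e in seq_len(config$n_experiments)) {
      ns <- config$samples_per_experiment
      act <- matrix(stats::rnorm(config$n_modules * ns), config$n_modules, ns)
      loading <- ifelse(is.na(module), 0,
                        as.integer(factor(module,
                                          levels = sprintf("M%02d", seq_len(config$n_modules)))))
      signal <- matrix(0, config$n_genes, ns)
      members <- !is.na(module)
      signal[members, ] <- act[loading[members], , drop = FALSE]
      signal <- signal + matrix(stats::rnorm(config$n_genes * ns,
                                             sd = config$noise_sd),
                                config$n_genes, ns)
      probe_vals <- signal[match(gene_of_probe, genes), , drop = FALSE] +
        matrix(stats::rnorm(length(probe_ids) * ns, sd = config$noise_sd),
               length(probe_ids), ns)
      dimnames(probe_vals) <- list(probe_ids, sprintf("s%02d", seq_len(ns)))
      dup <- stats::runif(ns) < config$duplicate_array_rate
      if (any(dup)) {
        twins <- probe_vals[, dup, drop = FALSE] +
          matrix(stats::rnorm(length(probe_ids) * sum(dup),
                              sd = config$duplicate_noise_sd),
                 length(probe_ids), sum(dup))
        colnames(twins) <- paste0(colnames(probe_vals)[dup], "d")
        probe_vals <- cbind(probe_vals, twins)
      }
      if (channels[e] == "single") probe_vals <- 2^probe_vals
      experiments[[e]] <- expression_matrix(
        probe_vals, channels[e],
        experiment_id = sprintf("E%03d", e),
        organism_id = config$organism_id)
    }

    annotated <- genes[!is.na(module)]
    gold <- gold_standard(annotated, module[annotated])
    structure(list(experiments = experiments, probe_map = map, gold = gold,
                   truth = module, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s: %d experiments, %d genes (%d in %d modules), %d probes\n",
              x$config$organism_id, length(x$experiments), x$config$n_genes,
              sum(!is.na(x$truth)), x$config$n_modules, length(x$probe_map)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Materializes the TSV dialects consumed by the pipeline: one
#' expression matrix per experiment (`<experiment>.<channel>.tsv`), the
#' probe map (`probe_map.tsv`) and the gold standard (`gold.tsv`).
#'
#' @param dataset a [simulate_expression()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in dataset$experiments)
    write_expression_matrix(m, file.path(dir, paste0(m$experiment_id, ".",
                                                     m$channel, ".tsv")))
  utils::write.table(
    data.frame(probe = names(dataset$probe_map), gene = dataset$probe_map),
    file.path(dir, "probe_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  gold_df <- data.frame(
    gene = rep(names(dataset$gold), lengths(dataset$gold)),
    pathway = unlist(dataset$gold))
  utils::write.table(gold_df, file.path(dir, "gold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Simulate a clade hierarchy with (optionally corrupted) ortholog groups
#'
#' Builds a balanced species tree of the requested depth, instantiates
#' each gene family with 1-3 paralogs per species, and derives nested
#' orthologous groups top-down (each clade's partition refines its
#' parent's restriction, splitting with probability 1/2 at each level),
#' which is consistent by construction. A `corruption_rate` fraction of
#' the below-root assignments is then reassigned to wrong groups,
#' emulating independently computed per-clade orthology; the
#' uncorrupted set is returned as truth.
#'
#' @param n_species number of species (leaves of the clade tree).
#' @param depth number of clade levels (>= 2, root included).
#' @param n_families number of gene families.
#' @param corruption_rate fraction of non-root assignments to corrupt.
#' @param seed RNG seed.
#' @return list with `tree` ([clade_tree()]), `groups` (corrupted
#'   [ortholog_groups()]), `truth` (uncorrupted [ortholog_groups()]).
#' @export
simulate_orthology <- function(n_species = 4L, depth = 3L, n_families = 5L,
                               corruption_rate = 0, seed = 1L) {
  if (depth < 2L) stop("depth must be >= 2")
  with_seed(seed, {
    species <- sprintf("sp%02d", seq_len(n_species))
    # balanced bisection down to `depth` levels
    clades <- list(root = list(parent = NA_character_, species = species))
    frontier <- "root"
    for (lvl in seq_len(depth - 1L)) {
      nxt <- character()
      for (cl in frontier) {
        sp <- clades[[cl]]$species
        if (length(sp) < 2L) next
        half <- ceiling(length(sp) / 2)
        kids <- list(sp[seq_len(half)], sp[-seq_len(half)])
        for (i in 1:2) {
          id <- paste0(cl, ".", i)
          clades[[id]] <- list(parent = cl, species = kids[[i]])
          nxt <- c(nxt, id)
        }
      }
      frontier <- nxt
      if (!length(frontier)) break
    }
    tree <- clade_tree(names(clades),
                       vapply(clades, `[[`, character(1), "parent"),
                       lapply(clades, `[[`, "species"))

    # proteins: per family and species, 1-3 paralogs
    prots <- list()
    for (f in seq_len(n_families)) for (s in species) {
      k <- sample.int(3L, 1L)
      prots[[length(prots) + 1L]] <- data.frame(
        protein_id = sprintf("%s_f%02d_%d", s, f, seq_len(k)),
        species = s, family = f)
    }
    prots <- do.call(rbind, prots)
    protein_species <- stats::setNames(prots$species, prots$protein_id)

    # nested groups, top-down: root = one group per family; children
    # restrict and sometimes split their parent group
    assign <- list()
    grp_at <- list()  # clade -> named vector protein -> group
    ord <- names(clades)[order(clade_depths(tree)[names(clades)])]
    for (cl in ord) {
      sp_here <- clades[[cl]]$species
      here <- prots[prots$species %in% sp_here, , drop = FALSE]
      if (identical(cl, tree$root)) {
        g <- sprintf("%s_f%02d", cl, here$family)
      } else {
        parent_grp <- grp_at[[clades[[cl]]$parent]][here$protein_id]
        key <- parent_grp
        for (pg in unique(parent_grp)) {
          sel <- parent_grp == pg
          if (sum(sel) >= 2L && stats::runif(1) < 0.5) {
            # split this inherited group in two
            members <- which(sel)
            cut <- sample(members, ceiling(length(members) / 2))
            key[cut] <- paste0(key[cut], "\r")  # internal split marker
          }
        }
        # canonical per-clade labels, collision-free by construction
        g <- paste0(cl, "_g", match(key, unique(key)))
      }
      grp_at[[cl]] <- stats::setNames(g, here$protein_id)
      assign[[cl]] <- data.frame(clade_id = cl, group_id = g,
                                 protein_id = here$protein_id)
    }
    truth_df <- do.call(rbind, assign)
    truth <- ortholog_groups(truth_df, protein_species, tree)

    corrupt_df <- truth_df
    below_root <- which(corrupt_df$clade_id != tree$root)
    n_corrupt <- round(corruption_rate * length(below_root))
    if (n_corrupt > 0) {
      victims <- sample(below_root, n_corrupt)
      for (i in victims) {
        cl <- corrupt_df$clade_id[i]
        others <- setdiff(unique(corrupt_df$group_id[corrupt_df$clade_id == cl]),
                          corrupt_df$group_id[i])
        corrupt_df$group_id[i] <- if (length(others))
          others[sample.int(length(others), 1L)] else
          paste0(corrupt_df$group_id[i], "_x")
      }
    }
    groups <- ortholog_groups(corrupt_df, protein_species, tree)
    list(tree = tree, groups = groups, truth = truth)
  })
}
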