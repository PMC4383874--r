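#' Construct a clade tree
#'
#' A rooted hierarchy of phylogenetic clades, each covering a set of
#' species. Sibling clades cover disjoint species sets and every child's
#' set is contained in its parent's; the root covers all species.
#'
#' @param clade_ids character vector of clade IDs.
#' @param parent_ids parent clade ID per clade (`NA` for the root).
#' @param species named list (by clade ID) of character vectors: the
#'   species covered by each clade.
#' @return a `clade_tree`: list with `parent` (named vector), `species`
#'   (named list) and `root`.
#' @export
clade_tree <- function(clade_ids, parent_ids, species) {
  clade_ids <- as.character(clade_ids)
  parent_ids <- as.character(parent_ids)
  if (anyDuplicated(clade_ids)) stop("duplicate clade IDs")
  if (!setequal(names(species), clade_ids))
    stop("species list must be keyed by the clade IDs")
  roots <- clade_ids[is.na(parent_ids)]
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (!all(parent_ids[!is.na(parent_ids)] %in% clade_ids))
    stop("unknown parent clade referenced")
  parent <- stats::setNames(parent_ids, clade_ids)
  species <- lapply(species[clade_ids], as.character)
  for (cl in clade_ids) {
    p <- parent[[cl]]
    if (!is.na(p) && !all(species[[cl]] %in% species[[p]]))
      stop("clade '", cl, "' covers species outside its parent '", p, "'")
  }
  for (p in clade_ids) {
    kids <- clade_ids[!is.na(parent_ids) & parent_ids == p]
    sp <- unlist(species[kids])
    if (anyDuplicated(sp))
      stop("sibling clades under '", p, "' share species")
  }
  structure(list(parent = parent, species = species, root = roots),
            class = "clade_tree")
}

#' Read a clade tree from a 3-column TSV
#' (`clade_id<TAB>parent_id<TAB>comma-separated species`; empty or `NA`
#' parent marks the root.)
#' @param path file path.
#' @return a [clade_tree()].
#' @export
read_clade_tree <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("clade_id", "parent_id", "species"),
                          colClasses = "character", quote = "", na.strings = c("", "NA"))
  clade_tree(df$clade_id, df$parent_id,
             stats::setNames(strsplit(df$species, ",", fixed = TRUE), df$clade_id))
}

# ancestors of a clade, nearest first (excluding the clade itself)
clade_ancestors <- function(tree, clade) {
  out <- character()
  p <- tree$parent[[clade]]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[[p]]
  }
  out
}

# depth of every clade (root = 0)
clade_depths <- function(tree) {
  vapply(names(tree$parent), function(cl) length(clade_ancestors(tree, cl)),
         integer(1))
}

#' Construct an orthologous-group set
#'
#' Per-clade partitions of proteins into orthologous groups, together
#' with the species of each protein. Within one clade a protein belongs
#' to at most one group, and only proteins of species covered by the
#' clade may be assigned there.
#'
#' @param assignments data frame with columns `clade_id`, `group_id`,
#'   `protein_id`.
#' @param protein_species named character vector: protein ID -> species ID.
#' @param tree optional [clade_tree()] used to validate coverage.
#' @return an `ortholog_groups` object (list with `assignments`,
#'   `protein_species`).
#' @export
ortholog_groups <- function(assignments, protein_species, tree = NULL) {
  req <- c("clade_id", "group_id", "protein_id")
  if (!all(req %in% names(assignments))) stop("assignments need columns ",
                                              paste(req, collapse = ", "))
  assignments <- assignments[req]
  assignments[] <- lapply(assignments, as.character)
  key <- paste(assignments$clade_id, assignments$protein_id)
  if (anyDuplicated(key))
    stop("a protein may belong to at most one group per clade")
  if (!all(assignments$protein_id %in% names(protein_species)))
    stop("unknown protein in assignments: ",
         paste(utils::head(setdiff(assignments$protein_id, names(protein_species))),
               collapse = ", "))
  if (!is.null(tree)) {
    if (!all(assignments$clade_id %in% names(tree$parent)))
      stop("assignments reference clades absent from the tree")
    sp <- protein_species[assignments$protein_id]
    cov <- mapply(function(cl, s) s %in% tree$species[[cl]],
                  assignments$clade_id, sp)
    if (!all(cov))
      stop("proteins assigned at clades that do not cover their species")
  }
  rownames(assignments) <- NULL
  structure(list(assignments = assignments,
                 protein_species = protein_species),
            class = "ortholog_groups")
}

#' Read ortholog groups from a 3-column TSV (`clade_id<TAB>group_id<TAB>protein_id`)
#' @param path file path.
#' @param protein_species named character vector protein -> species.
#' @param tree optional [clade_tree()] for validation.
#' @return an [ortholog_groups()] object.
#' @export
read_ortholog_groups <- function(path, protein_species, tree = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("clade_id", "group_id", "protein_id"),
                          colClasses = "character", quote = "")
  ortholog_groups(df, protein_species, tree)
}

#' @export
print.ortholog_groups <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("<ortholog_groups> %d assignments, %d clades, %d proteins, %d groups\n",
              nrow(a), length(unique(a$clade_id)),
              length(unique(a$protein_id)),
              length(unique(paste(a$clade_id, a$group_id)))))
  invisible(x)
}

# group membership lookup at one clade: named vector protein -> group_id
groups_at <- function(groups, clade) {
  a <- groups$assignments
  sel <- a$clade_id == clade
  stats::setNames(a$group_id[sel], a$protein_id[sel])
}

#' Check hierarchical self-consistency of ortholog groups
#'
#' The nested orthology assignments are self-consistent when proteins
#' grouped together at any clade are also grouped together at every
#' ancestor clade (among the proteins that are assigned there).
#'
#' @param groups an [ortholog_groups()] object.
#' @param tree a [clade_tree()].
#' @return logical; attribute `violations` holds a data frame with
#'   columns `clade`, `group`, `ancestor`, `witness_a`, `witness_b`
#'   (a protein pair co-grouped at `clade` but split at `ancestor`).
#' @export
is_consistent <- function(groups, tree) {
  stopifnot(inherits(groups, "ortholog_groups"), inherits(tree, "clade_tree"))
  if (!all(groups$assignments$clade_id %in% names(tree$parent)))
    stop("groups reference clades absent from the tree")
  viol <- list()
  clades <- unique(groups$assignments$clade_id)
  lookup <- lapply(stats::setNames(nm = unique(c(
    clades, unlist(lapply(clades, clade_ancestors, tree = tree))))),
    groups_at, groups = groups)
  for (cl in clades) {
    g_here <- lookup[[cl]]
    for (anc in clade_ancestors(tree, cl)) {
      g_anc <- lookup[[anc]]
      if (!length(g_anc)) next
      both <- names(g_here)[names(g_here) %in% names(g_anc)]
      if (length(both) < 2L) next
      tab <- split(g_anc[both], g_here[both])
      for (g in names(tab)) {
        anc_groups <- unique(tab[[g]])
        if (length(anc_groups) > 1L) {
          members <- tab[[g]]
          wa <- names(members)[members == anc_groups[1L]][1L]
          wb <- names(members)[members == anc_groups[2L]][1L]
          viol[[length(viol) + 1L]] <- data.frame(
            clade = cl, group = g, ancestor = anc,
            witness_a = wa, witness_b = wb)
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(clade = character(), group = character(), ancestor = character(),
               witness_a = character(), witness_b = character())
  structure(nrow(violations) == 0L, violations = violations)
}

#' Repair ortholog groups to hierarchical self-consistency
#'
#' Iteratively splits and merges orthologous groups across clades until
#' a fully consistent state is reached. Two strategies are available:
#'
#' * `merge_up` (default): processing clades leaves-to-root, any two
#'   ancestor groups that share proteins of one descendant group are
#'   union-merged. Conservative: groupings are never discarded, ancestor
#'   groups only grow.
#' * `split_down`: processing root-to-leaves, each group is split by its
#'   proteins' group membership at the nearest ancestor clade where they
#'   are assigned. Descendant groups only shrink. Proteins unassigned at
#'   every ancestor do not force a split; they stay with the largest
#'   resulting fragment.
#'
#' Passes repeat until a fixpoint (no further change); the result always
#' satisfies [is_consistent()].
#'
#' @param groups an [ortholog_groups()] object.
#' @param tree a [clade_tree()].
#' @param strategy `"merge_up"` or `"split_down"`.
#' @return a repaired [ortholog_groups()] object.
#' @export
enforce_consistency <- function(groups, tree,
                                strategy = c("merge_up", "split_down")) {
  strategy <- match.arg(strategy)
  a <- groups$assignments
  depths <- clade_depths(tree)
  clades <- unique(a$clade_id)
  clades <- clades[order(depths[clades],
                         decreasing = (strategy == "merge_up"))]

  repeat {
    changed <- FALSE
    if (strategy == "merge_up") {
      for (cl in clades) {
        here <- a$clade_id == cl
        grp_of <- stats::setNames(a$group_id[here], a$protein_id[here])
        for (anc in clade_ancestors(tree, cl)) {
          at_anc <- a$clade_id == anc
          if (!any(at_anc)) next
          anc_grp <- a$group_id[at_anc]
          prot_anc <- a$protein_id[at_anc]
          idx <- prot_anc %in% names(grp_of)
          if (!any(idx)) next
          # union-find over ancestor groups linked by shared child groups
          link <- split(anc_grp[idx], grp_of[prot_anc[idx]])
          relabel <- stats::setNames(unique(anc_grp), unique(anc_grp))
          find <- function(g) { while (relabel[[g]] != g) g <- relabel[[g]]; g }
          for (gs in link) {
            gs <- unique(gs)
            if (length(gs) < 2L) next
            roots <- unique(vapply(gs, find, character(1)))
            target <- min(roots)
            for (rt in roots) relabel[[rt]] <- target
          }
          new_grp <- vapply(anc_grp, find, character(1))
          if (!identical(unname(new_grp), anc_grp)) {
            a$group_id[at_anc] <- unname(new_grp)
            changed <- TRUE
          }
        }
      }
    } else {  # split_down
      for (cl in clades) {
        ancs <- clade_ancestors(tree, cl)
        if (!length(ancs)) next
        here <- which(a$clade_id == cl)
        if (!length(here)) next
        anc_lookup <- lapply(ancs, function(anc) {
          at <- a$clade_id == anc
          stats::setNames(a$group_id[at], a$protein_id[at])
        })
        # nearest assigned ancestor determines the split key
        key <- vapply(a$protein_id[here], function(p) {
          for (i in seq_along(ancs)) {
            g <- anc_lookup[[i]][p]
            if (!is.na(g)) return(paste0(ancs[i], "|", g))
          }
          NA_character_
        }, character(1))
        for (g in unique(a$group_id[here])) {
          sel <- here[a$group_id[here] == g]
          k <- key[match(sel, here)]
          uk <- unique(k[!is.na(k)])
          if (length(uk) < 2L) next
          sizes <- table(factor(k[!is.na(k)], levels = uk))
          main <- names(sizes)[order(-sizes, names(sizes))][1L]
          k[is.na(k)] <- main   # unconstrained proteins follow the largest fragment
          suffix <- match(k, sort(uk))
          keep_main <- k == main  # largest fragment keeps the original ID
          new_ids <- paste0(g, ".", suffix)
          while (any(new_ids[!keep_main] %in% a$group_id[here])) {
            new_ids <- paste0(new_ids, "s")   # avoid clashing with existing IDs
          }
          a$group_id[sel[!keep_main]] <- new_ids[!keep_main]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- groups
  out$assignments <- a
  out
}

#' Interolog-transfer configuration
#'
#' @param gamma paralogy-penalty exponent (>= 0): a source score S
#'   transferred through groups with `n_a` and `n_b` target-species
#'   members is down-weighted to `S * (n_a * n_b)^(-gamma)`. `gamma = 0`
#'   transfers scores unchanged.
#' @param min_transferred_score transferred edges below this score are
#'   dropped.
#' @return a `transfer_config` list.
#' @export
transfer_config <- function(gamma = 0.5, min_transferred_score = 0.15) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (min_transferred_score < 0 || min_transferred_score > 1)
    stop("min_transferred_score must lie in [0, 1]")
  structure(list(gamma = gamma, min_transferred_score = min_transferred_score),
            class = "transfer_config")
}

# lowest clade whose species set covers both species
lowest_common_clade <- function(tree, sp_a, sp_b) {
  covers <- vapply(names(tree$species), function(cl)
    all(c(sp_a, sp_b) %in% tree$species[[cl]]), logical(1))
  if (!any(covers)) stop("no clade covers both '", sp_a, "' and '", sp_b,
                         "' (is the tree rooted over all species?)")
  cand <- names(tree$species)[covers]
  cand[which.min(lengths(tree$species[cand]))]
}

#' Transfer scored interactions between species through ortholog groups
#'
#' For each source edge, the two proteins are mapped to their
#' orthologous groups at the lowest clade covering both species; every
#' pair of target-species proteins drawn from those two groups receives
#' the source score, down-weighted by the paralogy penalty
#' `(n_a * n_b)^(-gamma)` where `n_a`, `n_b` count the target-species
#' members of each group. Multiple transfers onto the same target pair
#' are merged with [combine_scores()] (prior 0); self-pairs are dropped,
#' as are transferred edges below the configured minimum score. Edges
#' whose proteins have no ortholog in the target species are skipped and
#' recorded.
#'
#' @param source data frame of source edges with columns `gene_a`,
#'   `gene_b` and a score column.
#' @param source_species,target_species species IDs present in the tree.
#' @param groups a self-consistent [ortholog_groups()] object (run
#'   [enforce_consistency()] first).
#' @param tree a [clade_tree()].
#' @param config a [transfer_config()].
#' @param score_col name of the score column in `source` (default
#'   `"combined"`, falling back to `"score"`).
#' @return data frame of transferred edges (`gene_a`, `gene_b`,
#'   `combined`), with a `skipped` attribute: data frame of source edges
#'   that could not be transferred and the reason.
#' @export
transfer_interactions <- function(source, source_species, target_species,
                                  groups, tree, config = transfer_config(),
                                  score_col = NULL) {
  stopifnot(inherits(groups, "ortholog_groups"), inherits(tree, "clade_tree"))
  all_species <- unique(unlist(tree$species))
  if (!source_species %in% all_species) stop("unknown species: ", source_species)
  if (!target_species %in% all_species) stop("unknown species: ", target_species)
  if (is.null(score_col))
    score_col <- if ("combined" %in% names(source)) "combined" else "score"
  clade <- lowest_common_clade(tree, source_species, target_species)
  grp <- groups_at(groups, clade)
  sp <- groups$protein_species
  members_by_group <- split(names(grp), grp)
  target_members <- lapply(members_by_group, function(p)
    p[sp[p] == target_species])

  acc <- new.env(parent = emptyenv())  # pair key -> vector of scores
  skipped <- list()
  skip <- function(a, b, reason)
    skipped[[length(skipped) + 1L]] <<- data.frame(gene_a = a, gene_b = b,
                                                   reason = reason)
  for (i in seq_len(nrow(source))) {
    a <- source$gene_a[i]; b <- source$gene_b[i]
    S <- source[[score_col]][i]
    ga <- grp[a]; gb <- grp[b]
    if (is.na(ga) || is.na(gb)) { skip(a, b, "protein not in any group at transfer clade"); next }
    A <- target_members[[ga]]; B <- target_members[[gb]]
    if (!length(A) || !length(B)) { skip(a, b, "no ortholog in target species"); next }
    w <- S * (length(A) * length(B))^(-config$gamma)
    for (x in A) for (y in B) {
      if (x == y) next
      key <- if (x < y) paste0(x, "\t", y) else paste0(y, "\t", x)
      acc[[key]] <- c(acc[[key]], w)
    }
  }
  keys <- sort(ls(acc))
  if (length(keys)) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    out <- data.frame(gene_a = vapply(parts, `[[`, character(1), 1L),
                      gene_b = vapply(parts, `[[`, character(1), 2L),
                      combined = vapply(keys, function(k)
                        combine_scores(acc[[k]], prior = 0), numeric(1)))
    out <- out[out$combined >= config$min_transferred_score, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      combined = numeric())
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene_a = character(), gene_b = character(), reason = character())
  attr(out, "clade") <- clade
  out
}
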