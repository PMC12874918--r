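#' Single-linkage clustering of tree tips at a branch-length threshold
#'
#' Two tips fall in the same cluster iff they are connected by a chain of
#' tips whose consecutive path distances are all `<= threshold` (the
#' transitive closure of single linkage), equivalent to cutting a
#' single-linkage dendrogram over the path-distance matrix at the threshold.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param threshold branch-length (path-distance) threshold, default 0.02
#'   substitutions/site.
#' @return list of character vectors (tip sets), ordered by the DFS rank of
#'   each cluster's first tip.
#' @export
single_linkage_cluster <- function(tree, threshold = 0.02) {
  if (threshold < 0) stop("threshold must be non-negative")
  d <- tip_distances(tree)
  adj <- d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  rank <- .dfs_tip_rank(tree)
  clusters <- split(names(memb), memb)
  first <- vapply(clusters, function(tp) min(rank[tp]), numeric(1))
  unname(clusters[order(first)])
}

# nodes (by tipset) fully contained in `tips`; returns the maximal one,
# ties broken by earliest DFS-first member
.major_clade <- function(tipsets, dfs_rank, tips) {
  best <- NULL
  best_size <- 0L
  best_first <- Inf
  for (ts in tipsets) {
    if (length(ts) > length(tips) || !all(ts %in% tips)) next
    first <- min(dfs_rank[ts])
    if (length(ts) > best_size || (length(ts) == best_size && first < best_first)) {
      best <- ts
      best_size <- length(ts)
      best_first <- first
    }
  }
  if (is.null(best)) {
    # no node (not even a tip) inside the set cannot happen: tips are nodes
    stop("internal error: no clade contained in cluster")
  }
  best
}

#' Iterative monophyly refinement of tip clusters
#'
#' Repeatedly decomposes every non-monophyletic cluster into its major
#' monophyletic clade (the tree node with the most tips whose tip set is
#' contained in the cluster; ties by earliest DFS-first tip) plus outliers.
#' Outliers are re-partitioned into maximal monophyletic subgroups
#' (`outlier_mode = "maximal"`, default) or one singleton cluster per tip
#' (`outlier_mode = "singletons"`), each recorded as a subcluster of its
#' parent. Iteration continues until every multi-tip cluster is
#' monophyletic; every split strictly shrinks a cluster, so at most one
#' split round per tip is possible.
#'
#' @param tree rooted `phylo`.
#' @param clusters list of tip sets partitioning the tree's tips.
#' @param outlier_mode how outliers become new clusters.
#' @return list of precursors: each a list with `tips`, `parent_y` (index of
#'   the originating input cluster), `z` (subcluster creation order within
#'   the parent; `NA` for the retained major/unsplit cluster).
#' @export
refine_monophyly <- function(tree, clusters,
                             outlier_mode = c("maximal", "singletons")) {
  outlier_mode <- match.arg(outlier_mode)
  all_tips <- sort(unlist(clusters))
  if (anyDuplicated(all_tips) || !setequal(all_tips, tree$tip.label))
    stop("clusters must partition the tree's tips")

  tipsets <- .node_tipsets(tree)
  dfs_rank <- .dfs_tip_rank(tree)

  pre <- lapply(seq_along(clusters), function(i)
    list(tips = clusters[[i]], parent_y = i, z = NA_integer_))
  z_counter <- integer(length(clusters))

  queue <- seq_along(pre)
  rounds <- 0L
  while (length(queue) > 0) {
    rounds <- rounds + 1L
    if (rounds > length(tree$tip.label) + 1L)
      stop("internal error: refinement failed to terminate")
    next_queue <- integer(0)
    for (i in queue) {
      tips <- pre[[i]]$tips
      if (length(tips) < 2) next
      if (is_monophyletic(tree, tips) != "non_monophyletic") next
      major <- .major_clade(tipsets, dfs_rank, tips)
      outliers <- setdiff(tips, major)
      pre[[i]]$tips <- major
      py <- pre[[i]]$parent_y
      groups <- if (outlier_mode == "singletons") {
        as.list(outliers[order(dfs_rank[outliers])])
      } else {
        .maximal_mono_groups(tipsets, dfs_rank, outliers)
      }
      for (grp in groups) {
        z_counter[py] <- z_counter[py] + 1L
        pre[[length(pre) + 1L]] <- list(tips = grp, parent_y = py,
                                        z = z_counter[py])
        next_queue <- c(next_queue, length(pre))
      }
      # the shrunk major set may still need a check only if it is not a clade,
      # but by construction it is one; no requeue needed
    }
    queue <- next_queue
  }

  for (p in pre)
    if (length(p$tips) > 1 &&
        is_monophyletic(tree, p$tips) == "non_monophyletic")
      stop("internal error: non-monophyletic cluster after refinement")
  pre
}

# greedy decomposition of a tip set into maximal contained clades
.maximal_mono_groups <- function(tipsets, dfs_rank, tips) {
  groups <- list()
  remaining <- tips
  while (length(remaining) > 0) {
    grp <- .major_clade(tipsets, dfs_rank, remaining)
    groups[[length(groups) + 1L]] <- grp
    remaining <- setdiff(remaining, grp)
  }
  groups
}

#' Consensus / tree-walking taxonomy for one phylotype
#'
#' If the phylotype holds at least one database tip, its taxonomy is the
#' strict rank-wise consensus of those tips (`direct_consensus`). Otherwise
#' the algorithm walks from the MRCA of the member tips toward the root; at
#' the first ancestor subtending at least one database tip that is neither
#' long-branch-flagged nor the sole member of a monotypic phylotype, the
#' taxonomy is the strict consensus of those tips truncated above species
#' rank (`lca_walk`). Reaching the root without valid tips yields an empty
#' lineage.
#'
#' @param tree rooted `phylo`.
#' @param member_tips tip labels of the phylotype.
#' @param records tip-record data.frame (with `long_branch` flags set).
#' @param monotypic_db_tips database tips that are sole members of their own
#'   phylotype (excluded during the walk).
#' @param rule consensus rule, see [consensus_taxonomy()].
#' @return list with `taxonomy` (named character) and `source`
#'   (`"direct_consensus"` or `"lca_walk"`).
#' @export
assign_taxonomy <- function(tree, member_tips, records,
                            monotypic_db_tips = character(0),
                            rule = "strict") {
  rec <- records[match(member_tips, records$tip_id), ]
  db_in <- rec$tip_id[rec$kind == "database"]
  if (length(db_in) > 0) {
    tax <- consensus_taxonomy(rec$lineage[rec$kind == "database"], rule = rule)
    return(list(taxonomy = tax, source = "direct_consensus"))
  }

  n_tip <- ape::Ntip(tree)
  node <- if (length(member_tips) == 1)
    match(member_tips, tree$tip.label) else ape::getMRCA(tree, member_tips)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]

  db_all <- records$tip_id[records$kind == "database"]
  invalid <- union(records$tip_id[records$long_branch], monotypic_db_tips)
  valid_db <- setdiff(db_all, invalid)

  repeat {
    under <- tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
    found <- intersect(under, valid_db)
    if (length(found) > 0) {
      lins <- records$lineage[match(found, records$tip_id)]
      tax <- consensus_taxonomy(lins, rule = rule)
      tax <- tax[setdiff(names(tax), "species")]  # above species level
      return(list(taxonomy = tax, source = "lca_walk"))
    }
    if (node == root) return(list(taxonomy = character(0), source = "lca_walk"))
    node <- parent[node]
  }
}

#' Name refined phylotypes
#'
#' A phylotype whose strict consensus resolves to a species by direct
#' consensus is named by the species binomial. Every other phylotype is
#' named `"<deepest taxon> pt x.y"` (or bare `"pt x.y"` for an empty
#' lineage): `x` is the subtree index, `y` numbers the original clusters by
#' DFS order of their first tip, subclusters created by refinement splits
#' append `.z` (creation order within the parent), and monotypic phylotypes
#' replace `y` with `"M"` and take a subtree-wide monotypic counter as `z`.
#' Species names that would collide fall back to the `pt` form so IDs stay
#' unique.
#'
#' @param precursors output of [refine_monophyly()], each element augmented
#'   with `taxonomy` and `taxonomy_source` (see [assign_taxonomy()]).
#' @param subtree_index integer `x` of the subtree.
#' @param dfs_rank named DFS ranks of the subtree's tips.
#' @return data.frame: `phylotype_id`, `x`, `y`, `z`, `status`, `lineage`,
#'   `taxonomy_source`, `n_tips`, `tips` (list column).
#' @export
name_phylotypes <- function(precursors, subtree_index, dfs_rank) {
  first_tip <- vapply(precursors, function(p) min(dfs_rank[p$tips]), numeric(1))
  # y numbers the original clusters by DFS order of their first tip (over all
  # fragments that originated from the same input cluster)
  orig_ids <- sort(unique(vapply(precursors, function(p) p$parent_y, integer(1))))
  orig_first <- vapply(orig_ids, function(oy) {
    min(first_tip[vapply(precursors, function(p) p$parent_y == oy, logical(1))])
  }, numeric(1))
  y_of_orig <- stats::setNames(rank(orig_first, ties.method = "first"), orig_ids)

  n <- length(precursors)
  status <- ifelse(vapply(precursors, function(p) length(p$tips), integer(1)) == 1,
                   "monotypic", "monophyletic")
  ord_mono <- order(first_tip)
  mono_counter <- stats::setNames(seq_len(sum(status == "monotypic")),
                                  ord_mono[status[ord_mono] == "monotypic"])

  ids <- character(n); ys <- character(n); zs <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- precursors[[i]]
    if (status[i] == "monotypic") {
      ys[i] <- "M"
      zs[i] <- unname(mono_counter[as.character(i)])
    } else {
      ys[i] <- as.character(y_of_orig[as.character(p$parent_y)])
      zs[i] <- p$z
    }
    suffix <- sprintf("pt %d.%s%s", subtree_index, ys[i],
                      if (is.na(zs[i])) "" else paste0(".", zs[i]))
    tax <- p$taxonomy
    deepest <- if (length(tax)) unname(tax[length(tax)]) else ""
    if ("species" %in% names(tax) && p$taxonomy_source == "direct_consensus") {
      ids[i] <- unname(tax[["species"]])
    } else {
      ids[i] <- if (nzchar(deepest)) paste(deepest, suffix) else suffix
    }
  }
  # resolve species-name collisions by falling back to the pt form
  dup <- ids[duplicated(ids)]
  for (d in unique(dup)) {
    idx <- which(ids == d)
    for (i in idx) {
      suffix <- sprintf("pt %d.%s%s", subtree_index, ys[i],
                        if (is.na(zs[i])) "" else paste0(".", zs[i]))
      ids[i] <- paste(d, suffix)
    }
  }
  if (anyDuplicated(ids)) stop("internal error: duplicate phylotype IDs")

  data.frame(
    phylotype_id = ids, x = subtree_index, y = ys, z = zs,
    status = status,
    lineage = vapply(precursors, function(p) format_lineage(p$taxonomy), character(1)),
    taxonomy_source = vapply(precursors, function(p) p$taxonomy_source, character(1)),
    n_tips = vapply(precursors, function(p) length(p$tips), integer(1)),
    tips = I(lapply(precursors, function(p) unname(p$tips))),
    stringsAsFactors = FALSE
  )
}

#' Parse a phylotype ID back into its (x, y, z) components
#'
#' @param ids character vector of phylotype IDs.
#' @return data.frame with `x` (int), `y` (`"M"` or integer string), `z`
#'   (int or NA); species-binomial IDs without a `pt` suffix return NA rows.
#' @export
parse_phylotype_id <- function(ids) {
  m <- regmatches(ids, regexec("pt ([0-9]+)\\.([0-9]+|M)(\\.([0-9]+))?$", ids))
  out <- lapply(m, function(g) {
    if (length(g) == 0) return(c(NA, NA, NA))
    c(g[2], g[3], if (nzchar(g[5])) g[5] else NA)
  })
  out <- do.call(rbind, out)
  data.frame(x = as.integer(out[, 1]), y = out[, 2], z = as.integer(out[, 3]),
             stringsAsFactors = FALSE)
}

#' Phylotype one or more subtrees end to end
#'
#' For each subtree: midpoint-roots, flags long branches, clusters tips by
#' single linkage at the branch-length threshold, refines monophyly, assigns
#' consensus/tree-walking taxonomy (monotypic database tips and long-branch
#' tips excluded from LCA walks), and names phylotypes.
#'
#' @param trees list of `phylo` subtrees (or a single `phylo`).
#' @param records tip-record data.frame covering all tips of all subtrees.
#' @param threshold clustering threshold (default 0.02).
#' @param long_branch_ratio diameter-ratio threshold for long-branch flags.
#' @param outlier_mode see [refine_monophyly()].
#' @param consensus_rule see [consensus_taxonomy()].
#' @return object of class `phylotype_set`: list with `phylotypes`
#'   (per-phylotype table), `membership` (tip_id -> phylotype_id), `records`
#'   (with long-branch flags set).
#' @export
phylotype_tree <- function(trees, records, threshold = 0.02,
                           long_branch_ratio = 1.5,
                           outlier_mode = "maximal",
                           consensus_rule = "strict") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  all_tabs <- list()
  for (x in seq_along(trees)) {
    tr <- midpoint_root(trees[[x]])
    lb <- if (ape::Ntip(tr) >= 3)
      flag_long_branches(tr, long_branch_ratio) else character(0)
    records$long_branch[records$tip_id %in% lb] <- TRUE

    clusters <- single_linkage_cluster(tr, threshold)
    pre <- refine_monophyly(tr, clusters, outlier_mode = outlier_mode)

    # database tips that ended up as the sole member of a phylotype are
    # treated as monotypic and skipped during the LCA walk
    singles <- unlist(lapply(pre, function(p) if (length(p$tips) == 1) p$tips))
    mono_db <- intersect(singles,
                         records$tip_id[records$kind == "database"])
    for (i in seq_along(pre)) {
      ta <- assign_taxonomy(tr, pre[[i]]$tips, records,
                            monotypic_db_tips = mono_db, rule = consensus_rule)
      pre[[i]]$taxonomy <- ta$taxonomy
      pre[[i]]$taxonomy_source <- ta$source
    }
    all_tabs[[x]] <- name_phylotypes(pre, x, .dfs_tip_rank(tr))
  }
  tab <- do.call(rbind, all_tabs)
  if (anyDuplicated(tab$phylotype_id)) stop("internal error: duplicate phylotype IDs across subtrees")
  membership <- data.frame(
    tip_id = unlist(tab$tips),
    phylotype_id = rep(tab$phylotype_id, tab$n_tips),
    stringsAsFactors = FALSE
  )
  structure(list(phylotypes = tab, membership = membership, records = records),
            class = "phylotype_set")
}

#' @export
print.phylotype_set <- function(x, ...) {
  cat("phylotype_set:", nrow(x$phylotypes), "phylotypes over",
      nrow(x$membership), "tips in", length(unique(x$phylotypes$x)),
      "subtree(s)\n")
  cat("  monophyletic:", sum(x$phylotypes$status == "monophyletic"),
      " monotypic:", sum(x$phylotypes$status == "monotypic"), "\n")
  invisible(x)
}
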