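#' @importFrom ape read.tree write.tree getMRCA
#' @importFrom stats median cor kruskal.test pbeta rbeta rgamma runif rnorm setNames
#' @importFrom utils read.delim write.table combn head
NULL

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
TAX_PREFIX <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

#' Read a newick tree
#'
#' Parses a newick string or file into an `ape::phylo` object, validating the
#' invariants the downstream phylotyping relies on: unique tip labels and
#' defined, non-negative branch lengths. Missing branch lengths are set to 0
#' with a warning.
#'
#' @param source a file path or a literal newick string (detected by the
#'   presence of `(`/`;`).
#' @return a `phylo` object, children stored in input order.
#' @export
read_newick <- function(source) {
  is_text <- grepl("[();]", source)
  txt <- if (is_text) source else paste(readLines(source, warn = FALSE), collapse = "")
  .check_newick_syntax(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("newick parse error: could not parse tree text")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warning("newick has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

# cheap structural scan so common malformations report a byte offset
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at byte %d: unmatched ')'", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("newick parse error at byte %d: %d unclosed '('", nchar(txt), depth))
  if (!grepl(";", txt))
    stop(sprintf("newick parse error at byte %d: missing terminating ';'", nchar(txt)))
  invisible(TRUE)
}

#' Write a tree to newick
#'
#' @param tree a `phylo` object.
#' @param path optional file path; if `NULL` the newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Midpoint-root a tree
#'
#' Roots the tree on the edge bisecting the longest tip-to-tip path, so the
#' two farthest tips are equidistant from the root.
#'
#' @param tree a `phylo` with at least 2 tips.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (ape::Ntip(tree) < 2) stop("midpoint rooting needs >= 2 tips")
  if (is.null(tree$edge.length) || all(tree$edge.length <= 0))
    stop("degenerate tree, midpoint undefined")
  if (ape::Ntip(tree) == 2) return(.midpoint_two_tips(tree))
  phangorn::midpoint(tree)
}

.midpoint_two_tips <- function(tree) {
  # phangorn::midpoint is unreliable on 2-tip trees; bisect directly
  tot <- sum(tree$edge.length)
  half <- tot / 2
  txt <- sprintf("(%s:%.12g,%s:%.12g);", tree$tip.label[1], half, tree$tip.label[2], half)
  ape::read.tree(text = txt)
}

#' Tip-to-tip path distance matrix
#'
#' @param tree a `phylo`.
#' @return symmetric matrix of summed branch lengths, tip labels as dimnames.
#' @export
tip_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Path distance between two tips
#'
#' Sum of branch lengths along the unique path connecting two tips.
#'
#' @param tree a `phylo`.
#' @param tip_a,tip_b tip labels.
#' @return non-negative scalar; 0 when `tip_a == tip_b`.
#' @export
path_distance <- function(tree, tip_a, tip_b) {
  if (!(tip_a %in% tree$tip.label)) stop("unknown tip: ", tip_a)
  if (!(tip_b %in% tree$tip.label)) stop("unknown tip: ", tip_b)
  if (tip_a == tip_b) return(0)
  d <- tip_distances(tree)
  unname(d[tip_a, tip_b])
}

# descendant tip labels for every node (1..Ntip+Nnode), as a list
.node_tipsets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# DFS (cladewise, left-to-right) visiting order of tips; rank named by label
.dfs_tip_rank <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  tip_idx <- tr$edge[tr$edge[, 2] <= ape::Ntip(tr), 2]
  if (ape::Ntip(tree) == 1) tip_idx <- 1L
  stats::setNames(seq_along(tip_idx), tree$tip.label[tip_idx])
}

#' Monophyly status of a tip set
#'
#' Classifies a tip set on a rooted tree as `monotypic` (a single tip),
#' `monophyletic` (the MRCA subtends exactly the set) or `non_monophyletic`.
#'
#' @param tree a rooted `phylo`.
#' @param tips character vector of tip labels (non-empty).
#' @return one of `"monophyletic"`, `"non_monophyletic"`, `"monotypic"`.
#' @export
is_monophyletic <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) == 0) stop("empty tip set")
  if (!all(tips %in% tree$tip.label)) stop("unknown tip(s) in set")
  if (length(tips) == 1) return("monotypic")
  mrca <- ape::getMRCA(tree, tips)
  clade <- tree$tip.label[phangorn::Descendants(tree, mrca, type = "tips")[[1]]]
  if (setequal(clade, tips)) "monophyletic" else "non_monophyletic"
}

#' Flag disproportionately long tip branches
#'
#' A tip is flagged when removing it shrinks the tree diameter (longest
#' tip-to-tip path) by at least `ratio_threshold`:
#' `diameter(T) / diameter(T - tip) >= ratio_threshold`. The rule is invariant
#' under rerooting since it only uses path distances.
#'
#' @param tree a `phylo` with >= 3 tips.
#' @param ratio_threshold flagging ratio (default 1.5). A threshold of 1
#'   degenerately flags every tip.
#' @return character vector of flagged tip labels (possibly empty).
#' @export
flag_long_branches <- function(tree, ratio_threshold = 1.5) {
  if (ape::Ntip(tree) < 3) stop("long-branch flagging needs >= 3 tips")
  d <- tip_distances(tree)
  diam <- max(d)
  flagged <- vapply(rownames(d), function(tp) {
    keep <- setdiff(rownames(d), tp)
    sub_diam <- max(d[keep, keep])
    if (sub_diam <= 0) return(TRUE)
    diam / sub_diam >= ratio_threshold
  }, logical(1))
  names(flagged)[flagged]
}

# ---- Taxonomy helpers -------------------------------------------------------

#' Parse a semicolon-delimited lineage string
#'
#' Accepts `"d__Fungi;p__Mucoromycota;...;s__Mucor zonatus"`. The lineage may
#' terminate early (LCA-truncated); gaps are not allowed.
#'
#' @param lineage lineage string ("" for an empty lineage).
#' @return named character vector (names = ranks, in domain-to-species order).
#' @export
parse_lineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage)) return(character(0))
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  pref <- substr(parts, 1, 1)
  ranks <- unname(TAX_PREFIX[pref])
  if (anyNA(ranks)) stop("unknown rank prefix in lineage: ", lineage)
  vals <- sub("^[a-z]__", "", parts)
  expected <- TAX_RANKS[seq_along(ranks)]
  if (!identical(ranks, expected))
    stop("lineage ranks out of order or gapped: ", lineage)
  stats::setNames(vals, ranks)
}

#' Format a rank-named taxonomy back into a lineage string
#' @param taxonomy named character vector as returned by [parse_lineage()].
#' @return semicolon-delimited lineage string ("" for empty).
#' @export
format_lineage <- function(taxonomy) {
  if (length(taxonomy) == 0) return("")
  pref <- names(TAX_PREFIX)[match(names(taxonomy), TAX_PREFIX)]
  paste(paste0(pref, "__", unname(taxonomy)), collapse = ";")
}

#' Strict rank-wise consensus of lineages
#'
#' Keeps the deepest prefix of ranks at which all lineages carry the same
#' name; stops at the first rank with disagreement or a missing name.
#'
#' @param lineages character vector of lineage strings.
#' @param rule `"strict"` (unanimous, default) or `"majority"` (>50%).
#' @return named character vector (possibly empty).
#' @export
consensus_taxonomy <- function(lineages, rule = c("strict", "majority")) {
  rule <- match.arg(rule)
  taxa <- lapply(lineages, parse_lineage)
  out <- character(0)
  for (rk in TAX_RANKS) {
    vals <- vapply(taxa, function(tx) if (rk %in% names(tx)) tx[[rk]] else NA_character_,
                   character(1))
    if (anyNA(vals)) break
    if (rule == "strict") {
      if (length(unique(vals)) != 1) break
      out[rk] <- vals[1]
    } else {
      tab <- sort(table(vals), decreasing = TRUE)
      if (tab[1] <= length(vals) / 2) break
      out[rk] <- names(tab)[1]
    }
  }
  out
}

#' Read a tip-record sidecar table
#'
#' TSV with columns `tip_id`, `kind` (`query`/`database`), `lineage`
#' (semicolon-delimited, empty for queries).
#'
#' @param path TSV path.
#' @return data.frame with `tip_id`, `kind`, `lineage`, `long_branch` (FALSE).
#' @export
read_tip_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tip_records(df$tip_id, df$kind, df$lineage)
}

#' Construct a tip-record table
#'
#' @param tip_id tip labels (unique).
#' @param kind `"query"` or `"database"` per tip.
#' @param lineage lineage strings; must be empty for query tips and non-empty
#'   for database tips.
#' @return validated data.frame with a `long_branch` flag column (FALSE).
#' @export
tip_records <- function(tip_id, kind, lineage = NULL) {
  if (is.null(lineage)) lineage <- ifelse(kind == "database", NA_character_, "")
  lineage[is.na(lineage)] <- ""
  if (anyDuplicated(tip_id)) stop("duplicate tip_id in tip records")
  if (!all(kind %in% c("query", "database"))) stop("kind must be query or database")
  if (any(kind == "query" & nzchar(lineage)))
    stop("query tips must have empty taxonomy")
  if (any(kind == "database" & !nzchar(lineage)))
    stop("database tips must carry a lineage")
  for (ln in lineage[nzchar(lineage)]) parse_lineage(ln)  # validates rank order
  data.frame(tip_id = tip_id, kind = kind, lineage = lineage,
             long_branch = FALSE, stringsAsFactors = FALSE)
}
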