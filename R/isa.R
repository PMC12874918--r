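# weighted Pearson correlation of each column of X with vector p,
# weights w (sum to 1 after normalization); returns NA for zero variance
.weighted_cor <- function(X, p, w) {
  w <- w / sum(w)
  mx <- colSums(X * w)
  mp <- sum(p * w)
  vx <- colSums(X^2 * w) - mx^2
  vp <- sum(p^2 * w) - mp^2
  cov <- colSums(X * p * w) - mx * mp
  r <- cov / sqrt(pmax(vx, 0) * max(vp, 0))
  r[!is.finite(r)] <- NA_real_
  r
}

#' Group-equalized indicator correlation (r.g) with permutation test
#'
#' The group-equalized point-biserial correlation: each sample carries
#' weight `1 / (K * n_g)` for its group, and `r.g` is the weighted Pearson
#' correlation between a phylotype's abundance and the target-group
#' indicator. Significance comes from a one-sided permutation test of the
#' group labels: `p = (#(r_perm >= r_obs) + 1) / (n_perm + 1)`, or exact
#' enumeration of all distinct label arrangements when `exact = TRUE`.
#'
#' @param rel samples x phylotypes abundance matrix (typically rarefied
#'   relative abundances).
#' @param groups group label per sample.
#' @param target_group the indicated group (e.g. `"S-soil"`).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param exact enumerate all distinct assignments of the target indicator
#'   (feasible for small n); `p = mean(r_perm >= r_obs)` over arrangements
#'   including the observed one.
#' @return data.frame: `phylotype_id`, `r_g`, `p_value` (NA abundance
#'   variance gives `r_g = NA`, `p = 1`).
#' @export
isa_rg <- function(rel, groups, target_group, n_perm = 1000, seed = 1,
                   exact = FALSE) {
  groups <- as.character(groups)
  if (!target_group %in% groups) stop("target_group absent from groups")
  X <- as.matrix(rel)
  n <- nrow(X)
  K <- length(unique(groups))
  n_g <- table(groups)
  w_of <- function(g) 1 / (K * as.numeric(n_g[g]))
  w_obs <- vapply(groups, w_of, numeric(1))
  p_obs <- as.numeric(groups == target_group)
  r_obs <- .weighted_cor(X, p_obs, w_obs)

  if (exact) {
    pos <- utils::combn(n, sum(p_obs))
    ge <- rep(0L, ncol(X))
    for (j in seq_len(ncol(pos))) {
      gp <- rep(setdiff(unique(groups), target_group)[1], n)
      gp[pos[, j]] <- target_group
      # group sizes are fixed, but weights follow the permuted labels
      wp <- vapply(gp, w_of, numeric(1))
      rp <- .weighted_cor(X, as.numeric(gp == target_group), wp)
      ge <- ge + as.integer(!is.na(rp) & !is.na(r_obs) & rp >= r_obs - 1e-12)
    }
    p_val <- ge / ncol(pos)
  } else {
    set.seed(seed)
    ge <- rep(0L, ncol(X))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      rp <- .weighted_cor(X, p_obs[perm], w_obs[perm])
      ge <- ge + as.integer(!is.na(rp) & !is.na(r_obs) & rp >= r_obs - 1e-12)
    }
    p_val <- (ge + 1) / (n_perm + 1)
  }
  p_val[is.na(r_obs)] <- 1
  data.frame(phylotype_id = colnames(X), r_g = unname(r_obs),
             p_value = unname(p_val), stringsAsFactors = FALSE,
             row.names = NULL)
}
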