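# Fisher/LDA discriminant with ridge-regularized pooled within-class
# covariance; w scaled so the discriminant has unit within-class variance.
.lda_coef <- function(X, y) {
  classes <- unique(y)
  mu <- lapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  Sw <- matrix(0, ncol(X), ncol(X))
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(Xi)
  }
  Sw <- Sw / max(1, nrow(X) - length(classes))
  ridge <- max(mean(diag(Sw)), 1e-8) * 1e-4
  Sw <- Sw + diag(ridge, ncol(X))
  w <- solve(Sw, mu[[1]] - mu[[2]])
  s2 <- drop(t(w) %*% Sw %*% w)
  if (s2 > 0) w <- w / sqrt(s2)
  list(w = w, dmu = mu[[1]] - mu[[2]])
}

#' Kruskal-Wallis screen plus bootstrap LDA effect sizes
#'
#' Relative abundances are scaled to a per-sample sum of 1e6. Each feature
#' is screened by a Kruskal-Wallis test across classes; features passing
#' `alpha` receive an LDA effect size: the mean over `n_boot` bootstrap
#' subsamples (two thirds of each class's samples) of
#' `log10(max(1, (|w_f| + |dmu_f|) / 2))`, where `w_f` is the feature's
#' linear-discriminant coefficient (unit within-class variance scaling;
#' one-vs-rest for more than two classes, taking the max across axes) and
#' `dmu_f` the between-class difference of scaled feature means.
#'
#' @param rel samples x phylotypes relative-abundance matrix (rows sum to 1).
#' @param classes factor/character class label per sample (>= 2 classes with
#'   >= 3 samples each; smaller classes are excluded with a warning).
#' @param n_boot bootstrap subsamples (default 1000).
#' @param alpha KW screening level (default 0.05).
#' @param seed RNG seed.
#' @return data.frame: `phylotype_id`, `p_value`, `lda_score`, `direction`
#'   (class with the higher scaled mean).
#' @export
lefse_effect_size <- function(rel, classes, n_boot = 1000, alpha = 0.05,
                              seed = 1) {
  classes <- as.character(classes)
  tab <- table(classes)
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    warning("class(es) with < 3 samples excluded: ", paste(small, collapse = ", "))
    keep <- classes %in% names(tab)[tab >= 3]
    rel <- rel[keep, , drop = FALSE]
    classes <- classes[keep]
  }
  if (length(unique(classes)) < 2) stop("need >= 2 classes with >= 3 samples")
  X <- rel * 1e6
  n_feat <- ncol(X)

  p_vals <- vapply(seq_len(n_feat), function(j) {
    x <- X[, j]
    if (length(unique(x)) == 1) return(1)
    stats::kruskal.test(x, factor(classes))$p.value
  }, numeric(1))

  direction <- vapply(seq_len(n_feat), function(j) {
    mu <- tapply(X[, j], classes, mean)
    names(mu)[which.max(mu)]
  }, character(1))

  scores <- numeric(n_feat)
  sig <- which(p_vals <= alpha)
  if (length(sig) > 0) {
    set.seed(seed)
    Xs <- X[, sig, drop = FALSE]
    class_set <- sort(unique(classes))
    acc <- matrix(0, n_boot, length(sig))
    idx_by_class <- split(seq_along(classes), classes)
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_class, function(ii)
        sample(ii, size = max(2, floor(2 * length(ii) / 3)), replace = TRUE)))
      Xb <- Xs[take, , drop = FALSE]
      yb <- classes[take]
      per_axis <- matrix(0, 0, length(sig))
      if (length(class_set) == 2) {
        fit <- .lda_coef(Xb, yb)
        per_axis <- rbind(per_axis, (abs(fit$w) + abs(fit$dmu)) / 2)
      } else {
        for (cl in class_set) {
          fit <- .lda_coef(Xb, ifelse(yb == cl, cl, "rest"))
          per_axis <- rbind(per_axis, (abs(fit$w) + abs(fit$dmu)) / 2)
        }
      }
      acc[b, ] <- apply(per_axis, 2, max)
    }
    scores[sig] <- colMeans(log10(pmax(acc, 1)))
  }
  data.frame(phylotype_id = colnames(rel), p_value = p_vals,
             lda_score = scores, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-niche LEfSe comparison
#'
#' Runs the KW + bootstrap LDA effect-size analysis across shiro niches
#' (default S-soil, S-root, S-fruitbody) and assigns each significant
#' phylotype a winning niche (the class with the maximum mean scaled
#' abundance), thresholded at a kingdom-specific minimum LDA score (4 for
#' bacteria, 3.5 for fungi).
#'
#' @param table a rarefied `community_table`.
#' @param niches niches to compare (those missing from the data are dropped
#'   with a warning).
#' @param lda_min minimum LDA score.
#' @param alpha,n_boot,seed see [lefse_effect_size()].
#' @return data.frame: `phylotype_id`, `p_value`, `lda_score`, `niche`,
#'   `significant`.
#' @export
cross_niche_lefse <- function(table, niches = c("S-soil", "S-root", "S-fruitbody"),
                              lda_min = 3.5, alpha = 0.05, n_boot = 1000,
                              seed = 1) {
  present <- intersect(niches, unique(table$metadata$niche))
  if (length(present) < length(niches))
    warning("missing niche(s): ", paste(setdiff(niches, present), collapse = ", "))
  if (length(present) < 2) stop("need >= 2 niches with samples")
  keep <- table$metadata$niche %in% present
  rel <- relative_abundance(table)[keep, , drop = FALSE]
  res <- lefse_effect_size(rel, table$metadata$niche[keep],
                           n_boot = n_boot, alpha = alpha, seed = seed)
  res$niche <- res$direction
  res$significant <- res$p_value <= alpha & res$lda_score >= lda_min
  res[, c("phylotype_id", "p_value", "lda_score", "niche", "significant")]
}
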