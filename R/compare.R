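#' Replicate agreement between two screens of the same bait
#'
#' Shared-hit fraction and density correlation between two interactome
#' tables over the same prey universe. `percent_shared` is intersection
#' over union of the positive-call sets (the reading under which a printed
#' shared/total hit pair reproduces its printed percentage). Pearson's r
#' is computed over preys positive in at least one replicate, on raw mean
#' densities with non-hit densities zero-filled.
#'
#' @param A,B Interactome data frames (`prey`, `mean_density`, `positive`)
#'   for the same bait; prey universes must be identical.
#' @return List with `shared`, `union`, `percent_shared`, `pearson_r`.
#' @examples
#' a <- data.frame(prey = c("x", "y"), mean_density = c(5, 2),
#'                 positive = c(TRUE, TRUE))
#' replicate_agreement(a, a)$percent_shared # 100
#' @export
replicate_agreement <- function(A, B) {
  if (!setequal(A$prey, B$prey) || anyDuplicated(A$prey) ||
      anyDuplicated(B$prey)) {
    stop("replicate tables must share one identical prey universe",
         call. = FALSE)
  }
  hits_a <- A$prey[A$positive %in% TRUE]
  hits_b <- B$prey[B$positive %in% TRUE]
  shared <- length(intersect(hits_a, hits_b))
  un <- length(union(hits_a, hits_b))
  either <- union(hits_a, hits_b)
  da <- ifelse(A$prey %in% hits_a, A$mean_density, 0)[match(either, A$prey)]
  db <- ifelse(B$prey %in% hits_b, B$mean_density, 0)[match(either, B$prey)]
  r <- if (length(either) >= 2 && stats::sd(da) > 0 && stats::sd(db) > 0) {
    stats::cor(da, db)
  } else {
    NA_real_
  }
  list(shared = shared, union = un,
       percent_shared = if (un > 0) 100 * shared / un else NA_real_,
       pearson_r = r)
}

#' Bait-enriched and bait-unique prey sets
#'
#' A prey is enriched for a bait when it is a positive hit for that bait
#' and its mean density is at least `fold` times the maximum mean density
#' over all other baits (a zero elsewhere makes the ratio infinite, hence
#' enriched). A prey is unique when positive for exactly one bait.
#'
#' @param tables Named list (>= 2) of interactome data frames sharing one
#'   prey universe.
#' @param fold Enrichment ratio threshold (> 1), default twofold.
#' @return Named list per bait: `enriched` and `unique` character vectors.
#' @export
bait_enrichment <- function(tables, fold = 2) {
  stopifnot(length(tables) >= 2)
  if (fold <= 1) stop("fold threshold must exceed 1", call. = FALSE)
  prey <- tables[[1]]$prey
  for (t in tables[-1]) {
    if (!setequal(t$prey, prey)) {
      stop("interactome tables must share one prey universe", call. = FALSE)
    }
  }
  if (is.null(names(tables))) names(tables) <- paste0("bait", seq_along(tables))
  dens <- sapply(tables, function(t) {
    d <- ifelse(t$positive %in% TRUE, t$mean_density, 0)
    d[match(prey, t$prey)]
  })
  pos <- sapply(tables, function(t) (t$positive %in% TRUE)[match(prey, t$prey)])
  out <- list()
  for (b in seq_along(tables)) {
    other_max <- apply(dens[, -b, drop = FALSE], 1, max)
    enr <- pos[, b] & (dens[, b] >= fold * other_max | other_max == 0)
    uniq <- pos[, b] & rowSums(pos) == 1L
    out[[names(tables)[b]]] <- list(enriched = prey[enr], unique = prey[uniq])
  }
  out
}

#' Venn-region counts for k hit sets
#'
#' Counts every non-empty membership pattern (2^k - 1 regions). Region
#' counts sum to the size of the union.
#'
#' @param sets Named list (k >= 2) of character vectors.
#' @return Data frame `region` (set names joined by `&`), `count`.
#' @examples
#' venn_counts(list(a = c("x", "y"), b = c("y", "z")))
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  all_el <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_el %in% s, logical(length(all_el)))
  if (length(all_el) == 1) memb <- matrix(memb, nrow = 1)
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  data.frame(
    region = apply(patterns, 1, function(p) {
      paste(names(sets)[as.logical(p)], collapse = "&")
    }),
    count = apply(patterns, 1, function(p) {
      if (length(all_el) == 0) return(0L)
      sum(apply(memb, 1, function(m) all(m == as.logical(p))))
    }),
    row.names = NULL)
}

#' Annotation-term enrichment of a hit set against a library background
#'
#' Upper-tail hypergeometric test per term: with `N` background preys of
#' which `K` carry the term, and `n` hits of which `k` carry it,
#' `p_raw = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Bonferroni
#' correction multiplies by the number of terms with at least one
#' annotated hit (terms annotating no hit get `p_raw = 1` and do not count
#' toward the correction).
#'
#' @param hits Character vector of hit preys (subset of `background`).
#' @param annotations Data frame `prey`, `term` (one pair per row); every
#'   annotated prey must be in the background.
#' @param background Character vector: the prey-library background set.
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return Data frame `term,k,n,K,N,p_raw,p_adj,significant`, ordered by
#'   `p_adj`.
#' @export
term_enrichment <- function(hits, annotations, background, alpha = 0.01) {
  hits <- unique(hits)
  background <- unique(background)
  if (!all(hits %in% background)) {
    stop("hits must be a subset of the background set", call. = FALSE)
  }
  ann <- unique(annotations[annotations$prey %in% background,
                            c("prey", "term")])
  if (!all(unique(annotations$prey) %in% background)) {
    stop("annotated preys outside the background set", call. = FALSE)
  }
  N <- length(background)
  n <- length(hits)
  terms <- unique(ann$term)
  K <- vapply(terms, function(t) sum(ann$term == t), 0L)
  k <- vapply(terms, function(t) sum(ann$prey[ann$term == t] %in% hits), 0L)
  p_raw <- ifelse(k == 0, 1,
                  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  m <- sum(k > 0)
  p_adj <- ifelse(k == 0, 1, pmin(1, p_raw * m))
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha, row.names = NULL)
  out[order(out$p_adj, out$p_raw, out$term), , drop = FALSE]
}

#' Row-wise hierarchical clustering of a density matrix
#'
#' Agglomerative clustering of the rows (preys) of a prey x bait mean
#' density matrix with Euclidean distance and complete linkage -- the
#' defaults of the common heatmap packages. The ordering is deterministic;
#' `stats::hclust` breaks distance ties by the lower merge index.
#'
#' @param mat Numeric matrix (rows complete; zero-fill non-hits).
#' @return List with `order` (row permutation), `merge` and `height`
#'   (agglomeration schedule as in [stats::hclust()]), and `hclust`.
#'   Fewer than 2 rows yield the identity ordering with an empty schedule.
#' @export
cluster_rows <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("density matrix must be complete", call. = FALSE)
  if (nrow(mat) < 2) {
    return(list(order = seq_len(nrow(mat)),
                merge = matrix(integer(0), 0, 2), height = numeric(0),
                hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "complete")
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}
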