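test_that("replicate agreement reproduces shared-hit arithmetic", {
  set.seed(10)
  # identical tables: 100% shared, r = 1
  a <- interactome(sprintf("p%02d", 1:20),
                   c(stats::rlnorm(10, 8, 1), rep(0, 10)),
                   rep(c(TRUE, FALSE), each = 10))
  ra <- replicate_agreement(a, a)
  expect_equal(ra$percent_shared, 100)
  expect_equal(ra$pearson_r, 1)

  # scale invariance of the density correlation
  b <- a
  b$mean_density <- 2 * a$mean_density
  expect_equal(replicate_agreement(a, b)$pearson_r, 1)

  # percent shared is intersection over union
  u <- sprintf("p%03d", 1:100)
  A <- interactome(u, as.numeric(seq_along(u)), u %in% u[1:40])
  B <- interactome(u, as.numeric(seq_along(u)), u %in% u[21:60])
  ra2 <- replicate_agreement(A, B)
  expect_equal(ra2$shared, 20)
  expect_equal(ra2$union, 60)
  expect_equal(ra2$percent_shared, 100 * 20 / 60)

  # mismatched universes are refused
  expect_error(replicate_agreement(A, B[-1, ]), "universe")
})

test_that("fold enrichment follows the max-over-other-baits rule", {
  u <- c("a", "b", "c")
  mk <- function(d, p) interactome(u, d, p)
  tabs <- list(x = mk(c(10, 10, 10), c(TRUE, TRUE, TRUE)),
               y = mk(c(4, 6, 0), c(TRUE, TRUE, FALSE)),
               z = mk(c(5, 4, 0), c(TRUE, TRUE, FALSE)))
  be <- bait_enrichment(tabs, fold = 2)
  # prey a: 10 >= 2*5 -> enriched for x; prey b: 10 < 2*6 -> not
  expect_setequal(be$x$enriched, c("a", "c"))
  # prey c: positive only for x, zero elsewhere -> unique and enriched
  expect_setequal(be$x$unique, "c")
  expect_length(be$y$enriched, 0)

  expect_error(bait_enrichment(tabs, fold = 1), "exceed 1")

  # disjointness at fold >= 2 when all densities are positive
  set.seed(11)
  for (i in 1:10) {
    dens <- matrix(stats::rlnorm(30, 3, 2), 10, 3)
    tabs2 <- lapply(1:3, function(j) {
      interactome(sprintf("p%02d", 1:10), dens[, j], rep(TRUE, 10))
    })
    names(tabs2) <- c("x", "y", "z")
    be2 <- bait_enrichment(tabs2, fold = 2)
    enr <- unlist(lapply(be2, `[[`, "enriched"))
    expect_equal(anyDuplicated(enr), 0L)
  }
})

test_that("venn regions enumerate memberships and conserve totals", {
  vc <- venn_counts(list(a = c("a", "b"), b = c("b", "c"), c = "b"))
  expect_equal(vc$count[vc$region == "a&b&c"], 1L)
  expect_equal(sum(vc$count), 3L)  # |union|

  # disjoint sets: all overlap regions zero
  vd <- venn_counts(list(a = c("1", "2"), b = c("3")))
  expect_equal(vd$count[vd$region == "a&b"], 0L)
  expect_equal(vd$count[vd$region == "a"], 2L)

  # identical sets: only the all-sets region is populated
  vi <- venn_counts(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(vi$count[vi$region == "a&b"], 5L)
  expect_equal(sum(vi$count), 5L)

  # totals: each set's size equals the sum over its incident regions
  set.seed(12)
  sets <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- c("x", "y", "z")
  vr <- venn_counts(sets)
  for (s in names(sets)) {
    inc <- grepl(s, vr$region, fixed = TRUE)
    expect_equal(sum(vr$count[inc]), length(unique(sets[[s]])))
  }
})

test_that("hypergeometric enrichment matches brute-force enumeration", {
  # worked example: background 10, term annotates 5, 4 hits all annotated
  bg <- sprintf("g%02d", 1:10)
  ann <- data.frame(prey = bg[1:5], term = "T1")
  res <- term_enrichment(bg[1:4], ann, bg)
  expect_equal(res$p_raw, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p_raw, choose(5, 4) / choose(10, 4), tolerance = 1e-12)

  # brute-force oracle on random universes of size <= 12
  set.seed(13)
  for (i in 1:8) {
    N <- sample(6:12, 1)
    bg <- sprintf("g%02d", seq_len(N))
    terms <- lapply(1:3, function(t) sample(N, sample(2:(N - 1), 1)))
    ann <- do.call(rbind, lapply(seq_along(terms), function(t) {
      data.frame(prey = bg[terms[[t]]], term = paste0("T", t))
    }))
    n <- sample(2:(N - 2), 1)
    hits <- sample(bg, n)
    res <- term_enrichment(hits, ann, bg)
    for (t in seq_along(terms)) {
      k_obs <- sum(bg[terms[[t]]] %in% hits)
      p_brute <- if (k_obs == 0) 1 else {
        brute_hyper_p(N, terms[[t]], n, k_obs)
      }
      expect_equal(res$p_raw[res$term == paste0("T", t)], p_brute,
                   tolerance = 1e-10)
    }
  }

  # hits = background: every p_raw is 1
  resb <- term_enrichment(bg, ann, bg)
  expect_true(all(resb$p_raw == 1))

  # terms annotating no hit are excluded from the Bonferroni divisor
  bg <- sprintf("g%02d", 1:10)
  ann2 <- data.frame(prey = c(bg[1:3], bg[8:10]),
                     term = rep(c("hit_term", "other"), each = 3))
  res2 <- term_enrichment(bg[1:3], ann2, bg)
  expect_equal(res2$p_adj[res2$term == "hit_term"],
               min(1, res2$p_raw[res2$term == "hit_term"] * 1))
  expect_equal(res2$p_raw[res2$term == "other"], 1)

  expect_error(term_enrichment("zz", ann2, bg), "subset")
})

test_that("row clustering follows Euclidean complete linkage", {
  m <- rbind(c(0, 0), c(0, 0.1), c(10, 10))
  cl <- cluster_rows(m)
  # the first merge joins rows 1 and 2 (distance 0.1)
  expect_setequal(cl$merge[1, ], c(-1L, -2L))
  expect_equal(cl$height[1], 0.1)

  # identical rows: all merge heights zero
  ident <- cluster_rows(matrix(1, 4, 3))
  expect_true(all(ident$height == 0))

  # single row: identity ordering, empty schedule
  single <- cluster_rows(matrix(1:3, 1))
  expect_equal(single$order, 1L)
  expect_equal(nrow(single$merge), 0L)

  # agrees with stats::hclust directly (complete linkage)
  set.seed(14)
  mm <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(cluster_rows(mm)$order,
               stats::hclust(stats::dist(mm), "complete")$order)
})
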