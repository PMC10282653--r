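test_that("chao1 matches hand-computed values and vegan", {
  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2, 2, 5)), 5 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(0, 0, 0)), 0)
  # finite when no doubletons are present
  expect_equal(chao1(c(1, 1, 1, 4)), 4 + 3 * 2 / 2)
  # estimator never falls below observed richness; equality iff F1 <= 1
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- rpois(30, 2)
      est <- chao1(x)
      expect_gte(est, sum(x > 0))
      if (sum(x == 1) <= 1) expect_equal(est, sum(x > 0))
      # vegan's S.chao1 uses the same bias-corrected form
      expect_equal(est, unname(vegan::estimateR(x)["S.chao1"]))
    }
  })
})

test_that("shannon and simpson match closed forms and vegan", {
  expect_equal(shannon(rep(0.25, 4)), log(4))
  expect_equal(shannon(1.0), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)))
  expect_equal(shannon(rep(0.25, 4), base = 2), 2)
  expect_equal(simpson(1.0), 0)
  expect_equal(simpson(rep(1 / 7, 7)), 1 - 1 / 7)
  expect_equal(simpson(c(0.5, 0.5)), 0.5)
  withr::with_seed(17, {
    for (i in 1:10) {
      p <- runif(12)
      p <- p / sum(p)
      expect_equal(shannon(p), unname(vegan::diversity(p, "shannon")))
      expect_equal(simpson(p), unname(vegan::diversity(p, "simpson")))
      # uniform maximizes shannon
      expect_lte(shannon(p), log(12) + 1e-12)
    }
  })
})

test_that("alpha-diversity group comparison is an exact rank test", {
  # identical multisets -> p = 1
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("A", "B"), each = 3)
  expect_equal(compare_alpha(v, g), 1)
  # fully separated 3 vs 3 -> exact p = 2 / choose(6, 3) = 0.1
  expect_equal(compare_alpha(c(1, 2, 3, 10, 11, 12), g), 0.1)
  # invariance under strictly monotone transforms
  x <- c(0.3, 1.2, 0.8, 2.5, 1.9, 0.6)
  expect_equal(compare_alpha(x, g), compare_alpha(exp(x), g))
  expect_error(compare_alpha(1:3, c("A", "A", "A")), "two")
})

test_that("beta distances match their formulas", {
  m <- rbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0, 0.5))
  colnames(m) <- paste0("t", 1:3)
  expect_equal(as.numeric(beta_distance(m, "bray_curtis")), 0.5)
  expect_equal(as.numeric(beta_distance(m, "binary_jaccard")), 1 - 1 / 3,
               tolerance = 1e-12)
  expect_equal(as.numeric(beta_distance(m, "euclidean")),
               sqrt(0.25 + 0.25))
  # identical samples -> 0; disjoint supports -> 1 for BC and Jaccard
  m2 <- rbind(a = c(0.4, 0.6, 0, 0), b = c(0.4, 0.6, 0, 0),
              c = c(0, 0, 0.7, 0.3))
  colnames(m2) <- paste0("t", 1:4)
  d <- as.matrix(beta_distance(m2, "bray_curtis"))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  dj <- as.matrix(beta_distance(m2, "binary_jaccard"))
  expect_equal(dj["a", "b"], 0)
  expect_equal(dj["a", "c"], 1)
  expect_error(beta_distance(m, "mahalanobis"))
})

test_that("beta distances agree with direct Bray-Curtis computation", {
  withr::with_seed(23, {
    m <- matrix(rlnorm(5 * 8), 5, 8,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
    m <- m / rowSums(m)
    d <- as.matrix(beta_distance(m, "bray_curtis"))
    for (i in 1:4) for (j in (i + 1):5) {
      bc <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
      expect_equal(d[i, j], bc)
      expect_equal(d[j, i], bc)      # symmetry
    }
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
  })
})

test_that("pcoa reproduces Euclidean configurations and ranks", {
  withr::with_seed(29, {
    pts <- matrix(rnorm(12), 6, 2)
    rownames(pts) <- paste0("s", 1:6)
    d <- dist(pts)
    res <- pcoa(d, k = 2)
    expect_equal(as.matrix(dist(res$points)), as.matrix(d),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(res$eig) <= 1e-9))  # non-increasing
    # collinear points embed in exactly one dimension
    line <- cbind(c(0, 1, 2), c(0, 0, 0))
    res1 <- pcoa(dist(line), k = 2)
    expect_equal(sum(res1$eig > 1e-10), 1L)
  })
})

test_that("permanova separates clusters and matches vegan's pseudo-F", {
  withr::with_seed(37, {
    pts <- rbind(matrix(rnorm(16, 0, 0.1), 8), matrix(rnorm(16, 5, 0.1), 8))
    rownames(pts) <- paste0("s", 1:16)
    d <- dist(pts)
    g <- rep(c("A", "B"), each = 8)
    res <- permanova(d, g, n_perm = 199, seed = 1)
    expect_equal(res$p, 1 / 200)  # attainable minimum
    ad <- vegan::adonis2(d ~ g, permutations = 99)
    expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
    # invariance to group-label renaming and sample order
    res2 <- permanova(d, c(A = "grp2", B = "grp1")[g], n_perm = 199, seed = 1)
    expect_equal(res2$pseudo_F, res$pseudo_F)
    expect_equal(res2$p, res$p)
    perm <- sample(16)
    res3 <- permanova(as.dist(as.matrix(d)[perm, perm]), g[perm],
                      n_perm = 199, seed = 1)
    expect_equal(res3$pseudo_F, res$pseudo_F)
  })
})

test_that("permanova on a zero-variation distance matrix is defined", {
  # identical presence/absence under a binary metric gives an all-zero
  # distance matrix; there is nothing to partition
  m <- matrix(c(0.4, 0.6, 0.5, 0.5, 0.3, 0.7, 0.2, 0.8), 4, 2,
              dimnames = list(paste0("s", 1:4), c("t1", "t2")))
  d <- beta_distance(m, "binary_jaccard")
  res <- permanova(d, rep(c("A", "B"), each = 2), n_perm = 99, seed = 1)
  expect_true(is.na(res$pseudo_F))
  expect_equal(res$p, 1)
})

test_that("permanova Monte-Carlo p matches full enumeration for small n", {
  withr::with_seed(43, {
    pts <- matrix(rnorm(12), 6, 2)
    rownames(pts) <- paste0("s", 1:6)
    d <- dist(pts)
    g <- rep(c("A", "B"), each = 3)
    f_obs <- pseudo_f_direct(d, g)
    fs <- vapply(all_perms(1:6), function(ix) pseudo_f_direct(
      as.dist(as.matrix(d)[ix, ix]), g), numeric(1))
    p_exact <- mean(fs >= f_obs - 1e-12)
    n_perm <- 999
    res <- permanova(d, g, n_perm = n_perm, seed = 7)
    se <- sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(res$p - p_exact), 3 * se + 2 / n_perm)
  })
})

test_that("alpha_diversity computes per-sample metrics with groups", {
  withr::with_seed(47, {
    tab <- null_table(4, 3, 10)
    a <- alpha_diversity(tab)
    expect_equal(nrow(a), 7L)
    expect_equal(a$chao1[1], chao1(tab$counts[1, ]))
    expect_equal(a$shannon[2], shannon(tab$values[2, ]))
    expect_equal(unique(a$group), c("MIBC", "NMIBC"))
  })
})
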