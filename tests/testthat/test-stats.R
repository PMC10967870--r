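# independent brute-force oracle for the paired cluster permutation test:
# enumerate every sign assignment, scan runs of supra-threshold t values
brute_force_paired_clusters <- function(A, B, cluster_alpha = 0.05) {
  D <- A - B
  n <- nrow(D)
  thr <- qt(1 - cluster_alpha / 2, n - 1)
  tvec <- function(d) colMeans(d) / (apply(d, 2, sd) / sqrt(n))
  runs <- function(t) {
    out <- list()
    cur <- NULL
    for (j in seq_along(t)) {
      s <- if (t[j] > thr) 1 else if (t[j] < -thr) -1 else 0
      if (s != 0 && !is.null(cur) && cur$sign == s) {
        cur$members <- c(cur$members, j)
      } else {
        if (!is.null(cur)) out[[length(out) + 1]] <- cur
        cur <- if (s != 0) list(sign = s, members = j) else NULL
      }
    }
    if (!is.null(cur)) out[[length(out) + 1]] <- cur
    out
  }
  obs <- runs(tvec(D))
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- apply(signs, 1, function(s) {
    cl <- runs(tvec(D * s))
    if (length(cl) == 0) 0
    else max(abs(vapply(cl, function(c) sum(tvec(D * s)[c$members]), numeric(1))))
  })
  lapply(obs, function(c) {
    mass <- sum(tvec(D)[c$members])
    list(members = c$members, mass = mass,
         p = mean(null_max >= abs(mass) - 1e-12))
  })
}

test_that("paired cluster p values match exhaustive sign-flip enumeration", {
  set.seed(60)
  for (rep in 1:3) {
    A <- matrix(rnorm(4 * 6), 4, 6) + matrix(rep(c(0, 0, 2, 2, 0, 0), each = 4), 4, 6)
    B <- matrix(rnorm(4 * 6), 4, 6)
    oracle <- brute_force_paired_clusters(A, B)
    got <- cluster_permutation(A, B, dimension = "time", paired = TRUE,
                               n_perm = 2000)
    expect_true(got$exact)
    expect_equal(length(got$clusters), length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(got$clusters[[k]]$members, oracle[[k]]$members)
      expect_equal(got$clusters[[k]]$mass, oracle[[k]]$mass, tolerance = 1e-12)
      expect_equal(got$clusters[[k]]$p, oracle[[k]]$p, tolerance = 1e-12)
    }
  }
})

test_that("identical conditions yield no clusters", {
  set.seed(61)
  A <- matrix(rnorm(30), 5, 6)
  res <- cluster_permutation(A, A, dimension = "time", paired = TRUE,
                             n_perm = 100)
  expect_equal(length(res$clusters), 0L)
})

test_that("cluster inference is seed-reproducible and affine-invariant", {
  set.seed(62)
  A <- matrix(rnorm(8 * 20), 8, 20); A[, 8:12] <- A[, 8:12] + 2
  B <- matrix(rnorm(8 * 20), 8, 20)
  r1 <- cluster_permutation(A, B, "time", n_perm = 300, seed = 7)
  r2 <- cluster_permutation(A, B, "time", n_perm = 300, seed = 7)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p"),
                   vapply(r2$clusters, `[[`, numeric(1), "p"))

  r3 <- cluster_permutation(3.2 * A - 5, 3.2 * B - 5, "time",
                            n_perm = 300, seed = 7)
  expect_equal(vapply(r1$clusters, `[[`, numeric(1), "mass"),
               vapply(r3$clusters, `[[`, numeric(1), "mass"),
               tolerance = 1e-9)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p"),
                   vapply(r3$clusters, `[[`, numeric(1), "p"))
})

test_that("the neighbor graph is symmetric, self-free, and covers the montage", {
  g <- neighbor_graph()
  expect_setequal(names(g), montage_1010()$label)
  for (ch in names(g)) {
    expect_false(ch %in% g[[ch]])
    for (nb in g[[ch]]) expect_true(ch %in% g[[nb]])
  }
  expect_false("C4" %in% g[["C3"]])            # C3-C4 are two steps apart
  expect_true("C1" %in% g[["C3"]])
  expect_true("Cz" %in% g[["C1"]])
})

test_that("topographic comparison flags injected group differences only", {
  mont <- montage_1010()
  mont <- mont[mont$label %in% small_channels(), ]
  g <- neighbor_graph(mont)
  set.seed(63)
  chans <- mont$label
  base <- matrix(rnorm(8 * length(chans), sd = 0.5), 8,
                 dimnames = list(NULL, chans))
  res0 <- topo_compare(base[1:4, ], base[5:8, ], g, n_perm = 300, seed = 1)
  sig0 <- Filter(function(c) c$p <= 0.05, res0$clusters)
  expect_equal(length(sig0), 0L)

  shifted <- base
  target <- intersect(sensorimotor_channels("left"), chans)
  shifted[5:8, target] <- shifted[5:8, target] + 3
  res1 <- topo_compare(shifted[1:4, ], shifted[5:8, ], g, n_perm = 500,
                       seed = 2)
  sig <- Filter(function(c) c$p <= 0.05, res1$clusters)
  expect_gte(length(sig), 1L)
  hit <- unique(unlist(lapply(sig, `[[`, "channels")))
  expect_gte(length(intersect(hit, target)), 1L)
})

test_that("a lone channel with a large offset forms its own cluster", {
  g <- structure(list(Cz = character(0)), class = "neighbor_graph")
  A <- matrix(rnorm(6, mean = 5, sd = 0.3), 6, 1, dimnames = list(NULL, "Cz"))
  B <- matrix(rnorm(6, mean = 0, sd = 0.3), 6, 1, dimnames = list(NULL, "Cz"))
  res <- topo_compare(A, B, g, n_perm = 500, seed = 3)
  expect_equal(length(res$clusters), 1L)
  expect_equal(res$clusters[[1]]$channels, "Cz")
})

test_that("the two-sample t statistic matches the closed-form hand computation", {
  x <- c(4.1, 5.0, 6.3); y <- c(7.2, 8.4, 9.9)
  got <- t.test(x, y, var.equal = TRUE)
  sp2 <- ((3 - 1) * var(x) + (3 - 1) * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(unname(got$statistic), t_hand, tolerance = 1e-12)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sqrt(sp2),
               tolerance = 1e-12)
})

test_that("mixed and repeated-measures ANOVA are calibrated under the null", {
  set.seed(64)
  n_sim <- 200
  p_mixed <- numeric(n_sim); p_rm <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    df <- expand.grid(subject_id = paste0("s", 1:6), scheme = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
    df$group <- ifelse(df$subject_id %in% paste0("s", 1:3), "g1", "g2")
    df$value <- rnorm(nrow(df))
    p_mixed[s] <- mixed_anova(df, "value", "group", "scheme",
                              "subject_id")$p[1]
    p_rm[s] <- rm_anova(df, "value", "scheme", "subject_id")$p
  }
  expect_gt(ks.test(p_mixed, "punif")$p.value, 0.01)
  expect_gt(ks.test(p_rm, "punif")$p.value, 0.01)
})

test_that("repeated-measures ANOVA reports missing cells on unbalanced input", {
  df <- expand.grid(subject_id = paste0("s", 1:4), scheme = c("A", "B"),
                    stringsAsFactors = FALSE)
  df$value <- rnorm(8)
  df <- df[-3, ]
  expect_error(rm_anova(df, "value", "scheme", "subject_id"), "missing cell")
})

test_that("the parametric battery returns the planned comparisons with effect sizes", {
  set.seed(65)
  schemes <- c("FVS-1", "FVS-2", "NMES-1")
  df <- expand.grid(subject_id = sprintf("c%02d", 1:6), scheme = schemes,
                    stringsAsFactors = FALSE)
  df$group <- ifelse(df$subject_id <= "c03", "stroke", "control")
  df$value <- rnorm(nrow(df)) + ifelse(df$scheme == "FVS-1", 2, 0)
  out <- parametric_battery(df, dv = "value")
  expect_true(all(c("mixed_anova", "rm_anova", "posthoc", "ttests") %in%
                    names(out)))
  expect_equal(nrow(out$posthoc) / length(unique(df$group)), choose(3, 2))
  expect_equal(out$posthoc$p_bonferroni,
               pmin(1, out$posthoc$p * choose(3, 2)))
  expect_true(all(is.finite(out$mixed_anova$partial_eta2)))
  expect_true(any(grepl("FVS vs NMES", out$ttests$comparison)))
  expect_true(any(grepl("independent", out$ttests$comparison)))
})

test_that("Mann-Whitney p matches exact rank enumeration on separated samples", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- nonparametric_compare(x, y, alternative = "less")
  # oracle: all C(6,3) = 20 assignments of ranks; only one gives U = 0
  combos <- combn(6, 3)
  u_all <- apply(combos, 2, function(ix) {
    xs <- (1:6)[ix]; ys <- setdiff(1:6, xs)
    sum(outer(xs, ys, ">"))
  })
  expect_equal(got$p, mean(u_all <= 0))
  expect_equal(got$p, 0.05)
  expect_equal(got$statistic, 0)

  # rank-biserial antisymmetry
  a <- c(1, 4, 6, 8); b <- c(2, 3, 7, 9)
  expect_equal(nonparametric_compare(a, b)$effect_size,
               -nonparametric_compare(b, a)$effect_size)

  expect_warning(res <- nonparametric_compare(c(1, 2, 3), c(1, 2, 3),
                                              paired = TRUE), "zero")
  expect_equal(res$p, 1)
})

test_that("the normality screen is calibrated and detects non-normal shapes", {
  set.seed(66)
  rej <- mean(replicate(200, !normality_check(rnorm(50))$normal))
  ci <- qbinom(c(0.025, 0.975), 200, 0.05) / 200
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2] + 0.01)

  rej_unif <- mean(replicate(50, !normality_check(runif(200))$normal))
  expect_gt(rej_unif, 0.8)

  expect_warning(res <- normality_check(rep(2, 10)), "constant")
  expect_false(res$normal)
  expect_equal(res$p, 0)
  expect_error(normality_check(c(1, 2, 3)), "at least 4")
})
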