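# Cluster-based permutation testing over time, channel, or
# time-frequency space, plus the parametric / nonparametric batteries.

tstat_bins <- function(A, B, paired) {
  if (paired) {
    d <- A - B
    n <- nrow(d)
    m <- colMeans(d)
    s <- apply(d, 2, stats::sd)
    list(t = m / (s / sqrt(n)), df = n - 1)
  } else {
    na <- nrow(A); nb <- nrow(B)
    va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    t <- (colMeans(A) - colMeans(B)) / (sp * sqrt(1 / na + 1 / nb))
    list(t = t, df = na + nb - 2)
  }
}

# connected components among `bins` (integer indices) under an adjacency
# closure `adj_fn(i) -> integer neighbors`
connected_components <- function(bins, adj_fn) {
  remaining <- bins
  comps <- list()
  inset <- logical(max(c(bins, 1L)))
  inset[bins] <- TRUE
  visited <- logical(length(inset))
  for (b in bins) {
    if (visited[b]) next
    queue <- b; visited[b] <- TRUE; comp <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in adj_fn(cur)) {
        if (nb >= 1 && nb <= length(inset) && inset[nb] && !visited[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

make_adjacency <- function(dimension, nbins, labels = NULL,
                           adjacency = NULL, tf_dim = NULL) {
  switch(dimension,
    time = function(i) c(i - 1L, i + 1L),
    channel = {
      if (is.null(adjacency)) stop("channel dimension needs a neighbor graph")
      idx <- stats::setNames(seq_along(labels), labels)
      nb_idx <- lapply(labels, function(l) unname(idx[adjacency[[l]]]))
      function(i) nb_idx[[i]]
    },
    "time-frequency" = {
      nf <- tf_dim[1]
      function(i) {
        f <- (i - 1L) %% nf + 1L
        out <- c(i - nf, i + nf)                 # time neighbors
        if (f > 1L) out <- c(out, i - 1L)        # frequency neighbors
        if (f < nf) out <- c(out, i + 1L)
        out
      }
    },
    stop("unknown cluster dimension: ", dimension))
}

cluster_stats <- function(t, threshold, adj_fn) {
  supra_pos <- which(t > threshold)
  supra_neg <- which(t < -threshold)
  comps <- c(connected_components(supra_pos, adj_fn),
             connected_components(supra_neg, adj_fn))
  lapply(comps, function(m) list(members = m, mass = sum(t[m])))
}

#' Cluster-based permutation test
#'
#' Per-bin t statistics (paired or independent) are thresholded at the
#' two-sided critical t for `cluster_alpha`; supra-threshold bins of
#' equal sign are clustered under the declared adjacency (consecutive
#' bins over time, a [neighbor_graph()] over channels, 4-connectivity
#' over a time-frequency grid) and each cluster's mass (sum of t) is
#' referred to the permutation distribution of the maximum absolute
#' cluster mass (random sign flips for paired data, label shuffles for
#' independent groups). Monte-Carlo p = (b + 1) / (n_perm + 1); for
#' paired designs with at most `log2(n_perm)` subjects the full set of
#' sign assignments is enumerated instead and p is the exact proportion.
#'
#' @param A,B observations x bins matrices (paired designs need equal row
#'   counts). For the time-frequency dimension pass freq x time maps
#'   flattened column-wise and give `tf_dim = c(nf, nt)`.
#' @param dimension `"time"`, `"channel"`, or `"time-frequency"`.
#' @param paired Paired design?
#' @param n_perm Number of permutations.
#' @param cluster_alpha Cluster-forming (per-bin) alpha.
#' @param alpha Cluster-level significance level.
#' @param adjacency A [neighbor_graph()] (channel dimension only); bin
#'   order must match the graph's label order given in `labels`.
#' @param labels Channel labels of the bins (channel dimension only).
#' @param tf_dim `c(n_freq, n_time)` (time-frequency dimension only).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return A `cluster_test_result`: `clusters` (list of `members`,
#'   `mass`, `p`), `stat`, `threshold`, `n_perm`, `exact`, `alpha`.
#' @export
cluster_permutation <- function(A, B, dimension = c("time", "channel",
                                                    "time-frequency"),
                                paired = FALSE, n_perm = 2000,
                                cluster_alpha = 0.05, alpha = 0.05,
                                adjacency = NULL, labels = NULL,
                                tf_dim = NULL, seed = NULL) {
  dimension <- match.arg(dimension)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must share the bin dimension")
  if (paired && nrow(A) != nrow(B))
    stop("paired test requires equal observation counts")
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("need at least 2 observations per condition")
  if (dimension == "channel" && is.null(labels)) labels <- colnames(A)
  if (!is.null(seed)) set.seed(seed)

  adj_fn <- make_adjacency(dimension, ncol(A), labels, adjacency, tf_dim)
  obs <- tstat_bins(A, B, paired)
  threshold <- stats::qt(1 - cluster_alpha / 2, obs$df)
  clusters <- cluster_stats(obs$t, threshold, adj_fn)

  if (length(clusters) == 0L) {
    return(structure(list(clusters = list(), stat = obs$t,
                          threshold = threshold, n_perm = n_perm,
                          exact = FALSE, alpha = alpha,
                          dimension = dimension, null_max = numeric(0)),
                     class = "cluster_test_result"))
  }

  max_mass <- function(t) {
    cl <- cluster_stats(t, threshold, adj_fn)
    if (length(cl) == 0L) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }

  exact <- FALSE
  if (paired) {
    n <- nrow(A)
    D <- A - B
    if (2^n <= n_perm) {                     # exhaustive sign enumeration
      exact <- TRUE
      signs_all <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      null_max <- apply(signs_all, 1, function(s) {
        d <- D * s
        m <- colMeans(d); sd <- apply(d, 2, stats::sd)
        max_mass(m / (sd / sqrt(n)))
      })
    } else {
      null_max <- vapply(seq_len(n_perm), function(i) {
        s <- sample(c(1, -1), n, replace = TRUE)
        d <- D * s
        m <- colMeans(d); sd <- apply(d, 2, stats::sd)
        max_mass(m / (sd / sqrt(n)))
      }, numeric(1))
    }
  } else {
    X <- rbind(A, B)
    na <- nrow(A)
    null_max <- vapply(seq_len(n_perm), function(i) {
      idx <- sample(nrow(X))
      max_mass(tstat_bins(X[idx[seq_len(na)], , drop = FALSE],
                          X[idx[-seq_len(na)], , drop = FALSE],
                          paired = FALSE)$t)
    }, numeric(1))
  }

  for (k in seq_along(clusters)) {
    m <- abs(clusters[[k]]$mass)
    clusters[[k]]$p <- if (exact) {
      mean(null_max >= m - 1e-12)
    } else {
      (sum(null_max >= m - 1e-12) + 1) / (n_perm + 1)
    }
    if (dimension == "channel")
      clusters[[k]]$channels <- labels[clusters[[k]]$members]
  }
  structure(list(clusters = clusters, stat = obs$t, threshold = threshold,
                 n_perm = if (exact) length(null_max) else n_perm,
                 exact = exact, alpha = alpha, dimension = dimension,
                 null_max = null_max),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %s, %d cluster(s), %s%d permutations\n",
              x$dimension, length(x$clusters),
              if (x$exact) "exhaustive " else "", x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  bins %d-%d mass %.2f p %.4f\n", min(cl$members),
                max(cl$members), cl$mass, cl$p))
  invisible(x)
}

significant_clusters <- function(res) {
  Filter(function(cl) cl$p <= res$alpha, res$clusters)
}

#' Compare ERD/ERS topographies between two groups
#'
#' Independent-samples [cluster_permutation()] over the channel dimension.
#'
#' @param topo_a,topo_b subjects x channels matrices of per-channel
#'   ERD/ERS values with channel labels as column names.
#' @param adjacency A [neighbor_graph()] covering those channels.
#' @param n_perm,alpha,cluster_alpha,seed See [cluster_permutation()].
#' @return A `cluster_test_result` over channels.
#' @export
topo_compare <- function(topo_a, topo_b, adjacency, n_perm = 2000,
                         alpha = 0.05, cluster_alpha = 0.05, seed = NULL) {
  if (!identical(colnames(topo_a), colnames(topo_b)))
    stop("topography montages do not match")
  cluster_permutation(topo_a, topo_b, dimension = "channel",
                      paired = FALSE, n_perm = n_perm, alpha = alpha,
                      cluster_alpha = cluster_alpha, adjacency = adjacency,
                      labels = colnames(topo_a), seed = seed)
}

#' Normality screen routing features to the test batteries
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test of composite normality
#' (the correction SPSS reports alongside Shapiro-Wilk) for n >= 5;
#' Shapiro-Wilk for n = 4. A constant sample is declared non-normal with
#' p = 0 and a warning.
#'
#' @param sample Numeric vector, length at least 4.
#' @param alpha Decision level.
#' @return List with `normal` (logical) and `p`.
#' @export
normality_check <- function(sample, alpha = 0.05) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 4L) stop("normality check needs at least 4 values")
  if (stats::sd(sample) == 0) {
    warning("constant sample: declared non-normal with p = 0")
    return(list(normal = FALSE, p = 0))
  }
  p <- if (length(sample) >= 5L) nortest::lillie.test(sample)$p.value
       else stats::shapiro.test(sample)$p.value
  list(normal = p > alpha, p = p)
}

#' Cohen's d
#'
#' Paired: mean difference over the SD of differences. Independent: mean
#' difference over the pooled SD.
#'
#' @param x,y Numeric samples.
#' @param paired Paired design?
#' @return A single number.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    mean(d) / stats::sd(d)
  } else {
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                 (nx + ny - 2))
    (mean(x) - mean(y)) / sp
  }
}

# rank-biserial effect sizes
rank_biserial_mw <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  2 * U / (length(x) * length(y)) - 1
}
rank_biserial_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) return(0)
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

# Greenhouse-Geisser epsilon from the subjects x levels response matrix
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- stats::cov(Y)
  M <- sweep(S, 1, rowMeans(S))
  M <- sweep(M, 2, colMeans(S))
  M <- M + mean(S)
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classic univariate RM-ANOVA on a complete subjects x levels layout.
#' When the Greenhouse-Geisser epsilon falls below `gg_cutoff` the
#' degrees of freedom are multiplied by epsilon before computing p.
#'
#' @param df Long data.frame.
#' @param dv,within,subject Column names.
#' @param gg_cutoff Epsilon below which the correction is applied.
#' @return One-row data.frame: F, df1, df2, p, epsilon, partial eta^2.
#' @export
rm_anova <- function(df, dv, within, subject, gg_cutoff = 0.75) {
  Y <- stats::xtabs(stats::reformulate(c(subject, within), dv), data = df)
  counts <- stats::xtabs(stats::reformulate(c(subject, within)), data = df)
  if (any(counts != 1)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    stop("unbalanced repeated-measures layout; missing cell(s): ",
         paste(apply(miss, 1, function(r)
           paste(rownames(counts)[r[1]], colnames(counts)[r[2]], sep = ":")),
           collapse = ", "))
  }
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_within_lvls <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_within_lvls - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_within_lvls / df1) / (ss_err / df2)
  eps <- gg_epsilon(Y)
  use_gg <- eps < gg_cutoff
  p <- if (use_gg) stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
       else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  data.frame(effect = within, F = Fv, df1 = df1, df2 = df2,
             epsilon = eps, gg_applied = use_gg, p = p,
             partial_eta2 = ss_within_lvls / (ss_within_lvls + ss_err))
}

#' Two-way mixed ANOVA (one between-, one within-subject factor)
#'
#' Univariate mixed-design ANOVA on a complete layout: between-group
#' effect tested against the subject stratum, within-subject and
#' interaction effects against the subject-by-within stratum. Reports
#' partial eta^2 per effect.
#'
#' @param df Long data.frame.
#' @param dv,between,within,subject Column names.
#' @return data.frame with one row per effect.
#' @export
mixed_anova <- function(df, dv, between, within, subject) {
  df[[between]] <- factor(df[[between]])
  df[[within]] <- factor(df[[within]])
  df[[subject]] <- factor(df[[subject]])
  form <- stats::as.formula(paste(
    dv, "~", between, "*", within, "+ Error(", subject, "/", within, ")"))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)
  out <- list()
  for (stratum in sm) {
    tb <- stratum[[1]]
    terms <- trimws(rownames(tb))
    res_i <- which(terms == "Residuals")
    ss_err <- tb[res_i, "Sum Sq"]
    for (i in setdiff(seq_len(nrow(tb)), res_i)) {
      out[[length(out) + 1L]] <- data.frame(
        effect = terms[i], F = tb[i, "F value"],
        df1 = tb[i, "Df"], df2 = tb[res_i, "Df"],
        p = tb[i, "Pr(>F)"],
        partial_eta2 = tb[i, "Sum Sq"] / (tb[i, "Sum Sq"] + ss_err))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parametric battery for a feature's reading units
#'
#' Runs, on one feature column: a two-way mixed ANOVA (between: group;
#' within: scheme), a one-way repeated-measures ANOVA across schemes per
#' group with Bonferroni-adjusted pairwise paired t-tests, a paired
#' t-test of FVS vs NMES (within-subject means by stimulation type), and
#' an independent t-test of stroke vs control (subject means). Effect
#' sizes are partial eta^2 (ANOVA) and Cohen's d (t-tests).
#'
#' @param features Long data.frame with columns `subject_id`, `group`,
#'   `scheme`, and the feature value.
#' @param dv Feature column name.
#' @return Named list of result tables: `mixed_anova`, `rm_anova`,
#'   `posthoc`, `ttests`.
#' @export
parametric_battery <- function(features, dv = "value") {
  stopifnot(all(c("subject_id", "group", "scheme", dv) %in% names(features)))
  # reading units: one value per subject x scheme
  ru <- stats::aggregate(features[[dv]],
                         by = list(subject_id = features$subject_id,
                                   group = features$group,
                                   scheme = features$scheme),
                         FUN = mean)
  names(ru)[4] <- "value"

  mixed <- mixed_anova(ru, "value", "group", "scheme", "subject_id")

  rm_tabs <- list(); posthoc <- list()
  for (g in unique(ru$group)) {
    sub <- ru[ru$group == g, ]
    tab <- rm_anova(sub, "value", "scheme", "subject_id")
    tab$group <- g
    rm_tabs[[g]] <- tab
    schemes <- sort(unique(sub$scheme))
    prs <- utils::combn(schemes, 2)
    ph <- data.frame(group = g, a = prs[1, ], b = prs[2, ],
                     t = NA_real_, p = NA_real_, d = NA_real_)
    wide <- stats::xtabs(value ~ subject_id + scheme, data = sub)
    for (j in seq_len(ncol(prs))) {
      x <- wide[, prs[1, j]]; y <- wide[, prs[2, j]]
      tt <- stats::t.test(x, y, paired = TRUE)
      ph$t[j] <- unname(tt$statistic); ph$p[j] <- tt$p.value
      ph$d[j] <- cohens_d(x, y, paired = TRUE)
    }
    ph$p_bonferroni <- pmin(1, ph$p * nrow(ph))
    posthoc[[g]] <- ph
  }

  ttests <- list()
  ru$stim_type <- ifelse(grepl("^FVS", ru$scheme), "FVS", "NMES")
  for (g in unique(ru$group)) {
    sub <- ru[ru$group == g, ]
    bytype <- stats::aggregate(value ~ subject_id + stim_type, sub, mean)
    wide <- stats::xtabs(value ~ subject_id + stim_type, data = bytype)
    if (all(c("FVS", "NMES") %in% colnames(wide))) {
      tt <- stats::t.test(wide[, "FVS"], wide[, "NMES"], paired = TRUE)
      ttests[[length(ttests) + 1L]] <- data.frame(
        comparison = paste0(g, ": FVS vs NMES (paired)"),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
        effect_size = cohens_d(wide[, "FVS"], wide[, "NMES"], paired = TRUE),
        n = nrow(wide))
    }
  }
  groups <- unique(ru$group)
  if (length(groups) == 2L) {
    bysub <- stats::aggregate(value ~ subject_id + group, ru, mean)
    x <- bysub$value[bysub$group == groups[1]]
    y <- bysub$value[bysub$group == groups[2]]
    if (length(x) >= 2 && length(y) >= 2) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      ttests[[length(ttests) + 1L]] <- data.frame(
        comparison = paste0(groups[1], " vs ", groups[2], " (independent)"),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
        effect_size = cohens_d(x, y), n = length(x) + length(y))
    }
  }
  list(mixed_anova = mixed,
       rm_anova = do.call(rbind, rm_tabs),
       posthoc = do.call(rbind, posthoc),
       ttests = do.call(rbind, ttests))
}

#' Nonparametric battery
#'
#' Mann-Whitney U for independent samples and Wilcoxon signed-rank for
#' paired samples, exact p where the sample permits, with rank-biserial
#' effect sizes (sign flips when the samples are swapped).
#'
#' @param x,y Numeric samples (>= 3 observations each).
#' @param paired Paired design?
#' @param alternative Passed to [stats::wilcox.test()].
#' @return One-row data.frame: statistic, p, effect size, n.
#' @export
nonparametric_compare <- function(x, y, paired = FALSE,
                                  alternative = "two.sided") {
  if (length(x) < 3L || length(y) < 3L)
    stop("need at least 3 observations per sample")
  if (paired && all(x - y == 0)) {
    warning("all paired differences are zero; p = 1")
    return(data.frame(test = "wilcoxon-signed-rank", statistic = 0,
                      p = 1, effect_size = 0, n = length(x)))
  }
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; p = 1")
    return(data.frame(test = if (paired) "wilcoxon-signed-rank"
                             else "mann-whitney-u",
                      statistic = NA_real_, p = 1, effect_size = 0,
                      n = length(x) + length(y)))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            alternative = alternative))
  es <- if (paired) rank_biserial_wilcoxon(x, y) else rank_biserial_mw(x, y)
  data.frame(test = if (paired) "wilcoxon-signed-rank" else "mann-whitney-u",
             statistic = unname(wt$statistic), p = wt$p.value,
             effect_size = es,
             n = if (paired) length(x) else length(x) + length(y))
}
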