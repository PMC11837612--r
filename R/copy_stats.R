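#' Orthogroup-by-species copy-number matrix
#'
#' @param table an [orthogroup_table()].
#' @param focal_species species to keep as columns (must be in the
#'   roster); absent species contribute zero cells.
#' @param orthogroups optional orthogroup subset (default: all rows).
#' @return integer matrix, orthogroups x focal species.
#' @export
copy_matrix <- function(table, focal_species, orthogroups = NULL) {
  bad <- setdiff(focal_species, table$species)
  if (length(bad) > 0L)
    stop("unknown focal species: ", paste(bad, collapse = ", "))
  if (is.null(orthogroups)) orthogroups <- table$orthogroups
  bad_og <- setdiff(orthogroups, table$orthogroups)
  if (length(bad_og) > 0L)
    stop("unknown orthogroup(s): ", paste(bad_og, collapse = ", "))
  table$counts[orthogroups, focal_species, drop = FALSE]
}

#' Retention fraction per orthogroup
#'
#' The fraction of focal species in which a family keeps at least one
#' copy; a family is called retained when the fraction reaches the
#' threshold (default 0.75, i.e. present in 75% or more of the focal
#' species).
#'
#' @param matrix a [copy_matrix()].
#' @param threshold retention threshold in (0, 1].
#' @return data.frame `orthogroup`, `n_present`, `n_species`, `fraction`,
#'   `retained`.
#' @export
retention <- function(matrix, threshold = 0.75) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  n_present <- rowSums(matrix >= 1L)
  frac <- n_present / ncol(matrix)
  data.frame(orthogroup = rownames(matrix),
             n_present = as.integer(n_present),
             n_species = ncol(matrix),
             fraction = unname(frac),
             retained = unname(frac >= threshold),
             stringsAsFactors = FALSE)
}

#' Anderson-Darling normality check on pooled copy counts
#'
#' Copy-number data are counts with a point mass at small values and a
#' right tail from expanded families, so parametric group comparisons are
#' inappropriate; this check formalises that with the Anderson-Darling
#' composite test (mean and variance estimated from the data,
#' [nortest::ad.test()]) on the pooled cells of the focal matrix.
#'
#' @param matrix a [copy_matrix()] (or a numeric vector of observations).
#' @param alpha significance level for the verdict (default 0.05).
#' @return list `statistic` (A squared), `p_value`, `reject_normality`,
#'   `skewness`, `n`.
#' @export
normality_check <- function(matrix, alpha = 0.05) {
  x <- as.numeric(matrix)
  if (length(x) < 8L)
    stop("need at least 8 observations for a stable Anderson-Darling test")
  if (stats::sd(x) == 0)
    stop("constant observations: normality is undefined for zero variance")
  ad <- nortest::ad.test(x)
  m <- mean(x); s <- stats::sd(x)
  skew <- mean((x - m)^3) / s^3
  list(statistic = unname(ad$statistic), p_value = ad$p.value,
       reject_normality = ad$p.value < alpha, skewness = skew,
       n = length(x))
}

#' Kruskal-Wallis rank test across orthogroups
#'
#' Groups are orthogroups; observations are the per-species copy counts,
#' zeros (absent species) included, so the grand mean is the mean number
#' of gene copies per orthogroup per species.  Uses the tie-corrected H
#' statistic with a chi-square reference ([stats::kruskal.test()]).
#'
#' @param matrix a [copy_matrix()].
#' @param include_zeros include zero cells as observations (default
#'   `TRUE`).
#' @return list `H`, `df`, `p_value`, `grand_mean`, `n_groups`.
#' @export
kruskal_wallis <- function(matrix, include_zeros = TRUE) {
  if (nrow(matrix) < 2L) stop("need at least 2 orthogroups (groups)")
  x <- as.numeric(t(matrix))
  g <- factor(rep(rownames(matrix), each = ncol(matrix)),
              levels = rownames(matrix))
  if (!include_zeros) {
    keep <- x > 0
    x <- x[keep]; g <- droplevels(g[keep])
    if (nlevels(g) < 2L) stop("fewer than 2 non-empty groups after dropping zeros")
  }
  kw <- stats::kruskal.test(x, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, grand_mean = mean(x), n_groups = nlevels(g))
}

# Dunn z statistics (shared rank-variance with tie correction).
# ranks over ALL observations are computed once; for groups i, j:
#   z = (Rbar_i - Rbar_j) / sqrt(S * (1/n_i + 1/n_j)),
#   S = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))
dunn_z <- function(rank_sum_i, n_i, rank_sum_j, n_j, S) {
  (rank_sum_i / n_i - rank_sum_j / n_j) / sqrt(S * (1 / n_i + 1 / n_j))
}

#' Flag copy-number-expanded orthogroups with Dunn's post-hoc test
#'
#' Runs after a significant Kruskal-Wallis test (the gate can be
#' overridden).  The primary comparison scheme is one-vs-rest: each
#' orthogroup's copy counts against the pooled counts of all remaining
#' orthogroups, using Dunn's rank-based z with tie correction on a single
#' joint ranking.  P-values are adjusted (Benjamini-Hochberg by default)
#' and an orthogroup is flagged when its adjusted p-value falls below
#' `alpha` AND its mean copy number exceeds the grand mean — the elevated
#' side only, since expansion is the question of interest.  An all-pairs
#' scheme is available; there an orthogroup is flagged when, after
#' adjustment over all pairs, it is significantly above more than half of
#' the other orthogroups.
#'
#' @param matrix a [copy_matrix()].
#' @param alpha significance level (default 0.05).
#' @param adjust a [stats::p.adjust()] method (default `"BH"`).
#' @param scheme `"one_vs_rest"` (default) or `"all_pairs"`.
#' @param require_kw gate on a significant Kruskal-Wallis test (default
#'   `TRUE`).
#' @param two_sided_flag flag deviations on both sides rather than
#'   elevated only (default `FALSE`).
#' @return list of class `outlier_report`: `anderson_darling`,
#'   `kruskal_wallis`, `table` (per-orthogroup `z`, `p`, `p_adj`,
#'   `group_mean`, `flagged`), `flagged` (IDs), `grand_mean`, `scheme`,
#'   `alpha`, `adjust`.
#' @export
dunn_flag <- function(matrix, alpha = 0.05, adjust = "BH",
                      scheme = c("one_vs_rest", "all_pairs"),
                      require_kw = TRUE, two_sided_flag = FALSE) {
  scheme <- match.arg(scheme)
  if (any(rowSums(!is.na(matrix)) == 0L))
    stop("orthogroup with zero observations")
  ad <- normality_check(matrix, alpha = alpha)
  kw <- kruskal_wallis(matrix)
  grand_mean <- kw$grand_mean
  ogs <- rownames(matrix)
  k <- length(ogs)
  x <- as.numeric(t(matrix))
  g <- rep(seq_len(k), each = ncol(matrix))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  S <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rank_sums <- vapply(split(r, g), sum, numeric(1))
  n_i <- rep(ncol(matrix), k)
  group_means <- rowMeans(matrix)

  if (scheme == "one_vs_rest") {
    tot <- sum(r)
    z <- vapply(seq_len(k), function(i) {
      dunn_z(rank_sums[i], n_i[i], tot - rank_sums[i], N - n_i[i], S)
    }, numeric(1))
    p <- 2 * stats::pnorm(-abs(z))
    p_adj <- stats::p.adjust(p, method = adjust)
    elevated <- group_means > grand_mean
    flagged <- p_adj < alpha & (if (two_sided_flag) TRUE else elevated)
    tab <- data.frame(orthogroup = ogs, z = z, p = p, p_adj = p_adj,
                      group_mean = unname(group_means),
                      flagged = flagged, stringsAsFactors = FALSE)
  } else {
    pairs <- utils::combn(k, 2)
    zp <- apply(pairs, 2, function(ij) {
      dunn_z(rank_sums[ij[1]], n_i[ij[1]], rank_sums[ij[2]], n_i[ij[2]], S)
    })
    p <- 2 * stats::pnorm(-abs(zp))
    p_adj <- stats::p.adjust(p, method = adjust)
    # per-orthogroup: how many others is it significantly ABOVE?
    above <- integer(k)
    for (m in seq_along(zp)) {
      i <- pairs[1, m]; j <- pairs[2, m]
      if (p_adj[m] < alpha) {
        if (zp[m] > 0) above[i] <- above[i] + 1L else above[j] <- above[j] + 1L
      }
    }
    flagged <- above > (k - 1) / 2
    if (!two_sided_flag) flagged <- flagged & group_means > grand_mean
    tab <- data.frame(orthogroup = ogs, n_above = above,
                      group_mean = unname(group_means),
                      flagged = flagged, stringsAsFactors = FALSE)
  }
  if (require_kw && kw$p_value >= alpha) {
    tab$flagged <- FALSE
  }
  structure(list(anderson_darling = ad, kruskal_wallis = kw,
                 table = tab, flagged = tab$orthogroup[tab$flagged],
                 grand_mean = grand_mean, scheme = scheme,
                 alpha = alpha, adjust = adjust),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report (", x$scheme, "): ", nrow(x$table),
      " orthogroups tested, ", length(x$flagged), " flagged; grand mean ",
      signif(x$grand_mean, 5), "\n", sep = "")
  invisible(x)
}
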