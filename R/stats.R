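#' Per-class median / IQR summaries
#'
#' Median and interquartile range of one element's summed peak areas per
#' tissue class, using the linear-interpolation quantile rule (R type 7).
#' The quantile rule is pinned because the IQRs depend on it.
#'
#' @param features a feature table from [features_table()].
#' @param element `"Ca"`, `"K"` or `"Na"`.
#' @return data.frame with columns `tissue`, `n`, `median`, `iqr`.
#' @export
summarize_groups <- function(features, element = c("Ca", "K", "Na")) {
  element <- match.arg(element)
  col <- switch(element, Ca = "ca_sum", K = "k_sum", Na = "na_sum")
  if (anyNA(features$tissue)) {
    stop("all features must carry a tissue label")
  }
  classes <- unique(features$tissue)
  res <- lapply(classes, function(cl) {
    v <- features[[col]][features$tissue == cl]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(tissue = cl, n = length(v), median = q[2L],
               iqr = q[3L] - q[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Kruskal--Wallis omnibus test
#'
#' Rank-based k-group test of identical distributions: mid-rank H statistic
#' with tie correction, referred to the chi-square upper tail with k - 1
#' degrees of freedom (the group sizes here are in the hundreds, so the
#' chi-square approximation is appropriate). Delegates to
#' [stats::kruskal.test()], which implements exactly this statistic.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return list of class `kw_result` with fields `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("all groups must be nonempty")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    # every observation tied: no evidence of any difference
    return(structure(list(H = 0, df = length(groups) - 1L, p = 1),
                     class = "kw_result"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value),
            class = "kw_result")
}

#' Dunn's post hoc test
#'
#' Pairwise mean-rank z-tests on the pooled mid-ranks following a
#' Kruskal--Wallis test, with tie correction and Bonferroni adjustment
#' across all k(k-1)/2 pairs. For groups i, j with mean pooled ranks
#' `Ri`, `Rj`:
#' \deqn{z = (Ri - Rj) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie term \eqn{T = \sum_t (t^3 - t) / (12 (N - 1))} over tie-group
#' sizes t. Two-sided p from the normal tail; `p_adj = min(1, m p_raw)`.
#' Bonferroni is the conventional companion to Dunn's test and the
#' conservative choice; it is isolated here so a different family can be
#' swapped in.
#'
#' @param groups named list of >= 2 nonempty numeric vectors.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`.
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("all groups must be nonempty")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), lengths(groups))
  r <- rank(values)  # mid-ranks
  N <- length(values)
  tie_sizes <- table(values)
  Tcorr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  mean_rank <- tapply(r, idx, mean)
  n <- lengths(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               z = z, p_raw = p_raw, p_adj = min(1, m * p_raw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# element-wise feature column helper shared by the statistics stages
element_column <- function(element) {
  switch(match.arg(element, c("Ca", "K", "Na")),
         Ca = "ca_sum", K = "k_sum", Na = "na_sum")
}

# split one element's values into a named list of per-class vectors,
# restricted to the four study classes (reference classes are PCA-only)
element_groups <- function(features, element, classes = study_classes()) {
  col <- element_column(element)
  present <- intersect(classes, unique(features$tissue))
  stats::setNames(
    lapply(present, function(cl) features[[col]][features$tissue == cl]),
    present)
}
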