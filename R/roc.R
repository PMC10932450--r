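#' Mann--Whitney AUC
#'
#' The empirical area under the ROC curve equals the probability that a
#' random positive scores above a random negative, counting ties as one
#' half. Computed from the pooled mid-ranks (algebraically identical to
#' pair counting). If the raw value falls below 0.5 the orientation is
#' flipped (`lower-is-positive`) so the reported AUC is always >= 0.5.
#'
#' @param pos,neg nonempty numeric vectors of the positive and negative
#'   class scores.
#' @return list with `auc` (oriented, >= 0.5), `auc_raw` (higher-is-positive
#'   convention) and `direction` (`"higher-is-positive"` or
#'   `"lower-is-positive"`).
#' @export
auc_mann_whitney <- function(pos, neg) {
  n_pos <- length(pos); n_neg <- length(neg)
  if (n_pos == 0L || n_neg == 0L) stop("pos and neg must be nonempty")
  r <- rank(c(pos, neg))
  auc_raw <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  if (auc_raw >= 0.5) {
    list(auc = auc_raw, auc_raw = auc_raw, direction = "higher-is-positive")
  } else {
    list(auc = 1 - auc_raw, auc_raw = auc_raw,
         direction = "lower-is-positive")
  }
}

#' DeLong 95% confidence interval for the AUC
#'
#' Structural-components (DeLong) variance with a normal 95% interval,
#' truncated to [0, 1]. Delegates to [pROC::ci.auc()], the field-standard
#' implementation. With perfect separation the variance degenerates to 0 and
#' the interval collapses to `(auc, auc)`, flagged via the `degenerate`
#' attribute.
#'
#' @param pos,neg numeric vectors with at least 2 values each.
#' @return numeric vector `c(lo, hi)`.
#' @export
auc_ci_delong <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need at least 2 values per group for a DeLong interval")
  }
  mw <- auc_mann_whitney(pos, neg)
  dir <- if (mw$direction == "higher-is-positive") "<" else ">"
  r <- pROC::roc(response = c(rep(0L, length(neg)), rep(1L, length(pos))),
                 predictor = c(neg, pos), direction = dir,
                 quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  lo <- max(0, ci[1L]); hi <- min(1, ci[3L])
  out <- c(lo = lo, hi = hi)
  if (hi - lo <= 0) attr(out, "degenerate") <- TRUE
  out
}

#' Youden-index optimal cutoff
#'
#' Scans thresholds at the midpoints between adjacent distinct pooled
#' values and maximizes J = sensitivity + specificity - 1 under the given
#' orientation. Ties are broken toward the cutoff with higher sensitivity,
#' then toward the lower cutoff. Midpoint candidates (rather than observed
#' values) make the scan reproducible and symmetric in direction.
#'
#' @param pos,neg nonempty numeric vectors.
#' @param direction `"higher-is-positive"`, `"lower-is-positive"`, or `NULL`
#'   to take the orientation from [auc_mann_whitney()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `J`,
#'   `direction`.
#' @export
youden_cutoff <- function(pos, neg, direction = NULL) {
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("pos and neg must be nonempty")
  }
  pooled <- sort(unique(c(pos, neg)))
  if (length(pooled) < 2L) {
    stop("identical constant samples: no informative threshold exists")
  }
  if (is.null(direction)) direction <- auc_mann_whitney(pos, neg)$direction
  direction <- match.arg(direction,
                         c("higher-is-positive", "lower-is-positive"))
  cuts <- (pooled[-1L] + pooled[-length(pooled)]) / 2
  if (direction == "higher-is-positive") {
    sens <- vapply(cuts, function(c) mean(pos > c), numeric(1))
    spec <- vapply(cuts, function(c) mean(neg < c), numeric(1))
  } else {
    sens <- vapply(cuts, function(c) mean(pos < c), numeric(1))
    spec <- vapply(cuts, function(c) mean(neg > c), numeric(1))
  }
  J <- sens + spec - 1
  # ties: higher sensitivity first, then lower cutoff
  ord <- order(-J, -sens, cuts)
  best <- ord[1L]
  list(cutoff = cuts[best], sensitivity = sens[best],
       specificity = spec[best], J = J[best], direction = direction)
}

# Table-3 pair order
.roc_pairs <- function() {
  list(c("fibrosis", "nerve"), c("fibrosis", "tumor_stroma"),
       c("fibrosis", "cell_rich_tumor"), c("nerve", "tumor_stroma"),
       c("nerve", "cell_rich_tumor"), c("tumor_stroma", "cell_rich_tumor"))
}

#' Pairwise ROC report
#'
#' One row per tissue pair and element (6 pairs x Ca/K = 12 rows): oriented
#' Mann--Whitney AUC, DeLong 95% CI, p-value of AUC = 0.5 from the normal
#' approximation to the Mann--Whitney null, Youden cutoff with its
#' sensitivity and specificity. The first class of each pair is the positive
#' class; the orientation (`direction`) says whether higher or lower values
#' indicate it.
#'
#' @param features a feature table containing all four study classes.
#' @return data.frame with 12 rows and columns `positive_class`,
#'   `negative_class`, `element`, `auc`, `ci_lo`, `ci_hi`, `p`, `direction`,
#'   `cutoff`, `sensitivity`, `specificity`.
#' @export
pairwise_roc_report <- function(features) {
  present <- unique(features$tissue)
  missing_cls <- setdiff(study_classes(), present)
  if (length(missing_cls)) {
    stop("feature table is missing class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  rows <- list()
  for (pair in .roc_pairs()) {
    for (el in c("Ca", "K")) {
      col <- element_column(el)
      pos <- features[[col]][features$tissue == pair[1L]]
      neg <- features[[col]][features$tissue == pair[2L]]
      mw <- auc_mann_whitney(pos, neg)
      ci <- auc_ci_delong(pos, neg)
      yj <- youden_cutoff(pos, neg, direction = mw$direction)
      n1 <- length(pos); n2 <- length(neg)
      se0 <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
      p <- 2 * stats::pnorm(-abs(mw$auc_raw - 0.5) / se0)
      rows[[length(rows) + 1L]] <- data.frame(
        positive_class = pair[1L], negative_class = pair[2L], element = el,
        auc = mw$auc, ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
        p = p, direction = mw$direction, cutoff = yj$cutoff,
        sensitivity = yj$sensitivity, specificity = yj$specificity,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
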