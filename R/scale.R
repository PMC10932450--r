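#' Build a four-class metric scale
#'
#' Orders the four study classes by their median of one element's summed
#' peak area and places a Youden-optimal cutoff between each
#' median-adjacent pair (adjacent-pair ROC, higher-is-positive toward the
#' upper class). The three cutoffs must come out strictly ascending --
#' that is the only reading under which they partition the nonnegative
#' axis into four ordered class intervals; a non-monotone result is an
#' error naming the violating pair.
#'
#' @param features a feature table with all four study classes.
#' @param element `"Ca"` or `"K"`.
#' @return list of class `metric_scale` with fields `element`,
#'   `ordered_classes` (ascending class medians), `cutoffs` (3 ascending AU
#'   values) and `medians`.
#' @export
build_metric_scale <- function(features, element = c("Ca", "K")) {
  element <- match.arg(element)
  col <- element_column(element)
  sub <- features[features$tissue %in% study_classes(), , drop = FALSE]
  missing_cls <- setdiff(study_classes(), unique(sub$tissue))
  if (length(missing_cls)) {
    stop("feature table is missing class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  med <- vapply(study_classes(),
                function(cl) stats::median(sub[[col]][sub$tissue == cl]),
                numeric(1))
  ordered <- names(sort(med))
  cutoffs <- numeric(3L)
  for (i in 1:3) {
    lower <- sub[[col]][sub$tissue == ordered[i]]
    upper <- sub[[col]][sub$tissue == ordered[i + 1L]]
    yj <- youden_cutoff(pos = upper, neg = lower,
                        direction = "higher-is-positive")
    cutoffs[i] <- yj$cutoff
  }
  if (any(diff(cutoffs) <= 0)) {
    bad <- which(diff(cutoffs) <= 0)[1L]
    stop("metric scale undefined for ", element, ": cutoff between ",
         ordered[bad + 1L], " and ", ordered[bad + 2L],
         " is not above the cutoff between ", ordered[bad], " and ",
         ordered[bad + 1L])
  }
  structure(list(element = element, ordered_classes = ordered,
                 cutoffs = cutoffs, medians = med[ordered]),
            class = "metric_scale")
}

#' Construct a metric scale from known cutoffs
#'
#' Builds a [build_metric_scale()]-shaped object directly from an ordered
#' class sequence and three ascending cutoffs -- for applying a previously
#' published scale to new values with [classify()].
#'
#' @param element `"Ca"` or `"K"`.
#' @param ordered_classes four tissue classes in ascending order of the
#'   element's class median.
#' @param cutoffs three strictly ascending boundary values, AU.
#' @return a `metric_scale`.
#' @export
metric_scale <- function(element, ordered_classes, cutoffs) {
  element <- match.arg(element, c("Ca", "K"))
  ordered_classes <- as_tissue_class(ordered_classes)
  stopifnot(length(ordered_classes) == 4L, !anyDuplicated(ordered_classes),
            length(cutoffs) == 3L)
  if (any(cutoffs <= 0) || any(diff(cutoffs) <= 0)) {
    stop("cutoffs must be positive and strictly ascending")
  }
  structure(list(element = element, ordered_classes = ordered_classes,
                 cutoffs = as.numeric(cutoffs), medians = NULL),
            class = "metric_scale")
}

#' @export
print.metric_scale <- function(x, ...) {
  bounds <- c(0, x$cutoffs, Inf)
  cat("<metric_scale> ", x$element, "\n", sep = "")
  for (i in seq_along(x$ordered_classes)) {
    cat(sprintf("  [%g, %g) -> %s\n", bounds[i], bounds[i + 1L],
                x$ordered_classes[i]))
  }
  invisible(x)
}

#' Classify a peak-area value on a metric scale
#'
#' Returns the class of the half-open interval containing the value; each
#' boundary belongs to the upper interval (the ">= lo to < hi" convention).
#'
#' @param value nonnegative summed peak area(s), AU.
#' @param scale a [build_metric_scale()] result.
#' @return character vector of tissue classes.
#' @export
classify <- function(value, scale) {
  stopifnot(inherits(scale, "metric_scale"))
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("values must be finite and nonnegative")
  }
  idx <- findInterval(value, scale$cutoffs) + 1L
  scale$ordered_classes[idx]
}
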