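test_that("Mann-Whitney AUC handles the canonical cases", {
  expect_equal(auc_mann_whitney(c(4, 5, 6), c(1, 2, 3))$auc, 1)
  expect_equal(auc_mann_whitney(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(auc_mann_whitney(c(2, 4), c(1, 3))$auc, 0.75)
  # orientation flips so the reported AUC is always >= 0.5
  flipped <- auc_mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(flipped$auc, 1)
  expect_equal(flipped$auc_raw, 0)
  expect_equal(flipped$direction, "lower-is-positive")
  expect_error(auc_mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("rank-based AUC equals the pair-counting oracle with ties", {
  pair_count_auc <- function(pos, neg) {
    wins <- 0
    for (p in pos) for (n in neg) {
      wins <- wins + (p > n) + 0.5 * (p == n)
    }
    wins / (length(pos) * length(neg))
  }
  set.seed(61)
  for (i in 1:30) {
    pos <- sample(0:12, sample(1:20, 1), replace = TRUE)  # integer ties
    neg <- sample(0:12, sample(1:20, 1), replace = TRUE)
    expect_equal(auc_mann_whitney(pos, neg)$auc_raw,
                 pair_count_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("empirical AUC converges to the binormal-on-log value", {
  p1 <- calibrate_lognormal(4.973, 8.369)
  p2 <- calibrate_lognormal(63.64, 15.07)
  theory <- pnorm((p2$mu - p1$mu) / sqrt(p1$sigma^2 + p2$sigma^2))
  set.seed(404)
  emp <- auc_mann_whitney(rlnorm(5000, p2$mu, p2$sigma),
                          rlnorm(5000, p1$mu, p1$sigma))$auc
  expect_lt(abs(emp - theory), 0.01)
})

test_that("DeLong interval behaves at the boundary and contracts with n", {
  ci_perfect <- auc_ci_delong(c(4, 5, 6), c(1, 2, 3))
  expect_equal(unname(ci_perfect["hi"]), 1)
  expect_true(isTRUE(attr(ci_perfect, "degenerate")))
  set.seed(8)
  pos <- rnorm(60, 1); neg <- rnorm(60)
  w1 <- diff(auc_ci_delong(pos, neg))
  w2 <- diff(auc_ci_delong(c(pos, rnorm(60, 1)), c(neg, rnorm(60))))
  expect_lt(w2, w1)
  expect_error(auc_ci_delong(1, 1:5), "at least 2")
})

test_that("DeLong 95% interval covers the true AUC at nominal rate", {
  p1 <- calibrate_lognormal(3.339, 1.31)
  p2 <- calibrate_lognormal(5.669, 2.812)
  truth <- pnorm((p2$mu - p1$mu) / sqrt(p1$sigma^2 + p2$sigma^2))
  set.seed(515)
  covered <- replicate(1000, {
    ci <- auc_ci_delong(rlnorm(100, p2$mu, p2$sigma),
                        rlnorm(100, p1$mu, p1$sigma))
    ci["lo"] <= truth && truth <= ci["hi"]
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("Youden cutoff separates the canonical cases", {
  y <- youden_cutoff(c(4, 5, 6), c(1, 2, 3))
  expect_equal(y$J, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  expect_gt(y$cutoff, 3); expect_lt(y$cutoff, 4)
  # symmetric overlap: enumerating the 3 midpoints gives J = 0 at 2.5
  y2 <- youden_cutoff(c(1, 3), c(2, 4), direction = "higher-is-positive")
  expect_equal(y2$cutoff, 2.5)
  expect_equal(y2$J, 0)
  expect_error(youden_cutoff(c(2, 2), c(2, 2)), "constant")
})

test_that("Youden scan equals the exhaustive brute-force oracle", {
  brute <- function(pos, neg, direction) {
    pooled <- sort(unique(c(pos, neg)))
    cuts <- (pooled[-1] + pooled[-length(pooled)]) / 2
    best <- NULL
    for (c_ in cuts) {
      if (direction == "higher-is-positive") {
        sens <- mean(pos > c_); spec <- mean(neg < c_)
      } else {
        sens <- mean(pos < c_); spec <- mean(neg > c_)
      }
      J <- sens + spec - 1
      better <- is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && sens > best$sens + 1e-12)
      if (better) best <- list(cut = c_, J = J, sens = sens, spec = spec)
    }
    best
  }
  set.seed(78)
  for (i in 1:50) {
    pos <- round(runif(sample(2:20, 1), 0, 10), 1)
    neg <- round(runif(sample(2:20, 1), 0, 10), 1)
    if (length(unique(c(pos, neg))) < 2) next
    dir <- sample(c("higher-is-positive", "lower-is-positive"), 1)
    got <- youden_cutoff(pos, neg, direction = dir)
    want <- brute(pos, neg, dir)
    expect_equal(got$cutoff, want$cut)
    expect_equal(got$J, want$J)
    expect_equal(got$sensitivity, want$sens)
    expect_equal(got$specificity, want$spec)
  }
})

test_that("pairwise report is Table-3 shaped and self-consistent", {
  ft <- feature_draws(default_model(), c(fibrosis = 60, nerve = 80,
                                         tumor_stroma = 90,
                                         cell_rich_tumor = 100), seed = 7)
  roc <- pairwise_roc_report(ft)
  expect_equal(nrow(roc), 12L)
  expect_equal(sum(roc$element == "Ca"), 6L)
  expect_true(all(roc$ci_lo <= roc$auc + 1e-12))
  expect_true(all(roc$auc <= roc$ci_hi + 1e-12))
  expect_true(all(roc$auc >= 0.5))
  expect_true(all(roc$p >= 0 & roc$p <= 1))
  # stored (cutoff, sensitivity, specificity) recompute exactly
  for (row in seq_len(nrow(roc))) {
    col <- if (roc$element[row] == "Ca") "ca_sum" else "k_sum"
    pos <- ft[[col]][ft$tissue == roc$positive_class[row]]
    neg <- ft[[col]][ft$tissue == roc$negative_class[row]]
    if (roc$direction[row] == "higher-is-positive") {
      sens <- mean(pos > roc$cutoff[row]); spec <- mean(neg < roc$cutoff[row])
    } else {
      sens <- mean(pos < roc$cutoff[row]); spec <- mean(neg > roc$cutoff[row])
    }
    expect_equal(roc$sensitivity[row], sens)
    expect_equal(roc$specificity[row], spec)
  }
  expect_error(pairwise_roc_report(ft[ft$tissue != "nerve", ]),
               "missing class")
})

test_that("element-specific accuracy ordering matches the study", {
  # Ca outperforms K for fibrosis vs nerve; K outperforms Ca for
  # fibrosis vs cell-rich tumor
  ft <- feature_draws(default_model(), dataset_spec()$counts, seed = 11)
  roc <- pairwise_roc_report(ft)
  pick <- function(p2, el) {
    roc$auc[roc$positive_class == "fibrosis" & roc$negative_class == p2 &
              roc$element == el]
  }
  expect_gt(pick("nerve", "Ca"), pick("nerve", "K"))
  expect_gt(pick("cell_rich_tumor", "K"), pick("cell_rich_tumor", "Ca"))
})
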