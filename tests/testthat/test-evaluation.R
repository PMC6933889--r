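# build a probability matrix that predicts `pred` with probability 0.8
.probs_for <- function(pred, labels = c("acceptor", "donor", "non_splice")) {
  p <- matrix(0.1, nrow = length(pred), ncol = length(labels),
              dimnames = list(NULL, labels))
  p[cbind(seq_along(pred), match(pred, labels))] <- 0.8
  p
}

test_that("recall, precision and F1 follow the printed formulas", {
  # donor: TP=8, FN=2, FP=2 -> all 0.8
  y <- c(rep("donor", 10), rep("non_splice", 10))
  pred <- c(rep("donor", 8), rep("non_splice", 2),
            rep("donor", 2), rep("non_splice", 8))
  r <- classification_metrics(y, .probs_for(pred))
  don <- r$per_class[r$per_class$class == "donor", ]
  expect_equal(don$recall, 0.8)
  expect_equal(don$precision, 0.8)
  expect_equal(don$f1, 0.8)
  # donor: TP=6, FN=4, FP=2 -> recall .6, precision .75, F1 = 2/3
  pred2 <- c(rep("donor", 6), rep("non_splice", 4),
             rep("donor", 2), rep("non_splice", 8))
  r2 <- classification_metrics(y, .probs_for(pred2))
  don2 <- r2$per_class[r2$per_class$class == "donor", ]
  expect_equal(don2$recall, 0.6)
  expect_equal(don2$precision, 0.75)
  expect_equal(don2$f1, 2 / 3)
})

test_that("perfect predictions give accuracy 1 and AUC 1", {
  y <- rep(c("acceptor", "donor", "non_splice"), each = 5)
  r <- classification_metrics(y, .probs_for(y))
  expect_equal(r$accuracy, 1)
  expect_equal(r$per_class$auc, c(1, 1))
  expect_equal(r$per_class$f1, c(1, 1))
})

test_that("metrics agree with a naive confusion-matrix oracle", {
  labels <- c("acceptor", "donor", "non_splice")
  naive <- function(y, pred, cls) {
    tp <- sum(y == cls & pred == cls)
    fp <- sum(y != cls & pred == cls)
    fn <- sum(y == cls & pred != cls)
    c(recall = if (tp + fn > 0) tp / (tp + fn) else NA,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA,
      acc = mean(y == pred))
  }
  # exhaustive over all (y_true, y_pred) assignments for n = 3
  grid <- expand.grid(rep(list(1:3), 6))
  for (i in seq_len(nrow(grid))) {
    y <- labels[as.integer(grid[i, 1:3])]
    pred <- labels[as.integer(grid[i, 4:6])]
    r <- classification_metrics(y, .probs_for(pred))
    expect_equal(r$accuracy, unname(naive(y, pred, "donor")["acc"]))
    for (cls in c("donor", "acceptor")) {
      row <- r$per_class[r$per_class$class == cls, ]
      o <- naive(y, pred, cls)
      if (!any(y == cls)) {
        expect_true(is.na(row$recall))
      } else {
        expect_equal(row$recall, unname(o["recall"]))
        if (!is.na(o["precision"]))
          expect_equal(row$precision, unname(o["precision"]))
      }
    }
  }
  # random label sets at n = 8
  set.seed(20)
  for (i in 1:100) {
    y <- sample(labels, 8, replace = TRUE)
    pred <- sample(labels, 8, replace = TRUE)
    r <- classification_metrics(y, .probs_for(pred))
    for (cls in c("donor", "acceptor")) {
      if (!any(y == cls)) next
      row <- r$per_class[r$per_class$class == cls, ]
      expect_equal(row$recall, unname(naive(y, pred, cls)["recall"]))
    }
  }
})

test_that("ROC/PR sweep matches pROC and behaves at the extremes", {
  set.seed(21)
  y <- rep(c(TRUE, FALSE), each = 50)
  s <- ifelse(y, stats::rnorm(100, 1), stats::rnorm(100, 0))
  cc <- curves(y, s)
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
  expect_equal(cc$auc, auc_ref, tolerance = 1e-10)
  # perfect separation passes through (0,1)
  cp <- curves(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.1))
  expect_equal(cp$auc, 1)
  expect_true(any(cp$roc_points$fpr == 0 & cp$roc_points$tpr == 1))
  # label-independent scores: AUC ~ 0.5
  set.seed(22)
  y0 <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  expect_lt(abs(curves(y0, stats::runif(4000))$auc - 0.5), 0.03)
  # degenerate single-class input
  expect_true(is.na(curves(rep(TRUE, 5), 1:5)$auc))
})

.mk_calls <- function(b, s, ty = "donor") {
  data.frame(seq_name = "chr1", boundary = b, site_type = ty, score = s,
             passed_filter = NA, stringsAsFactors = FALSE)
}
.mk_sites <- function(b, ty = "donor") {
  data.frame(seq_name = "chr1", site_type = ty, boundary = b,
             canonical = TRUE, stringsAsFactors = FALSE)
}

test_that("FP-at-recall reports the sweep's most stringent threshold", {
  truth <- .mk_sites(c(10L, 50L))
  calls <- .mk_calls(c(10L, 30L, 50L, 70L), c(0.9, 0.8, 0.6, 0.7))
  r1 <- fp_at_recall(calls, truth, recall_target = 1.0)
  don <- r1$per_type[r1$per_type$site_type == "donor", ]
  expect_equal(don$threshold, 0.6)
  expect_equal(don$fp_count, 2L)
  expect_true(don$attainable)
  r2 <- fp_at_recall(calls, truth, recall_target = 0.5)
  don2 <- r2$per_type[r2$per_type$site_type == "donor", ]
  expect_equal(don2$threshold, 0.9)
  expect_equal(don2$fp_count, 0L)
  # unreachable recall
  r3 <- fp_at_recall(.mk_calls(c(10L, 30L), c(0.9, 0.8)), truth, 1.0)
  don3 <- r3$per_type[r3$per_type$site_type == "donor", ]
  expect_false(don3$attainable)
  expect_true(is.na(don3$fp_count))
  expect_error(fp_at_recall(calls, truth, 1.5), "parameter error")
})

test_that("FP count is monotone in the recall target", {
  set.seed(23)
  for (rep in 1:10) {
    truth <- .mk_sites(sort(sample(1000L, 8)))
    nb <- sort(sample(2000L, 30))
    calls <- .mk_calls(c(truth$boundary, nb),
                       stats::runif(8 + 30))
    fps <- sapply(c(0.25, 0.5, 0.75, 1.0), function(t) {
      r <- fp_at_recall(calls, truth, t)
      r$per_type$fp_count[r$per_type$site_type == "donor"]
    })
    expect_true(all(diff(fps) >= 0))
  }
})

test_that("a large match tolerance absorbs every call into a site", {
  truth <- .mk_sites(c(100L, 500L))
  calls <- .mk_calls(c(101L, 103L, 480L), c(0.9, 0.8, 0.7))
  r <- fp_at_recall(calls, truth, 1.0, tolerance = 1000L)
  expect_equal(r$per_type$fp_count[r$per_type$site_type == "donor"], 0L)
  # combined count sums per-type FP counts at their own thresholds
  truth2 <- rbind(truth, .mk_sites(200L, "acceptor"))
  calls2 <- rbind(calls, .mk_calls(c(200L, 300L), c(0.9, 0.8), "acceptor"))
  r2 <- fp_at_recall(calls2, truth2, 1.0, tolerance = 0L)
  acc <- r2$per_type[r2$per_type$site_type == "acceptor", ]
  expect_equal(acc$fp_count, 0L)  # threshold 0.9 already reaches recall 1
})
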