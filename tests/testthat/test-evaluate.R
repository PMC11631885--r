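test_that("Cohen's kappa reproduces the clinical validation fixture", {
  # pooled 2x2 table: 53 of 65 narrowed sites detected, 219 of 229 normal
  # sites correctly rejected
  tab <- confusion_table(tp = 53, fn = 12, fp = 10, tn = 219)
  expect_identical(round_half_up(cohen_kappa(tab), 3), 0.78)
  expect_identical(cohen_kappa(confusion_table(10, 0, 0, 10)), 1)
  expect_identical(cohen_kappa(confusion_table(25, 25, 25, 25)), 0)
  expect_error(confusion_table(0, 0, 0, 0), "empty")
})

test_that("diagnostic metrics reproduce the printed validation row", {
  m <- confusion_metrics(confusion_table(53, 12, 10, 219))
  expect_identical(round_half_up(m$sensitivity, 1), 81.5)
  expect_identical(round_half_up(m$specificity, 1), 95.6)
  expect_identical(round_half_up(m$ppv, 1), 84.1)
  expect_identical(round_half_up(m$npv, 1), 94.8)
  expect_identical(round_half_up(m$accuracy, 1), 92.5)
  expect_length(m$undefined, 0)
  all100 <- confusion_metrics(confusion_table(10, 0, 0, 10))
  expect_true(all(unlist(all100[1:5]) == 100))
  deg <- confusion_metrics(confusion_table(0, 10, 0, 10))
  expect_identical(deg$sensitivity, 0)
  expect_identical(deg$npv, 50)
  expect_true(is.na(deg$ppv))
  expect_identical(deg$undefined, "ppv")
})

test_that("kappa and metrics satisfy the algebraic identity", {
  withr::local_seed(11)
  for (i in 1:20) {
    cnt <- sample(0:40, 4, replace = TRUE)
    if (sum(cnt) == 0) next
    tab <- confusion_table(cnt[1], cnt[2], cnt[3], cnt[4])
    k <- cohen_kappa(tab)
    expect_gte(k, -1)
    expect_lte(k, 1)
    acc <- confusion_metrics(tab)$accuracy / 100
    n <- sum(cnt)
    pe <- ((cnt[1] + cnt[2]) * (cnt[1] + cnt[3]) +
             (cnt[3] + cnt[4]) * (cnt[2] + cnt[4])) / n^2
    if (abs(1 - pe) > 1e-12) expect_equal(k, (acc - pe) / (1 - pe))
    if (cnt[2] == 0 && cnt[3] == 0) expect_identical(k, 1)
  }
})

test_that("Fleiss' kappa matches the direct formula", {
  expect_identical(fleiss_kappa(rbind(c(3, 0), c(0, 3), c(3, 0), c(0, 3))), 1)
  m <- rbind(c(2, 1), c(1, 2), c(3, 0), c(0, 3))
  # independent brute-force evaluation of the standard formulation
  nr <- 3
  Pi <- (rowSums(m^2) - nr) / (nr * (nr - 1))
  pj <- colSums(m) / sum(m)
  expected <- (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
  expect_equal(fleiss_kappa(m), expected)
  expect_error(fleiss_kappa(rbind(c(2, 1), c(1, 1))), "row sums")
  expect_error(fleiss_kappa(matrix(c(3, 0), 1, 2)), "2 items")
})

test_that("ROC/Youden separates and matches brute-force AUC", {
  r <- roc_youden(c(0.4, 0.5, 1.0, 1.1), c(TRUE, TRUE, FALSE, FALSE),
                  n_boot = 0)
  expect_identical(r$auc, 1)
  expect_identical(r$sensitivity, 100)
  expect_identical(r$specificity, 100)
  expect_gte(r$threshold, 0.5)
  expect_lt(r$threshold, 1.0)
  # worked 3-vs-3 example: 8 of 9 positive-negative pairs correctly ordered
  r2 <- roc_youden(c(0.5, 0.6, 1.0, 0.9, 1.1, 1.2),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), n_boot = 0)
  expect_equal(r2$auc, 8 / 9)
  expect_error(roc_youden(c(1, 2), c(TRUE, TRUE), n_boot = 0), "both")
})

test_that("rank AUC equals brute-force pair counting on random instances", {
  withr::local_seed(5)
  for (i in 1:100) {
    n1 <- sample(2:100, 1)
    n0 <- sample(2:100, 1)
    ratios <- c(round(runif(n1, 0.2, 1.2), 2), round(runif(n0, 0.5, 1.5), 2))
    truth <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_youden(ratios, truth, n_boot = 0)
    expect_equal(r$auc, auc_brute(ratios, truth), tolerance = 1e-12)
  }
})

test_that("shuffled labels give chance-level AUC", {
  withr::local_seed(8)
  ratios <- runif(400, 0.3, 1.3)
  truth <- sample(rep(c(TRUE, FALSE), each = 200))
  r <- roc_youden(ratios, truth, n_boot = 0)
  se <- sqrt((200 + 200 + 1) / (12 * 200 * 200))  # null Wilcoxon SE
  expect_lt(abs(r$auc - 0.5), 3 * se)
})

test_that("bootstrap CI is seeded and ordered", {
  withr::local_seed(2)
  ratios <- c(runif(40, 0.3, 0.8), runif(60, 0.7, 1.4))
  truth <- rep(c(TRUE, FALSE), c(40, 60))
  a <- roc_youden(ratios, truth, n_boot = 200, seed = 9)
  b <- roc_youden(ratios, truth, n_boot = 200, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci[1], a$auc)
  expect_gte(a$ci[2], a$auc)
})

test_that("agreement_report pools gaps across images", {
  gaps <- data.frame(image = rep(1:4, each = 5), gap_index = rep(1:5, 4),
                     label = rep(c("narrowed", "normal"), c(8, 12)))
  rep1 <- agreement_report(gaps, gaps)
  expect_identical(rep1$kappa, 1)
  expect_identical(rep1$metrics$accuracy, 100)
  flipped <- gaps
  flipped$label <- ifelse(gaps$label == "narrowed", "normal", "narrowed")
  expect_lt(agreement_report(flipped, gaps)$kappa, 0)
  # unassigned counts as not-narrowed
  una <- gaps
  una$label[una$label == "normal"] <- "unassigned"
  expect_identical(agreement_report(una, gaps)$kappa, 1)
  bad <- gaps[-1, ]
  expect_error(agreement_report(bad, gaps), "misaligned")
})
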