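#' 2x2 confusion table of narrowed-vs-not decisions
#'
#' Reference (rows) is the clinician judgement, test (columns) the model.
#'
#' @param tp,fn,fp,tn non-negative counts: true/false positives/negatives for
#'   the "narrowed" class.
#' @return an object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("empty confusion table", call. = FALSE)
  structure(as.list(counts), class = "confusion_table")
}

#' Cohen's kappa for a 2x2 narrowed-vs-not table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn) / N` and chance agreement `p_e` from the row
#' and column margins. Degenerate tables with `p_e = 1` return 1 when
#' agreement is perfect.
#'
#' @param table a [confusion_table()].
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$tp + table$fn + table$fp + table$tn
  po <- (table$tp + table$tn) / n
  ref_pos <- table$tp + table$fn
  test_pos <- table$tp + table$fp
  pe <- (ref_pos * test_pos + (n - ref_pos) * (n - test_pos)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Diagnostic metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, and accuracy, all in percent. A metric whose
#' denominator is zero is undefined: it is returned as `NA` and named in the
#' `undefined` element rather than failing the whole table.
#'
#' @param table a [confusion_table()].
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`
#'   (percent, unrounded) and `undefined` (character vector).
#' @export
confusion_metrics <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$tp + table$fn + table$fp + table$tn
  safe <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    sensitivity = safe(table$tp, table$tp + table$fn),
    specificity = safe(table$tn, table$tn + table$fp),
    ppv = safe(table$tp, table$tp + table$fp),
    npv = safe(table$tn, table$tn + table$fn),
    accuracy = 100 * (table$tp + table$tn) / n)
  out$undefined <- names(out)[vapply(out, function(x) is.na(x[1]), logical(1))]
  out
}

#' Fleiss' kappa for multiple raters
#'
#' Standard formulation for `n` items rated by a constant number of raters
#' into `k` categories: per-item agreement `P_i`, mean observed agreement,
#' chance agreement from pooled category proportions.
#'
#' @param ratings items x categories count matrix; every row must sum to the
#'   same number of raters (>= 2).
#' @return kappa value.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) stop("need at least 2 items", call. = FALSE)
  m <- unique(rowSums(ratings))
  if (length(m) != 1L)
    stop("non-constant row sums: every item needs the same number of raters",
         call. = FALSE)
  if (m < 2) stop("need at least 2 raters", call. = FALSE)
  n <- nrow(ratings)
  Pi <- (rowSums(ratings^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  pj <- colSums(ratings) / (n * m)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < .Machine$double.eps) return(if (Pbar == 1) 1 else 0)
  (Pbar - Pe) / (1 - Pe)
}

#' ROC analysis of the ratio-to-mean score with Youden-index thresholding
#'
#' Narrowed gaps have smaller width ratios, so the classifier score is the
#' negated ratio. AUC is computed by the rank (Mann-Whitney) method with ties
#' counted one half. The operating threshold maximizes the Youden index
#' `J = sensitivity + specificity - 1` over the observed ratio cuts
#' (prediction: narrowed iff `ratio <= threshold`); ties in `J` resolve
#' toward higher specificity. The AUC confidence interval is a seeded
#' stratified percentile bootstrap.
#'
#' @param ratios per-gap ratio-to-mean values.
#' @param reference logical (or "narrowed"/"normal") per-gap truth.
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 skips it).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `roc_result`: `auc`, `ci`, `threshold`,
#'   `sensitivity`, `specificity` (percent at the threshold), `youden_j`.
#' @export
roc_youden <- function(ratios, reference, n_boot = 2000L, conf = 0.95,
                       seed = NULL) {
  if (is.character(reference)) reference <- reference == "narrowed"
  reference <- as.logical(reference)
  stopifnot(length(ratios) == length(reference), !anyNA(ratios),
            !anyNA(reference))
  if (!any(reference) || all(reference))
    stop("reference must contain both narrowed and normal gaps", call. = FALSE)
  auc_of <- function(r, ref) {
    sc <- -r
    rk <- rank(sc)  # midranks handle ties with weight 1/2
    n1 <- sum(ref)
    n0 <- sum(!ref)
    (sum(rk[ref]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(ratios, reference)
  cuts <- sort(unique(ratios))
  best <- list(j = -Inf, spec = -Inf, thr = cuts[1], sens = NA, spec_pct = NA)
  for (thr in cuts) {
    pred <- ratios <= thr
    sens <- sum(pred & reference) / sum(reference)
    spec <- sum(!pred & !reference) / sum(!reference)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(j = j, spec = spec, thr = thr, sens = sens, spec_pct = spec)
    }
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ci <- with_seed(seed, {
      pos <- which(reference)
      neg <- which(!reference)
      reps <- vapply(seq_len(n_boot), function(i) {
        idx <- c(sample(pos, length(pos), replace = TRUE),
                 sample(neg, length(neg), replace = TRUE))
        auc_of(ratios[idx], reference[idx])
      }, numeric(1))
      unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    })
  }
  structure(list(auc = auc, ci = ci, conf = conf, threshold = best$thr,
                 sensitivity = 100 * best$sens,
                 specificity = 100 * best$spec_pct,
                 youden_j = best$j, n_pos = sum(reference),
                 n_neg = sum(!reference)),
            class = "roc_result")
}

#' Agreement report between model and reference gap labels
#'
#' Pools per-gap narrowed-vs-not decisions across all images into one 2x2
#' table (the pooled-validation reading of the headline agreement analysis)
#' and reports Cohen's kappa plus the diagnostic metrics. Gap lists must
#' align one-to-one per image by ordinal gap index; `"unassigned"` model
#' gaps count as not-narrowed.
#'
#' @param model_gaps,reference_gaps data frames with columns `image`,
#'   `gap_index`, `label`.
#' @return list of class `agreement_report`: `table`, `kappa`, `metrics`.
#' @export
agreement_report <- function(model_gaps, reference_gaps) {
  need <- c("image", "gap_index", "label")
  stopifnot(all(need %in% names(model_gaps)),
            all(need %in% names(reference_gaps)))
  mo <- model_gaps[order(model_gaps$image, model_gaps$gap_index), ]
  re <- reference_gaps[order(reference_gaps$image, reference_gaps$gap_index), ]
  if (nrow(mo) != nrow(re) ||
      !identical(paste(mo$image, mo$gap_index), paste(re$image, re$gap_index)))
    stop("model and reference gap tables are misaligned", call. = FALSE)
  mpos <- mo$label == "narrowed"
  rpos <- re$label == "narrowed"
  tab <- confusion_table(tp = sum(mpos & rpos), fn = sum(!mpos & rpos),
                         fp = sum(mpos & !rpos), tn = sum(!mpos & !rpos))
  structure(list(table = tab, kappa = cohen_kappa(tab),
                 metrics = confusion_metrics(tab)),
            class = "agreement_report")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(reference = c("narrowed", "normal"),
                              model = c("narrowed", "normal")))
  print(t(m))
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f), %d narrowed vs %d normal\n",
              x$auc, round(100 * x$conf), x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  cat(sprintf(
    "Youden threshold: ratio <= %.4g  (sensitivity %.1f%%, specificity %.1f%%)\n",
    x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$table)
  m <- x$metrics
  cat(sprintf(
    "kappa %.3f | sensitivity %.1f%% specificity %.1f%% PPV %.1f%% NPV %.1f%% accuracy %.1f%%\n",
    x$kappa, m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy))
  invisible(x)
}
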