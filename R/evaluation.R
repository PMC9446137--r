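#' Confusion matrix between two label maps
#'
#' Tallies pixel pairs over all palette classes, truth in rows and
#' prediction in columns.  With `ignore_unlabeled` (the default), pixels
#' unlabeled (0) in either map are excluded and their count is reported in
#' `attr(, "ignored")`.
#'
#' @param pred predicted `label_map` (or integer matrix).
#' @param truth reference `label_map` of identical dimensions.
#' @param palette a [tissue_palette()] naming the classes to tally.
#' @param ignore_unlabeled exclude pixels that are 0 in either map.
#' @return a `confusion_matrix`: `C x C` integer matrix with class names
#'   on both dimensions; `sum(cm) + attr(cm, "ignored")` equals the pixel
#'   count.
#' @export
confusion_matrix <- function(pred, truth, palette = default_palette(),
                             ignore_unlabeled = TRUE) {
  if (!all(dim(pred) == dim(truth)))
    stop("`pred` and `truth` dimensions differ", call. = FALSE)
  p <- as.vector(unclass(pred))
  t <- as.vector(unclass(truth))
  keep <- if (ignore_unlabeled) p != 0L & t != 0L else rep(TRUE, length(p))
  C <- nrow(palette)
  counts <- table(factor(t[keep], levels = c(if (!ignore_unlabeled) 0L,
                                             palette$id)),
                  factor(p[keep], levels = c(if (!ignore_unlabeled) 0L,
                                             palette$id)))
  cm <- matrix(as.integer(counts), nrow = nrow(counts))
  nm <- c(if (!ignore_unlabeled) "unlabeled", palette$name)
  dimnames(cm) <- list(truth = nm, pred = nm)
  structure(cm, class = c("confusion_matrix", "matrix", "array"),
            ignored = sum(!keep), classes = palette$id)
}

#' F-score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`, defined as 0 when `p + r = 0`.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return the F-score.
#' @export
f_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class precision, recall and F-score
#'
#' For class `c`: precision is the fraction of pixels predicted `c` that
#' are truly `c` (column-normalized diagonal), recall the fraction of
#' truly-`c` pixels predicted `c` (row-normalized diagonal), and F-score
#' their harmonic mean.  A zero denominator yields 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return a tibble with columns `class`, `precision`, `recall`, `fscore`,
#'   one row per tallied class (the unlabeled row/column, when present, is
#'   not scored).
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  keep <- rownames(cm) != "unlabeled"
  m <- cm[keep, keep, drop = FALSE]
  diagm <- diag(m)
  colsum <- colSums(m)
  rowsum <- rowSums(m)
  if (any(colsum == 0) || any(rowsum == 0))
    warning("class absent from prediction or truth: its metrics are 0",
            call. = FALSE)
  precision <- ifelse(colsum == 0, 0, diagm / colsum)
  recall <- ifelse(rowsum == 0, 0, diagm / rowsum)
  tibble::tibble(class = rownames(m), precision = unname(precision),
                 recall = unname(recall),
                 fscore = unname(f_score(precision, recall)))
}

#' Binary disagreement map
#'
#' 1 where the two label maps differ, 0 where they agree — highlighting,
#' typically, the segment edges where labelings disagree.
#'
#' @param a,b label maps of identical dimensions.
#' @return an integer 0/1 matrix.
#' @export
difference_map <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("dimensions differ", call. = FALSE)
  out <- matrix(as.integer(unclass(a) != unclass(b)), nrow(a), ncol(a))
  out
}

#' Aggregate metrics over several prediction/truth pairs
#'
#' Reports both aggregation rules: *pooled* (sum the confusion matrices,
#' then compute metrics) and *macro* (compute per-pair metrics, then
#' average each class over the pairs where it occurs in the truth).  The
#' two coincide for a single pair but differ when class prevalence varies
#' across images, so both are always emitted.
#'
#' @param pairs list of `list(pred = , truth = )` label-map pairs.
#' @param palette a [tissue_palette()].
#' @param ignore_unlabeled passed to [confusion_matrix()].
#' @param csv optional path; when given, the table is also written as CSV
#'   (values at full precision; round for presentation with
#'   `round(x, 4)`).
#' @return a tibble with columns `class`, `precision`, `recall`, `fscore`,
#'   `aggregation` (`"pooled"` or `"macro"`).
#' @export
metrics_report <- function(pairs, palette = default_palette(),
                           ignore_unlabeled = TRUE, csv = NULL) {
  if (length(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  cms <- lapply(pairs, function(p)
    confusion_matrix(p$pred, p$truth, palette, ignore_unlabeled))
  pooled_cm <- Reduce(`+`, lapply(cms, unclass))
  pooled_cm <- structure(pooled_cm, class = class(cms[[1]]),
                         classes = palette$id)
  pooled <- class_metrics(pooled_cm)
  pooled$aggregation <- "pooled"

  per <- lapply(cms, function(cm) {
    met <- suppressWarnings(class_metrics(cm))
    met$present <- rowSums(cm[rownames(cm) != "unlabeled",
                              rownames(cm) != "unlabeled", drop = FALSE]) > 0
    met
  })
  macro <- tibble::tibble(class = pooled$class,
                          precision = pooled$precision,
                          recall = pooled$recall, fscore = pooled$fscore)
  for (i in seq_len(nrow(macro))) {
    vals <- do.call(rbind, lapply(per, function(m) m[i, ]))
    vals <- vals[vals$present, , drop = FALSE]
    if (nrow(vals) > 0) {  # classes in no truth keep the pooled value
      macro$precision[i] <- mean(vals$precision)
      macro$recall[i] <- mean(vals$recall)
      macro$fscore[i] <- mean(vals$fscore)
    }
  }
  macro$aggregation <- "macro"
  out <- rbind(pooled, macro)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
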