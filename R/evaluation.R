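#' Micro-aggregated set-based confusion counts
#'
#' For each sample, with A the set of manually marked formula names and B
#' the set of algorithm-identified names, the three tallies are summed
#' over samples: f11 = sum |A ∩ B| (names both marked and identified),
#' f12 = sum |B - A| (spurious identifications), f21 = sum |A - B|
#' (missed names).  Counts are aggregated across samples before any
#' ratio is taken (micro-averaging).
#'
#' @param truth named list of character vectors: manual formula names per
#'   sample id.
#' @param predicted named list of character vectors: identified names per
#'   sample id; names must match `truth` exactly as a set.
#' @return object of class `confusion_counts` with fields `f11`, `f12`,
#'   `f21`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (is.null(names(truth)) || is.null(names(predicted)) ||
      !setequal(names(truth), names(predicted)) ||
      anyDuplicated(names(truth)) || anyDuplicated(names(predicted))) {
    stop("truth and predicted must be lists named by the same sample ids",
         call. = FALSE)
  }
  predicted <- predicted[names(truth)]
  f11 <- f12 <- f21 <- 0L
  for (i in seq_along(truth)) {
    a <- unique(truth[[i]]); b <- unique(predicted[[i]])
    inter <- length(intersect(a, b))
    f11 <- f11 + inter
    f12 <- f12 + length(b) - inter
    f21 <- f21 + length(a) - inter
  }
  structure(list(f11 = f11, f12 = f12, f21 = f21),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> f11=%d f12=%d f21=%d\n",
              x$f11, x$f12, x$f21))
  invisible(x)
}

# quiet P/R/F1 with the zero-denominator -> 0 convention
prf_from_counts <- function(f11, f12, f21) {
  p <- if (f11 + f12 > 0) f11 / (f11 + f12) else 0
  r <- if (f11 + f21 > 0) f11 / (f11 + f21) else 0
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall numbers in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = f11/(f11+f12), recall = f11/(f11+f21), F1 their harmonic
#' mean.  A zero denominator yields 0 with a warning.
#'
#' @param counts a [confusion_counts()].
#' @return object of class `siap_metrics`: named list `precision`,
#'   `recall`, `f1`.
#' @export
prf_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$f11 + counts$f12 == 0) {
    warning("no predictions made: precision defined as 0", call. = FALSE)
  }
  if (counts$f11 + counts$f21 == 0) {
    warning("no true labels present: recall defined as 0", call. = FALSE)
  }
  m <- prf_from_counts(counts$f11, counts$f12, counts$f21)
  structure(as.list(m), class = "siap_metrics")
}

#' @export
print.siap_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate an identification model on labelled prescriptions
#'
#' Runs threshold identification on every prescription, accumulates the
#' micro-averaged confusion counts against the manual labels, and returns
#' overall metrics plus a per-sample report of truth, prediction, missed
#' and spurious names.
#'
#' @param model a [weight_model()].
#' @param prescriptions labelled prescriptions.
#' @param formulary a [formulary()].
#' @return list with `metrics` (a `siap_metrics`), `counts`
#'   (a `confusion_counts`) and `report` (data.frame with list columns
#'   `truth`, `predicted`, `missed`, `spurious` keyed by `id`).
#' @export
evaluate_model <- function(model, prescriptions, formulary) {
  unlab <- vapply(prescriptions, function(p) is.null(p$labels), NA)
  if (any(unlab)) {
    stop("evaluation needs labelled prescriptions", call. = FALSE)
  }
  pd <- pair_distances(prescriptions, formulary)
  sim <- pair_similarity(pd, model)
  sim[pd$d5 == 0] <- -Inf
  fnames <- names(formulary$formulas)
  ids <- vapply(prescriptions, `[[`, "", "id")
  pred_sets <- lapply(seq_along(prescriptions), function(i)
    fnames[sim[i, ] >= model$threshold])
  truth_sets <- lapply(prescriptions, `[[`, "labels")
  names(pred_sets) <- names(truth_sets) <- ids
  counts <- confusion_counts(truth_sets, pred_sets)
  report <- data.frame(id = ids, stringsAsFactors = FALSE)
  report$truth <- unname(truth_sets)
  report$predicted <- unname(pred_sets)
  report$missed <- mapply(setdiff, truth_sets, pred_sets, SIMPLIFY = FALSE,
                          USE.NAMES = FALSE)
  report$spurious <- mapply(setdiff, pred_sets, truth_sets,
                            SIMPLIFY = FALSE, USE.NAMES = FALSE)
  list(metrics = suppressWarnings(prf_metrics(counts)), counts = counts,
       report = report)
}
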