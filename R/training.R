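#' Construct a weight model
#'
#' Bundles a scoring variant with its level weights and trained similarity
#' threshold.  Variants: `"ISR"` (baseline; similarity is the full-set
#' overlap ratio d5, weight fixed at 1), `"SIAP-All"` (weighted sum over
#' the level distances d1..d4), `"SIAP+All"` (d1..d5).
#'
#' @param variant one of `"ISR"`, `"SIAP-All"`, `"SIAP+All"`.
#' @param weights named numeric vector of normalized weights over the
#'   variant's active components (names among `d1`..`d5`), summing to 1.
#' @param threshold similarity threshold in \[0, 1\].
#' @param beta0,betas,sds,p_values,beta_primes optional fitted logistic
#'   coefficients, per-predictor standard deviations, Wald p-values and
#'   standardized coefficients, kept for transparency.
#' @param config optional list of training settings.
#' @param seed optional integer seed the model was trained with.
#' @return object of class `weight_model`.
#' @export
weight_model <- function(variant, weights, threshold = 0.5,
                         beta0 = NA_real_, betas = NULL, sds = NULL,
                         p_values = NULL, beta_primes = NULL,
                         config = NULL, seed = NULL) {
  comps <- variant_components(variant)
  weights <- weights[comps]
  if (anyNA(weights)) {
    stop("weights must be named over the active components: ",
         paste(comps, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1)
  structure(
    list(variant = variant, weights = weights, threshold = threshold,
         beta0 = beta0, betas = betas, sds = sds, p_values = p_values,
         beta_primes = beta_primes, config = config, seed = seed),
    class = "weight_model"
  )
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("<weight_model> variant %s, threshold %.3f\n", x$variant,
              x$threshold))
  cat("  weights:",
      paste(sprintf("%s=%.4f", names(x$weights), x$weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Build labelled training records via the ISR gate
#'
#' For every labelled prescription, each candidate formula whose full-set
#' overlap ratio d5 reaches `isr_threshold` contributes one record carrying
#' the full five-component distance vector; the record is a positive
#' example when the candidate's name is among the prescription's manual
#' labels and a negative example otherwise.  This is how the baseline ISR
#' run mines hard negatives for the logistic fit: wrong candidates that
#' nonetheless cover at least half of a standard formula.
#'
#' @param prescriptions list of labelled [prescription()] objects.
#' @param formulary a [formulary()].
#' @param isr_threshold gate on d5 (default 0.5).
#' @return data.frame with columns `prescription_id`, `formula_name`,
#'   `d1`..`d5`, `label` (0/1).
#' @export
build_training_records <- function(prescriptions, formulary,
                                   isr_threshold = 0.5) {
  if (length(prescriptions) == 0L) {
    stop("no prescriptions supplied", call. = FALSE)
  }
  unlab <- vapply(prescriptions, function(p) is.null(p$labels), NA)
  if (any(unlab)) {
    stop("all training prescriptions must carry manual labels",
         call. = FALSE)
  }
  pd <- pair_distances(prescriptions, formulary)
  fnames <- names(formulary$formulas)
  ids <- vapply(prescriptions, `[[`, "", "id")
  keep <- which(pd$d5 >= isr_threshold, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    stop("no (prescription, candidate) pair passes the ISR gate; ",
         "cannot build training records", call. = FALSE)
  }
  i <- keep[, 1L]; j <- keep[, 2L]
  rec <- data.frame(
    prescription_id = ids[i],
    formula_name = fnames[j],
    d1 = pd$d1[keep], d2 = pd$d2[keep], d3 = pd$d3[keep],
    d4 = pd$d4[keep], d5 = pd$d5[keep],
    stringsAsFactors = FALSE
  )
  rec$label <- as.integer(mapply(function(pi, fn)
    fn %in% prescriptions[[pi]]$labels, i, rec$formula_name))
  ord <- order(i, j)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Unregularized logistic fit of match correctness on the distances
#'
#' Maximum-likelihood logistic regression (with intercept) of the binary
#' record label on the chosen distance components; no shrinkage, since the
#' downstream standardized-coefficient weighting presumes plain ML
#' coefficients.  A constant predictor, or one implicated in perfect
#' separation, is dropped with a warning and reported in `dropped`; its
#' standardized coefficient is taken as zero downstream.
#'
#' @param records data.frame from [build_training_records()].
#' @param predictors character vector of predictor columns (default
#'   `d1`..`d5`).
#' @return list with `beta0`, `betas` (named, dropped predictors = 0),
#'   `sds` (sample standard deviation of each predictor, n-1 denominator),
#'   `p_values` (Wald), `dropped` (character).
#' @export
fit_logistic <- function(records, predictors = c("d1", "d2", "d3",
                                                 "d4", "d5")) {
  stopifnot(all(predictors %in% names(records)), "label" %in% names(records))
  if (length(unique(records$label)) < 2L) {
    stop("training records must contain both positive and negative labels",
         call. = FALSE)
  }
  sds <- vapply(records[predictors], stats::sd, 0)
  dropped <- predictors[sds == 0]
  if (length(dropped)) {
    warning("constant predictor(s) dropped from the logistic fit: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  active <- setdiff(predictors, dropped)
  fit <- NULL
  repeat {
    if (length(active) == 0L) {
      stop("no usable predictors remain for the logistic fit",
           call. = FALSE)
    }
    fml <- stats::reformulate(active, response = "label")
    fit <- suppressWarnings(
      stats::glm(fml, data = records, family = stats::binomial())
    )
    cf <- stats::coef(fit)[active]
    if (fit$converged && all(abs(cf) < 20)) break
    worst <- active[which.max(abs(cf))]
    warning("predictor ", worst,
            " dropped (perfect or quasi-perfect separation)",
            call. = FALSE)
    dropped <- c(dropped, worst)
    active <- setdiff(active, worst)
  }
  sm <- stats::coef(summary(fit))
  betas <- stats::setNames(numeric(length(predictors)), predictors)
  pvals <- stats::setNames(rep(NA_real_, length(predictors)), predictors)
  betas[active] <- sm[active, "Estimate"]
  pvals[active] <- sm[active, "Pr(>|z|)"]
  list(beta0 = unname(sm["(Intercept)", "Estimate"]), betas = betas,
       sds = sds, p_values = pvals, dropped = dropped)
}

#' Standardized logistic coefficient
#'
#' Converts a raw logistic coefficient to its standardized form
#' `|beta| * sqrt(3) * S / pi`, where S is the predictor's sample standard
#' deviation; sqrt(3)/pi is the standard deviation of the logistic
#' distribution's inverse scale.  Returns 0 when S is 0.
#'
#' @param beta raw coefficient.
#' @param s predictor standard deviation (>= 0).
#' @return standardized coefficient (>= 0).
#' @export
standardize_coefficient <- function(beta, s) {
  stopifnot(all(s >= 0))
  abs(beta) * sqrt(3) * s / pi
}

#' Normalize standardized coefficients into weights
#'
#' `w_i = beta'_i / sum(beta'_i)`; order is preserved and the result sums
#' to 1.
#'
#' @param beta_primes numeric vector of standardized coefficients (>= 0).
#' @return numeric vector of weights.
#' @export
normalize_weights <- function(beta_primes) {
  stopifnot(all(beta_primes >= 0))
  s <- sum(beta_primes)
  if (s <= 0) {
    stop("degenerate model: all standardized coefficients are zero",
         call. = FALSE)
  }
  beta_primes / s
}

#' Bootstrap grid search for the similarity threshold
#'
#' Sweeps thresholds over a regular grid in \[0, 1\].  At each grid point,
#' `boot_reps` bootstrap resamples of `boot_n` prescriptions (uniform with
#' replacement) are drawn; micro-averaged precision, recall and F1 are
#' computed on each resample and averaged.  The returned threshold
#' maximizes mean F1, ties going to the smallest threshold.  All pairwise
#' similarities are computed once up front, so the sweep itself is pure
#' counting.
#'
#' @param model a [weight_model()] (its current threshold is ignored).
#' @param prescriptions labelled prescriptions.
#' @param formulary a [formulary()].
#' @param grid_step grid spacing (default 0.05).
#' @param boot_n resample size (default 200).
#' @param boot_reps number of resamples per grid point (default 100).
#' @param seed integer seed driving the resampling.
#' @return list with `threshold` (best grid point) and `curve`, a
#'   data.frame of `threshold`, `precision`, `recall`, `f1` (bootstrap
#'   means).
#' @export
train_threshold <- function(model, prescriptions, formulary,
                            grid_step = 0.05, boot_n = 200,
                            boot_reps = 100, seed = NULL) {
  stopifnot(grid_step > 0, grid_step <= 1, boot_n >= 1, boot_reps >= 1)
  unlab <- vapply(prescriptions, function(p) is.null(p$labels), NA)
  if (any(unlab)) {
    stop("threshold training needs labelled prescriptions", call. = FALSE)
  }
  pd <- pair_distances(prescriptions, formulary)
  sim <- pair_similarity(pd, model)
  sim[pd$d5 == 0] <- -Inf   # non-candidates are never predicted
  fnames <- names(formulary$formulas)
  truth <- matrix(FALSE, length(prescriptions), length(fnames))
  for (i in seq_along(prescriptions)) {
    truth[i, match(intersect(prescriptions[[i]]$labels, fnames),
                   fnames)] <- TRUE
  }
  n_labels <- vapply(prescriptions, function(p) length(p$labels), 0L)
  grid <- round(seq(0, 1, by = grid_step), 10)
  if (!is.null(seed)) set.seed(seed)
  np <- length(prescriptions)
  curve <- data.frame(threshold = grid, precision = NA_real_,
                      recall = NA_real_, f1 = NA_real_)
  for (g in seq_along(grid)) {
    pred <- sim >= grid[g]
    f11_p <- rowSums(pred & truth)
    f12_p <- rowSums(pred & !truth)
    f21_p <- n_labels - f11_p
    acc <- matrix(NA_real_, boot_reps, 3L)
    for (r in seq_len(boot_reps)) {
      idx <- sample.int(np, boot_n, replace = TRUE)
      acc[r, ] <- prf_from_counts(sum(f11_p[idx]), sum(f12_p[idx]),
                                  sum(f21_p[idx]))
    }
    curve$precision[g] <- mean(acc[, 1L])
    curve$recall[g] <- mean(acc[, 2L])
    curve$f1[g] <- mean(acc[, 3L])
  }
  list(threshold = grid[which.max(curve$f1)], curve = curve)
}

#' Train a complete identification model
#'
#' The full pipeline: ISR-gated training records, an unregularized
#' logistic fit on the variant's own distance components (d1..d4 for
#' SIAP-All, d1..d5 for SIAP+All), standardization and normalization of
#' the coefficients into weights, then the bootstrap threshold search.
#' Fitting each variant on its own predictors avoids the collinearity
#' between the full-set distance d5 and the level distances it aggregates,
#' which can otherwise flip the sign of the weakest level coefficient.
#' The ISR baseline skips fitting entirely (its weight is fixed at 1 on
#' d5) and only trains a threshold.
#'
#' @inheritParams train_threshold
#' @param variant `"ISR"`, `"SIAP-All"` or `"SIAP+All"`.
#' @param isr_threshold d5 gate for training-record construction.
#' @return a [weight_model()] with trained threshold; the threshold curve
#'   is attached as attribute `"curve"`.
#' @export
train_siap <- function(prescriptions, formulary, variant = "SIAP+All",
                       isr_threshold = 0.5, grid_step = 0.05,
                       boot_n = 200, boot_reps = 100, seed = NULL) {
  comps <- variant_components(variant)
  config <- list(isr_threshold = isr_threshold, grid_step = grid_step,
                 boot_n = boot_n, boot_reps = boot_reps)
  if (variant == "ISR") {
    model <- weight_model("ISR", c(d5 = 1), config = config, seed = seed)
  } else {
    records <- build_training_records(prescriptions, formulary,
                                      isr_threshold = isr_threshold)
    fit <- fit_logistic(records, predictors = comps)
    bp <- standardize_coefficient(fit$betas, fit$sds)
    weights <- stats::setNames(normalize_weights(bp[comps]), comps)
    model <- weight_model(variant, weights, beta0 = fit$beta0,
                          betas = fit$betas, sds = fit$sds,
                          p_values = fit$p_values, beta_primes = bp,
                          config = config, seed = seed)
  }
  tt <- train_threshold(model, prescriptions, formulary,
                        grid_step = grid_step, boot_n = boot_n,
                        boot_reps = boot_reps, seed = seed)
  model$threshold <- tt$threshold
  attr(model, "curve") <- tt$curve
  model
}

#' Read / write a weight model as JSON
#'
#' Numeric fields are written at full precision so a round-trip reproduces
#' identical identification output.
#'
#' @param path file path.
#' @return `read_weight_model()` returns a [weight_model()].
#' @export
read_weight_model <- function(path) {
  doc <- jsonlite::read_json(path)
  num <- function(x) {
    if (is.null(x)) return(NULL)
    vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  }
  weight_model(doc$variant, weights = num(doc$weights),
               threshold = doc$threshold, beta0 = doc$beta0 %||% NA_real_,
               betas = num(doc$betas), sds = num(doc$sds),
               p_values = num(doc$p_values),
               beta_primes = num(doc$beta_primes),
               config = doc$config, seed = doc$seed %||% NULL)
}

#' @rdname read_weight_model
#' @param x a [weight_model()].
#' @export
write_weight_model <- function(x, path) {
  stopifnot(inherits(x, "weight_model"))
  # named numeric vectors are written as JSON objects so names survive
  obj <- function(v) if (is.null(v)) NULL else as.list(v)
  doc <- list(variant = x$variant, weights = obj(x$weights),
              threshold = x$threshold, beta0 = x$beta0,
              betas = obj(x$betas), sds = obj(x$sds),
              p_values = obj(x$p_values),
              beta_primes = obj(x$beta_primes),
              config = x$config, seed = x$seed)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
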