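#' Candidate pooling by set intersection
#'
#' A standard formula enters the candidate pool for a prescription when its
#' full composition set shares at least one drug with the prescription,
#' i.e. |A ∩ B| >= 1 where A is the prescription's drug set and B the
#' formula's full set.
#'
#' @param drugs character vector: the prescription's drug set (symbol A).
#' @param formulary a [formulary()].
#' @return list of `standard_formula` objects (possibly empty), in
#'   formulary order.
#' @export
candidate_set <- function(drugs, formulary) {
  stopifnot(length(drugs) > 0L, inherits(formulary, "formulary"))
  keep <- vapply(formulary$formulas,
                 function(f) any(f$full %in% drugs), NA)
  unname(formulary$formulas[keep])
}

#' Per-level distance coefficient
#'
#' The fraction of a candidate level set covered by the prescription:
#' d = |A ∩ B| / |B|, in \[0, 1\].  An empty level is treated as vacuously
#' satisfied (d = 1): a requirement with no members imposes nothing, and
#' formularies commonly have formulas without an envoy (C4) drug.
#'
#' @param a prescription drug set.
#' @param b candidate level set (any of C1..C5).
#' @return a number in \[0, 1\].
#' @export
level_distance <- function(a, b) {
  if (length(b) == 0L) return(1)
  sum(b %in% a) / length(b)
}

#' Five-level distance vector for a (prescription, formula) pair
#'
#' Applies [level_distance()] to each of the candidate's level sets C1..C4
#' and to its full composition set (the C5 role).
#'
#' @param drugs prescription drug set.
#' @param formula a `standard_formula`.
#' @return named numeric vector `c(d1, d2, d3, d4, d5)`, each in \[0, 1\].
#' @export
distance_vector <- function(drugs, formula) {
  stopifnot(inherits(formula, "standard_formula"))
  d <- c(
    d1 = level_distance(drugs, formula$levels$C1),
    d2 = level_distance(drugs, formula$levels$C2),
    d3 = level_distance(drugs, formula$levels$C3),
    d4 = level_distance(drugs, formula$levels$C4),
    d5 = level_distance(drugs, formula$full)
  )
  d
}

# which distance components a variant uses
variant_components <- function(variant) {
  switch(variant,
         "ISR" = "d5",
         "SIAP-All" = c("d1", "d2", "d3", "d4"),
         "SIAP+All" = c("d1", "d2", "d3", "d4", "d5"),
         stop("unknown variant: ", variant, call. = FALSE))
}

#' Weighted similarity coefficient
#'
#' sim = sum(d_i * w_i) over the variant's active components: d1..d4 for
#' SIAP-All, d1..d5 for SIAP+All.  For the ISR baseline the similarity is
#' the full-set overlap ratio d5 itself.  Because the weights are
#' normalized to sum to one, sim lies in \[0, 1\] and equals 1 exactly when
#' every active component is 1.
#'
#' @param d distance vector from [distance_vector()].
#' @param model a [weight_model()].
#' @return a number in \[0, 1\].
#' @export
similarity <- function(d, model) {
  stopifnot(inherits(model, "weight_model"))
  comps <- variant_components(model$variant)
  w <- model$weights[comps]
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
    stop("model weights are not normalized over the active components",
         call. = FALSE)
  }
  sum(d[comps] * w)
}

#' Identify the standard formulas contained in a prescription
#'
#' Pools candidates by set intersection, scores each with the model's
#' weighted similarity, and returns every candidate whose similarity
#' reaches the model's trained threshold (sim >= threshold), sorted by
#' similarity descending with ties broken by formula name ascending.  The
#' result may be empty; there is no forced top-1 fallback.
#'
#' @param x a [prescription()] or a character vector of drug names.
#' @param formulary a [formulary()].
#' @param model a [weight_model()] with a trained threshold in \[0, 1\].
#' @return data.frame with columns `name`, `sim`, `d1`..`d5`, one row per
#'   matched formula.
#' @export
identify_formulas <- function(x, formulary, model) {
  drugs <- if (inherits(x, "prescription")) x$drugs else
    normalize_drugs(x)
  stopifnot(model$threshold >= 0, model$threshold <= 1)
  cands <- candidate_set(drugs, formulary)
  out <- empty_match_frame()
  if (length(cands) == 0L) return(out)
  rows <- lapply(cands, function(f) {
    d <- distance_vector(drugs, f)
    c(sim = similarity(d, model), d)
  })
  m <- do.call(rbind, rows)
  out <- data.frame(name = vapply(cands, `[[`, "", "name"), m,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$sim >= model$threshold, , drop = FALSE]
  out <- out[order(-out$sim, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_match_frame <- function() {
  data.frame(name = character(), sim = numeric(), d1 = numeric(),
             d2 = numeric(), d3 = numeric(), d4 = numeric(),
             d5 = numeric(), stringsAsFactors = FALSE)
}

# ---- fast path ------------------------------------------------------------
#
# All pairwise (prescription, formula) distances at once via incidence
# matrices over the joint drug vocabulary.  Equivalent to looping
# distance_vector() over every pair (asserted in the test suite); used by
# training and evaluation where the naive loop would dominate runtime.
#
# Returns a list of matrices d1..d5 (n_prescriptions x n_formulas).
pair_distances <- function(prescriptions, formulary) {
  drug_sets <- lapply(prescriptions, `[[`, "drugs")
  vocab <- unique(c(unlist(drug_sets, use.names = FALSE),
                    unlist(lapply(formulary$formulas, `[[`, "full"),
                           use.names = FALSE)))
  np <- length(prescriptions); nf <- length(formulary$formulas)
  A <- matrix(0, np, length(vocab))
  for (i in seq_len(np)) A[i, match(drug_sets[[i]], vocab)] <- 1
  level_mat <- function(sets) {
    B <- matrix(0, length(vocab), nf)
    for (j in seq_len(nf)) {
      s <- sets[[j]]
      if (length(s)) B[match(s, vocab), j] <- 1
    }
    B
  }
  out <- list()
  sets_of <- function(lv) lapply(formulary$formulas,
                                 function(f) f$levels[[lv]])
  all_sets <- c(lapply(c("C1", "C2", "C3", "C4"), sets_of),
                list(lapply(formulary$formulas, `[[`, "full")))
  for (k in 1:5) {
    B <- level_mat(all_sets[[k]])
    sizes <- colSums(B)
    inter <- A %*% B
    d <- sweep(inter, 2, pmax(sizes, 1), "/")
    d[, sizes == 0] <- 1  # vacuously satisfied empty level
    out[[paste0("d", k)]] <- d
  }
  out
}

# similarity matrix (n_prescriptions x n_formulas) from pair distances
pair_similarity <- function(pd, model) {
  comps <- variant_components(model$variant)
  w <- model$weights[comps]
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
    stop("model weights are not normalized over the active components",
         call. = FALSE)
  }
  s <- 0
  for (k in comps) s <- s + pd[[k]] * w[[k]]
  s
}
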