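#' Configuration for the synthetic benchmark generator
#'
#' Describes a synthetic formulary and clinical-prescription benchmark
#' with the statistical shape of a real chief/deputy/assistant/envoy
#' formulary: per-level size distributions targeting medians (C1, C2, C3,
#' C4) = (1, 2, 2, 0) with a total composition around 7-8 drugs, clinical
#' prescriptions built from 1-2 constituent formulas plus noise drugs
#' (overall size around 11-15), and level-graded drug dropout so that
#' chief/deputy drugs are retained more reliably than assistant/envoy
#' drugs.  Drug popularity over the vocabulary is Zipf-skewed and a
#' fraction of formulas are generated as variants of earlier ones, so
#' distinct formulas share drugs and realistic false candidates arise.
#'
#' @param n_formulas number of standard formulas.
#' @param vocabulary_size number of distinct drug names available.
#' @param level_size_probs per-level named probability tables over level
#'   sizes (names are the sizes).
#' @param extra_size_probs probability table over the number of ungraded
#'   drugs added to the full set.
#' @param zipf_exponent skew of drug popularity (0 = uniform).
#' @param variant_fraction fraction of formulas generated by mutating an
#'   earlier formula (creates families of confusable formulas).
#' @param mutation_rate per-drug replacement probability inside a variant.
#' @param n_prescriptions number of clinical prescriptions.
#' @param formulas_per_prescription probability table over the number of
#'   constituent formulas (default: 1 or 2).
#' @param keep_probabilities per-level retention probability of a source
#'   formula's drugs in the prescription (`other` covers ungraded drugs);
#'   at least one chief (C1) drug is always retained so labels stay
#'   recoverable.
#' @param noise_size_probs probability table over the number of extraneous
#'   noise drugs per prescription.
#' @param seed integer seed; all sampling is driven by it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    n_formulas = 376,
    vocabulary_size = 450,
    level_size_probs = list(
      C1 = c("1" = 0.6, "2" = 0.4),
      C2 = c("1" = 0.3, "2" = 0.4, "3" = 0.3),
      C3 = c("1" = 0.3, "2" = 0.3, "3" = 0.1, "4" = 0.3),
      C4 = c("0" = 0.6, "1" = 0.3, "2" = 0.1)),
    extra_size_probs = c("0" = 0.35, "1" = 0.3, "2" = 0.2, "3" = 0.15),
    zipf_exponent = 0.8,
    variant_fraction = 0.3,
    mutation_rate = 0.25,
    n_prescriptions = 1438,
    formulas_per_prescription = c("1" = 0.6, "2" = 0.4),
    keep_probabilities = c(C1 = 0.95, C2 = 0.85, C3 = 0.6, C4 = 0.4,
                           other = 0.4),
    noise_size_probs = c("4" = 0.2, "5" = 0.2, "6" = 0.2, "7" = 0.2,
                         "8" = 0.2),
    seed = NULL) {
  stopifnot(n_formulas >= 1, vocabulary_size >= 10,
            all(keep_probabilities > 0), all(keep_probabilities <= 1),
            variant_fraction >= 0, variant_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (min(as.integer(names(level_size_probs$C1))) < 1) {
    stop("C1 must contain at least one drug", call. = FALSE)
  }
  structure(
    list(n_formulas = n_formulas, vocabulary_size = vocabulary_size,
         level_size_probs = level_size_probs,
         extra_size_probs = extra_size_probs,
         zipf_exponent = zipf_exponent,
         variant_fraction = variant_fraction,
         mutation_rate = mutation_rate,
         n_prescriptions = n_prescriptions,
         formulas_per_prescription = formulas_per_prescription,
         keep_probabilities = keep_probabilities,
         noise_size_probs = noise_size_probs,
         seed = seed),
    class = "generator_config"
  )
}

draw_count <- function(tab) {
  as.integer(sample(names(tab), 1L, prob = tab))
}

gen_vocab <- function(config) {
  vocab <- sprintf("herb%03d", seq_len(config$vocabulary_size))
  weights <- 1 / seq_len(config$vocabulary_size)^config$zipf_exponent
  list(vocab = vocab, weights = weights / sum(weights))
}

check_seed <- function(config) {
  if (is.null(config$seed)) {
    stop("generator_config needs an explicit integer seed", call. = FALSE)
  }
  as.integer(config$seed %% .Machine$integer.max)
}

#' Generate a synthetic standard formulary
#'
#' Samples per-level sizes from the configured distributions and fills
#' them with Zipf-weighted draws from the vocabulary (without replacement
#' within a formula).  A configurable fraction of formulas are variants of
#' earlier ones — the composition is copied and each drug independently
#' replaced with probability `mutation_rate` — emulating the families of
#' closely related classical formulas found in real formularies.  The full
#' set is the union of the levels plus any ungraded extras.
#'
#' @param config a [generator_config()] with a seed.
#' @return a [formulary()] of `n_formulas` valid formulas.
#' @export
generate_formulary <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(check_seed(config))
  vw <- gen_vocab(config)
  max_size <- sum(vapply(config$level_size_probs,
                         function(p) max(as.integer(names(p))), 0L)) +
    max(as.integer(names(config$extra_size_probs)))
  if (max_size > config$vocabulary_size) {
    stop("vocabulary too small for the configured formula sizes",
         call. = FALSE)
  }
  formulas <- vector("list", config$n_formulas)
  for (i in seq_len(config$n_formulas)) {
    nm <- sprintf("F%03d", i)
    if (i > 1L && stats::runif(1) < config$variant_fraction) {
      base <- formulas[[sample.int(i - 1L, 1L)]]
      parts <- c(base$levels, list(extra = setdiff(base$full,
                                                   unlist(base$levels))))
      for (lv in names(parts)) {
        drugs <- parts[[lv]]
        for (k in seq_along(drugs)) {
          if (stats::runif(1) < config$mutation_rate) {
            pool <- setdiff(vw$vocab, unlist(parts, use.names = FALSE))
            drugs[k] <- sample(pool, 1L,
                               prob = vw$weights[match(pool, vw$vocab)])
            parts[[lv]] <- drugs
          }
        }
      }
      # a variant must differ from its base in at least one drug, so no
      # two formulas share an identical composition under different names
      if (setequal(unlist(parts, use.names = FALSE), base$full)) {
        lv <- sample(names(parts)[lengths(parts) > 0], 1L)
        k <- sample.int(length(parts[[lv]]), 1L)
        pool <- setdiff(vw$vocab, unlist(parts, use.names = FALSE))
        parts[[lv]][k] <- sample(pool, 1L,
                                 prob = vw$weights[match(pool, vw$vocab)])
      }
      formulas[[i]] <- standard_formula(
        nm, c1 = parts$C1, c2 = parts$C2, c3 = parts$C3, c4 = parts$C4,
        extra = parts$extra, source = paste("synthetic variant of",
                                            base$name))
    } else {
      sizes <- vapply(config$level_size_probs, draw_count, 0L)
      n_extra <- draw_count(config$extra_size_probs)
      total <- sum(sizes) + n_extra
      drugs <- sample(vw$vocab, total, prob = vw$weights)
      split_at <- cumsum(c(sizes, extra = n_extra))
      take <- function(k) {
        lo <- if (k == 1L) 1L else split_at[k - 1L] + 1L
        if (split_at[k] < lo) character() else drugs[lo:split_at[k]]
      }
      formulas[[i]] <- standard_formula(
        nm, c1 = take(1L), c2 = take(2L), c3 = take(3L), c4 = take(4L),
        extra = take(5L), source = "synthetic")
    }
  }
  formulary(formulas)
}

#' Generate labelled synthetic clinical prescriptions
#'
#' Each prescription draws 1-2 source formulas (without replacement),
#' retains each source drug independently with its level's keep
#' probability — always forcing at least one chief (C1) drug per source so
#' the label remains recoverable — and adds extraneous noise drugs drawn
#' from the same Zipf-weighted vocabulary (so noise can accidentally
#' overlap other formulas).  Labels are the source formula names.
#'
#' @param formulary a [formulary()], typically from [generate_formulary()].
#' @param config the same [generator_config()]; prescription sampling is
#'   seeded independently of the formulary (seed + 1).
#' @return list of labelled [prescription()] objects.
#' @export
generate_prescriptions <- function(formulary, config) {
  stopifnot(inherits(formulary, "formulary"),
            inherits(config, "generator_config"), length(formulary) > 0)
  set.seed((check_seed(config) + 1L) %% .Machine$integer.max)
  vw <- gen_vocab(config)
  kp <- config$keep_probabilities
  out <- vector("list", config$n_prescriptions)
  if (config$n_prescriptions == 0L) return(out)
  for (i in seq_len(config$n_prescriptions)) {
    k <- min(draw_count(config$formulas_per_prescription),
             length(formulary))
    sources <- formulary$formulas[sample.int(length(formulary), k)]
    drugs <- character()
    for (f in sources) {
      kept <- character()
      for (lv in c("C1", "C2", "C3", "C4")) {
        s <- f$levels[[lv]]
        if (length(s)) kept <- c(kept, s[stats::runif(length(s)) < kp[[lv]]])
      }
      extra <- setdiff(f$full, unlist(f$levels))
      if (length(extra)) {
        kept <- c(kept, extra[stats::runif(length(extra)) < kp[["other"]]])
      }
      c1 <- f$levels$C1
      if (length(c1) && !any(c1 %in% kept)) {
        kept <- c(kept, if (length(c1) == 1L) c1 else sample(c1, 1L))
      }
      drugs <- c(drugs, kept)
    }
    n_noise <- draw_count(config$noise_size_probs)
    if (n_noise > 0L) {
      drugs <- c(drugs, sample(vw$vocab, n_noise, prob = vw$weights))
    }
    out[[i]] <- prescription(sprintf("P%05d", i), drugs,
                             labels = names(sources))
  }
  out
}
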