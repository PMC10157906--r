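test_that("training records pair gated candidates with correct labels", {
  fl <- formulary(list(
    standard_formula("F1", c1 = "a", c2 = "b", c3 = "c"),
    standard_formula("F2", c1 = "x", c2 = "y")))
  # exact match of F1, disjoint from F2 -> one positive record
  rec <- build_training_records(
    list(prescription("p1", c("a", "b", "c"), labels = "F1")), fl)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$label, 1L)
  expect_equal(unlist(rec[1, c("d1", "d2", "d3", "d4", "d5")]),
               c(d1 = 1, d2 = 1, d3 = 1, d4 = 1, d5 = 1))

  # half-covered unlabelled formula appears as a negative
  rec2 <- build_training_records(
    list(prescription("p1", c("a", "b", "c", "x"), labels = "F1")), fl)
  expect_equal(rec2$label[rec2$formula_name == "F2"], 0L)
  expect_equal(rec2$d5[rec2$formula_name == "F2"], 0.5)

  expect_error(build_training_records(
    list(prescription("p1", "a")), fl), "labels")
  expect_error(build_training_records(
    list(prescription("p1", "zzz", labels = "F1")), fl), "ISR gate")
})

test_that("training-record construction agrees with a brute-force oracle", {
  cfg <- generator_config(seed = 99, n_formulas = 15, n_prescriptions = 50,
                          vocabulary_size = 60)
  fl <- generate_formulary(cfg)
  ps <- generate_prescriptions(fl, cfg)
  rec <- build_training_records(ps, fl)
  # oracle: nested loops, plain set arithmetic
  n <- 0L; pos <- 0L
  for (p in ps) {
    for (f in fl$formulas) {
      d5 <- length(intersect(p$drugs, f$full)) / length(f$full)
      if (d5 >= 0.5) {
        n <- n + 1L
        if (f$name %in% p$labels) pos <- pos + 1L
      }
    }
  }
  expect_equal(nrow(rec), n)
  expect_equal(sum(rec$label), pos)
})

test_that("logistic fit recovers known coefficients and matches an IRLS oracle", {
  set.seed(123)
  # null data: no predictor effect, coefficients near zero
  n <- 2000
  recs <- data.frame(d1 = runif(n), d2 = runif(n), d3 = runif(n),
                     d4 = runif(n), d5 = runif(n),
                     label = rbinom(n, 1, 0.5))
  fit <- fit_logistic(recs)
  se <- sqrt(diag(stats::vcov(stats::glm(
    label ~ d1 + d2 + d3 + d4 + d5, data = recs,
    family = stats::binomial()))))[-1]
  expect_true(all(abs(fit$betas) < 1.96 * se + 0.5))

  # simulated truth: beta = (2, 1, 0.5, 0.1)
  set.seed(124)
  n <- 5000
  X <- matrix(runif(4 * n), n, 4,
              dimnames = list(NULL, c("d1", "d2", "d3", "d4")))
  truth <- c(2, 1, 0.5, 0.1)
  eta <- -2 + X %*% truth
  recs2 <- data.frame(X, label = rbinom(n, 1, plogis(eta)))
  fit2 <- fit_logistic(recs2, predictors = colnames(X))
  se2 <- sqrt(diag(stats::vcov(stats::glm(
    label ~ ., data = recs2, family = stats::binomial()))))[-1]
  expect_true(all(abs(fit2$betas - truth) < 3 * se2))

  # single-predictor fit cross-checked against independent IRLS
  set.seed(125)
  x <- runif(400)
  y <- rbinom(400, 1, plogis(-1 + 3 * x))
  recs3 <- data.frame(d1 = x, label = y)
  fit3 <- fit_logistic(recs3, predictors = "d1")
  oracle <- bf_logistic(matrix(x, ncol = 1), y)
  expect_equal(unname(c(fit3$beta0, fit3$betas)), oracle,
               tolerance = 1e-6)
})

test_that("degenerate predictors are dropped with a warning", {
  set.seed(126)
  recs <- data.frame(d1 = runif(100), d2 = 1,
                     label = rbinom(100, 1, 0.5))
  expect_warning(fit <- fit_logistic(recs, predictors = c("d1", "d2")),
                 "constant predictor")
  expect_equal(unname(fit$betas["d2"]), 0)
  # perfectly separating predictor gets dropped too
  recs2 <- data.frame(d1 = c(runif(50, 0, 0.4), runif(50, 0.6, 1)),
                      d2 = runif(100),
                      label = rep(0:1, each = 50))
  expect_warning(fit2 <- fit_logistic(recs2, predictors = c("d1", "d2")),
                 "separation")
  expect_equal(unname(fit2$betas["d1"]), 0)
  expect_error(
    suppressWarnings(fit_logistic(data.frame(d1 = 1, label = 0:1),
                                  predictors = "d1")),
    "no usable predictors")
  expect_error(fit_logistic(data.frame(d1 = runif(5), label = 1),
                            predictors = "d1"), "both positive and negative")
})

test_that("coefficient standardization follows the sqrt(3)/pi rule", {
  expect_lt(abs(standardize_coefficient(4.5659, 0.4525) - 1.1391), 5e-5)
  expect_lt(abs(standardize_coefficient(2.8336, 0.3490) - 0.5452), 5e-5)
  expect_equal(standardize_coefficient(-2.8336, 0.3490),
               standardize_coefficient(2.8336, 0.3490))
  expect_equal(standardize_coefficient(5, 0), 0)
})

test_that("weight normalization preserves order, scale-invariance and symmetry", {
  bp <- c(1.1391, 0.8254, 0.5452, 0.0770)
  expect_lt(abs(normalize_weights(bp)[1] - 0.4404), 5e-5)
  expect_lt(abs(normalize_weights(c(bp, 0.7458))[1] - 0.3418), 5e-5)
  expect_equal(normalize_weights(rep(2.7, 4)), rep(0.25, 4))
  set.seed(127)
  for (i in 1:10) {
    v <- runif(5)
    k <- runif(1, 0.1, 50)
    expect_equal(normalize_weights(v * k), normalize_weights(v))
    expect_equal(sum(normalize_weights(v)), 1)
  }
  expect_error(normalize_weights(c(0, 0)), "degenerate")
})

test_that("threshold search maximizes mean bootstrap F1 with smallest-tie rule", {
  # separable toy set: the labelled formula matches at sim 1 while the
  # other formula is a candidate (shares an ungraded drug) scoring sim 0
  fl <- formulary(list(
    standard_formula("F1", c1 = c("a", "b")),
    standard_formula("F2", c1 = "x", c2 = "y", c3 = "z", c4 = "w",
                     extra = "a")))
  ps <- lapply(1:10, function(i)
    prescription(paste0("p", i), c("a", "b"), labels = "F1"))
  m <- equal_model("SIAP-All")
  tt <- train_threshold(m, ps, fl, grid_step = 0.05, boot_n = 5,
                        boot_reps = 10, seed = 1)
  # F1 = 1 on every grid point above 0; smallest such grid point wins
  expect_equal(tt$threshold, 0.05)
  expect_true(all(tt$curve$f1[tt$curve$threshold > 0] == 1))

  # determinism: same seed, bit-identical curve
  tt2 <- train_threshold(m, ps, fl, grid_step = 0.05, boot_n = 5,
                         boot_reps = 10, seed = 1)
  expect_identical(tt, tt2)
})

test_that("threshold search equals an exhaustive same-seed recomputation", {
  cfg <- generator_config(seed = 7, n_formulas = 20, n_prescriptions = 40,
                          vocabulary_size = 80)
  fl <- generate_formulary(cfg)
  ps <- generate_prescriptions(fl, cfg)
  m <- equal_model("SIAP+All")
  grid_step <- 0.25; boot_n <- 20; boot_reps <- 5
  tt <- train_threshold(m, ps, fl, grid_step = grid_step, boot_n = boot_n,
                        boot_reps = boot_reps, seed = 31)

  # oracle: plain loops, identify_formulas per prescription, same RNG use
  grid <- seq(0, 1, by = grid_step)
  truth <- lapply(ps, `[[`, "labels")
  names(truth) <- vapply(ps, `[[`, "", "id")
  m0 <- m
  set.seed(31)
  best <- NULL
  for (t in grid) {
    m0$threshold <- t
    preds <- lapply(ps, function(p) identify_formulas(p, fl, m0)$name)
    names(preds) <- names(truth)
    f1s <- numeric(boot_reps)
    for (r in seq_len(boot_reps)) {
      idx <- sample.int(length(ps), boot_n, replace = TRUE)
      cc <- bf_confusion(truth[idx], preds[idx])
      p <- if (cc$f11 + cc$f12 > 0) cc$f11 / (cc$f11 + cc$f12) else 0
      rc <- if (cc$f11 + cc$f21 > 0) cc$f11 / (cc$f11 + cc$f21) else 0
      f1s[r] <- if (p + rc > 0) 2 * p * rc / (p + rc) else 0
    }
    if (is.null(best) || mean(f1s) > best$f1 + 1e-12) {
      best <- list(t = t, f1 = mean(f1s))
    }
  }
  expect_equal(tt$threshold, best$t)
  g <- match(best$t, tt$curve$threshold)
  expect_equal(tt$curve$f1[g], best$f1)
})

test_that("bootstrap sampling uses named ids consistently in the oracle check", {
  # duplicate indices in a bootstrap resample must each count once per draw;
  # confusion_counts over a resample with repeats is exercised through
  # unique ids in the implementation, so verify a repeated-index resample
  # aggregates counts additively
  truth <- list(p1 = "A", p2 = c("A", "B"))
  pred <- list(p1 = "A", p2 = "B")
  cc <- confusion_counts(truth, pred)
  expect_equal(c(cc$f11, cc$f12, cc$f21), c(2, 0, 1))
})

test_that("full training composes the pipeline per variant", {
  cfg <- generator_config(seed = 3, n_formulas = 40,
                          n_prescriptions = 150, vocabulary_size = 120)
  fl <- generate_formulary(cfg)
  ps <- generate_prescriptions(fl, cfg)

  isr <- train_siap(ps, fl, variant = "ISR", boot_n = 50, boot_reps = 20,
                    seed = 5)
  expect_equal(unname(isr$weights), 1)
  expect_equal(names(isr$weights), "d5")
  expect_null(isr$betas)

  m <- suppressWarnings(train_siap(ps, fl, variant = "SIAP-All",
                                   boot_n = 50, boot_reps = 20, seed = 5))
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  expect_equal(names(m$weights), c("d1", "d2", "d3", "d4"))
  expect_true(m$threshold >= 0 && m$threshold <= 1)
  expect_equal(unname(m$beta_primes),
               unname(standardize_coefficient(m$betas, m$sds)))

  # model JSON round-trip reproduces identical identification output
  path <- withr::local_tempfile(fileext = ".json")
  write_weight_model(m, path)
  m2 <- read_weight_model(path)
  expect_equal(m2$weights, m$weights, tolerance = 0)
  q <- ps[[1]]
  expect_identical(identify_formulas(q, fl, m2),
                   identify_formulas(q, fl, m))
})

test_that("SIAP-All weights equal SIAP+All weights when beta'5 is zero", {
  bp <- c(d1 = 1.2, d2 = 0.8, d3 = 0.5, d4 = 0.1, d5 = 0)
  expect_equal(normalize_weights(bp)[1:4], normalize_weights(bp[1:4]))
})

test_that("level-graded dropout training recovers the importance ordering", {
  cfg <- generator_config(seed = 17, n_prescriptions = 1000)
  fl <- generate_formulary(cfg)
  ps <- generate_prescriptions(fl, cfg)
  rec <- build_training_records(ps, fl)
  fit <- suppressWarnings(
    fit_logistic(rec, predictors = c("d1", "d2", "d3", "d4")))
  w <- normalize_weights(standardize_coefficient(fit$betas, fit$sds))
  expect_true(w[1] > w[2] && w[2] > w[3] && w[3] > w[4])
})
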