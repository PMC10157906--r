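# Independent brute-force oracles: plain nested-loop set arithmetic,
# sharing no code with the package internals they cross-check.

bf_candidates <- function(drugs, fl) {
  out <- character()
  for (f in fl$formulas) {
    if (length(intersect(drugs, f$full)) >= 1) out <- c(out, f$name)
  }
  out
}

bf_distance <- function(drugs, f) {
  one <- function(b) {
    if (length(b) == 0) return(1)
    n <- 0
    for (x in b) if (x %in% drugs) n <- n + 1
    n / length(b)
  }
  c(one(f$levels$C1), one(f$levels$C2), one(f$levels$C3),
    one(f$levels$C4), one(f$full))
}

bf_confusion <- function(truth, predicted) {
  f11 <- f12 <- f21 <- 0
  for (id in names(truth)) {
    a <- unique(truth[[id]]); b <- unique(predicted[[id]])
    for (x in b) if (x %in% a) f11 <- f11 + 1 else f12 <- f12 + 1
    for (x in a) if (!(x %in% b)) f21 <- f21 + 1
  }
  list(f11 = f11, f12 = f12, f21 = f21)
}

# Independent logistic fit by plain Newton-Raphson IRLS (no glm).
bf_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Small random instance builders for property tests.

rand_formulary <- function(n_formulas, vocab, rng_max_level = 3) {
  formulas <- lapply(seq_len(n_formulas), function(i) {
    draw <- function(k) if (k == 0) character() else sample(vocab, k)
    pool <- sample(vocab)
    sizes <- c(sample(1:2, 1), sample(0:rng_max_level, 3, replace = TRUE))
    tot <- sum(sizes)
    extra <- sample(0:2, 1)
    picks <- pool[seq_len(tot + extra)]
    ends <- cumsum(c(sizes, extra))
    part <- function(k) {
      lo <- if (k == 1) 1 else ends[k - 1] + 1
      if (ends[k] < lo) character() else picks[lo:ends[k]]
    }
    standard_formula(sprintf("RF%02d", i), c1 = part(1), c2 = part(2),
                     c3 = part(3), c4 = part(4), extra = part(5))
  })
  formulary(formulas)
}

rand_drugs <- function(vocab, n = sample(2:8, 1)) {
  sample(vocab, min(n, length(vocab)))
}

toy_vocab <- sprintf("h%02d", 1:30)

# tiny deterministic two-formula formulary used across tests
toy_formulary <- function() {
  formulary(list(
    standard_formula("painful-diarrhoea", c1 = "baizhu", c2 = "baishao",
                     c3 = "chenpi", c4 = "fangfeng"),
    standard_formula("magnolia-warming", c1 = "houpo", c2 = "caodoukou",
                     c3 = c("chenpi", "fuling", "muxiang", "shengjiang"),
                     c4 = "zhigancao")
  ))
}

# formulary of n formulas over pairwise-disjoint 8-drug blocks
disjoint_formulary <- function(n) {
  formulary(lapply(seq_len(n), function(i) {
    v <- sprintf("herb%03d", ((i - 1) * 8 + 1):(i * 8))
    standard_formula(sprintf("D%02d", i), c1 = v[1], c2 = v[2:3],
                     c3 = v[4:6], c4 = v[7], extra = v[8])
  }))
}

equal_model <- function(variant, threshold = 0.5) {
  comps <- switch(variant, "ISR" = "d5",
                  "SIAP-All" = c("d1", "d2", "d3", "d4"),
                  "SIAP+All" = c("d1", "d2", "d3", "d4", "d5"))
  weight_model(variant,
               stats::setNames(rep(1 / length(comps), length(comps)),
                               comps),
               threshold = threshold)
}
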