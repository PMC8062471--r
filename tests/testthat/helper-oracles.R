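# Independent oracles, written as direct transcriptions of the model
# equations with their own arithmetic; they deliberately avoid the package's
# update/weighting/choice functions so that agreement is informative.

# Naive trial-by-trial log-likelihood of any of the eight models.
naive_loglik <- function(trials, model, par, reset_blocks = TRUE, S0 = 1) {
  weighted <- grepl("w$", model)
  base <- sub("w$", "", model)
  gamma <- if (weighted) par[["gamma"]] else 1
  beta <- par[["beta"]]
  w <- function(p) min(max(gamma * (p - 0.5) + 0.5, 0), 1)
  n <- nrow(trials)
  pA <- 0.5
  S <- S0
  cur <- trials$block[1]
  ll <- 0
  for (t in seq_len(n)) {
    if (reset_blocks && trials$block[t] != cur) {
      cur <- trials$block[t]; pA <- 0.5; S <- S0
    }
    ch <- trials$chosen[t]
    if (is.na(ch)) next
    qA <- trials$mag_A[t] * w(pA)
    qB <- trials$mag_B[t] * w(1 - pA)
    # log(1/(1+e^(-x))) = -log(1+e^(-x)), with x signed toward the choice
    x <- beta * (qA - qB)
    if (ch == "B") x <- -x
    ll <- ll - log1p(exp(-x))
    pc <- if (ch == "A") pA else 1 - pA
    rc <- if (trials$rewarded[t] == ch) 1 else 0
    delta <- rc - pc
    if (base == "s1") {
      a <- par[["alpha"]]
    } else if (base == "s2") {
      a <- if (delta > 0) par[["alpha_pos"]] else par[["alpha_neg"]]
    } else if (base == "d1") {
      S <- (1 - par[["mu"]]) * S + par[["mu"]] * abs(delta)
      a <- min(par[["kappa"]] * S, 1)
    } else {
      a <- if (t <= n %/% 2) par[["alpha1"]] else par[["alpha2"]]
    }
    pc <- pc + a * delta
    pA <- if (ch == "A") pc else 1 - pc
  }
  ll
}

# Brute-force proportion-correct: per-trial expected-value comparison.
naive_prop_correct <- function(trials, p_high = 0.75) {
  n_ok <- 0; n_correct <- 0
  for (t in seq_len(nrow(trials))) {
    if (!trials$response_made[t] || is.na(trials$chosen[t])) next
    pA <- if (trials$high_prob_option[t] == "A") p_high else 1 - p_high
    evA <- pA * trials$mag_A[t]
    evB <- (1 - pA) * trials$mag_B[t]
    if (evA == evB) next
    n_ok <- n_ok + 1
    better <- if (evA > evB) "A" else "B"
    if (trials$chosen[t] == better) n_correct <- n_correct + 1
  }
  if (n_ok == 0) NA_real_ else n_correct / n_ok
}

# Textbook balanced two-way ANOVA sums of squares (equal cell sizes).
hand_anova_2x2 <- function(y, f1, f2) {
  grand <- mean(y)
  n <- length(y)
  m1 <- tapply(y, f1, mean); n1 <- tapply(y, f1, length)
  m2 <- tapply(y, f2, mean); n2 <- tapply(y, f2, length)
  cellm <- tapply(y, interaction(f1, f2), mean)
  celln <- tapply(y, interaction(f1, f2), length)
  ss1 <- sum(n1 * (m1 - grand)^2)
  ss2 <- sum(n2 * (m2 - grand)^2)
  sscells <- sum(celln * (cellm - grand)^2)
  ss12 <- sscells - ss1 - ss2
  sse <- sum((y - ave(y, interaction(f1, f2)))^2)
  dfe <- n - length(cellm)
  list(
    F1 = (ss1 / (length(m1) - 1)) / (sse / dfe),
    F2 = (ss2 / (length(m2) - 1)) / (sse / dfe),
    F12 = (ss12 / ((length(m1) - 1) * (length(m2) - 1))) / (sse / dfe),
    df_error = dfe)
}

# Random completed trial log (not produced by the task module) for
# likelihood cross-checks.
random_trials <- function(n = 60, block_length = 20, seed = NULL,
                          p_none = 0) {
  if (!is.null(seed)) set.seed(seed)
  block <- rep(seq_len(n / block_length), each = block_length)
  high <- sample(c("A", "B"), max(block), replace = TRUE)[block]
  mag_A <- sample(1:99, n, replace = TRUE)
  rewarded <- ifelse(runif(n) < 0.75, high, ifelse(high == "A", "B", "A"))
  chosen <- sample(c("A", "B"), n, replace = TRUE)
  chosen[runif(n) < p_none] <- NA
  tibble::tibble(trial = 1:n, block = block, high_prob_option = high,
                 mag_A = as.integer(mag_A), mag_B = 100L - as.integer(mag_A),
                 chosen = chosen, rewarded = rewarded,
                 response_made = !is.na(chosen))
}

# Random valid parameter vector for a model.
random_params <- function(model) {
  nm <- rl_par_names(model)
  vals <- lapply(nm, function(p) switch(p,
    alpha = , alpha_pos = , alpha_neg = , alpha1 = , alpha2 =
      runif(1, 0.02, 0.6),
    mu = runif(1, 0.1, 0.9),
    kappa = runif(1, 0.1, 0.9),
    gamma = runif(1, 0.4, 2.5),
    beta = runif(1, 0.01, 0.4)))
  setNames(unlist(vals), nm)
}
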