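# Independent trial-by-trial oracle for the PVL-Delta recursions, coded
# naively and kept free of any package internals: utilities, delta-rule
# updates and softmax probabilities are recomputed step by step.

oracle_utility <- function(x, A, w) {
  if (x == 0) return(0)
  if (x > 0) x^A else -w * (abs(x)^A)
}

oracle_softmax <- function(ev, c) {
  theta <- 3^c - 1
  e <- exp(theta * ev - max(theta * ev))
  e / sum(e)
}

# full one-step-ahead probability matrix and log-likelihood for a choice
# sequence (deck 1-4, net outcomes already divided by the scale constant)
oracle_pvl <- function(deck, net_scaled, A, w, a, c) {
  T <- length(deck)
  ev <- rep(0, 4)
  P <- matrix(NA_real_, T, 4)
  ll <- 0
  theta <- 3^c - 1
  for (t in seq_len(T)) {
    pr <- oracle_softmax(ev, c)
    P[t, ] <- pr
    # log probability written in log-sum-exp form so the oracle stays finite
    # wherever the model likelihood is
    s <- theta * ev - max(theta * ev)
    ll <- ll + s[deck[t]] - log(sum(exp(s)))
    u <- oracle_utility(net_scaled[t], A, w)
    ev[deck[t]] <- ev[deck[t]] + a * (u - ev[deck[t]])
  }
  list(probs = P, loglik = ll)
}

# random in-range parameter vector
random_params <- function() {
  pvl_params(A = runif(1, 0.05, 0.95), w = runif(1, 0.1, 4.5),
             a = runif(1, 0.05, 0.95), c = runif(1, 0.1, 3))
}

# small hand-rolled participant with an arbitrary but valid payoff pattern
random_participant <- function(n_trials = 20, id = "x") {
  deck <- sample(1:4, n_trials, replace = TRUE)
  reward <- ifelse(deck <= 2, 100, 50)
  loss <- -sample(c(0, 0, 50, 250, 1250), n_trials, replace = TRUE)
  participant_data(id, deck, reward, loss)
}
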