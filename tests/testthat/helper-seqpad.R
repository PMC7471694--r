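# shared fixtures and independent oracles, all built in code

tiny_alphabet <- function() build_alphabet(c("A", "B", "C"), pad = "0")

# brute-force subsequence check: is `sub` a subsequence of `s`?
is_subsequence <- function(sub, s) {
  i <- 1L
  a <- strsplit(sub, "")[[1]]
  b <- strsplit(s, "")[[1]]
  for (ch in b) {
    if (i <= length(a) && ch == a[i]) i <- i + 1L
  }
  i > length(a)
}

# pairwise-enumeration AUC oracle: P(score_pos > score_neg) + 0.5 ties
auc_oracle <- function(truth, prob) {
  pos <- prob[truth == 1]
  neg <- prob[truth == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (no zero differences, no ties in |d|)
wilcoxon_exact_oracle <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# small simulated labelled dataset with short sequences
toy_samples <- function(n = 300, seed = 42, length_min = 30, length_max = 100,
                        motif_policy = "n_term", multi_ec_rate = 0.01) {
  sim <- simulate_dataset(sim_config(
    n = n, length_min = length_min, length_max = length_max,
    motif_policy = motif_policy, multi_ec_rate = multi_ec_rate, seed = seed
  ))
  simulated_samples(sim)
}

# desk-scale training configuration: the step size compensates for the
# short schedule (see the methods vignette)
desk_config <- function(epochs = 10, seed = 1) {
  training_config(epochs = epochs, batch_size = 16, learning_rate = 1e-2, seed = seed)
}

random_residue_string <- function(len, residues = aa_residues()) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}
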