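# Shared fixture builders and independent scalar reference implementations
# used as oracles across the test files.

tiny_panel <- function(n = 3) {
  gene_panel(paste0("GENE", seq_len(n)),
             intolerance = seq(-1, 1, length.out = n),
             pubweight = seq_len(n) * 2)
}

# deterministic small cohort with planted signal, for model/federated tests
tiny_cohort <- function(n_cases = 10, n_controls = 10, n_genes = 8,
                        effect = 3, seed = 1, center_id = "T") {
  panel <- generate_panel(panel_spec(n_genes), seed)
  sp <- center_spec(center_id, n_cases, n_controls,
                    signal_genes = seq_len(min(3, n_genes)),
                    effect_size = effect, seed = seed)
  generate_center_cohort(sp, panel)
}

random_updates <- function(k, len, seed) {
  with_seed <- function(s, e) {
    set.seed(s); e
  }
  set.seed(seed)
  lapply(seq_len(k), function(i)
    client_update(rnorm(len), sample.int(20, 1)))
}

# scalar double-loop reference for the weighted mean
ref_weighted_mean <- function(updates) {
  len <- length(updates[[1]]$parameters)
  tot <- sum(vapply(updates, `[[`, 0L, "n_samples"))
  out <- numeric(len)
  for (j in seq_len(len)) {
    acc <- 0
    for (u in updates) acc <- acc + u$n_samples / tot * u$parameters[j]
    out[j] <- acc
  }
  out
}

# per-coordinate scalar references for the server optimizers
ref_fedavgm <- function(buffer, prev, wm, beta, eta) {
  len <- length(prev)
  nb <- numeric(len); ng <- numeric(len)
  for (j in seq_len(len)) {
    d <- wm[j] - prev[j]
    nb[j] <- beta * buffer[j] + d
    ng[j] <- prev[j] + eta * nb[j]
  }
  list(global = ng, buffer = nb)
}

ref_fedopt <- function(m, v, prev, wm, variant, beta1, beta2, eta, tau) {
  len <- length(prev)
  nm <- numeric(len); nv <- numeric(len); ng <- numeric(len)
  for (j in seq_len(len)) {
    d <- wm[j] - prev[j]
    nm[j] <- beta1 * m[j] + (1 - beta1) * d
    nv[j] <- switch(variant,
      adagrad = v[j] + d^2,
      adam = beta2 * v[j] + (1 - beta2) * d^2,
      yogi = v[j] - (1 - beta2) * d^2 * sign(v[j] - d^2))
    ng[j] <- prev[j] + eta * nm[j] / (sqrt(nv[j]) + tau)
  }
  list(global = ng, m = nm, v = nv)
}

# O(n^2) pair-counting AUC oracle (ties get half credit)
ref_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

rel_err <- function(a, b) {
  d <- abs(a - b)
  s <- pmax(abs(a), abs(b))
  ifelse(s == 0, d, d / s)
}
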