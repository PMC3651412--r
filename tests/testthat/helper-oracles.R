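# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, plain loops, and
# closed forms.

# --- Boolean algebra -------------------------------------------------------

# dependence test via explicit pairing of states that differ in one input
oracle_depends_on_all <- function(outputs) {
  K <- round(log2(length(outputs)))
  states <- as.matrix(expand.grid(rep(list(0:1), K)))
  for (k in seq_len(K)) {
    flipped <- states
    flipped[, k] <- 1L - flipped[, k]
    idx <- function(sm) sm %*% 2^(seq_len(K) - 1) + 1
    if (any(outputs[idx(states)] != outputs[idx(flipped)])) next
    return(FALSE)
  }
  TRUE
}

# all non-degenerate truth tables on K inputs, as a list of 0/1 vectors
oracle_enumerate <- function(K) {
  n <- 2^K
  tables <- as.matrix(expand.grid(rep(list(0:1), n)))
  keep <- apply(tables, 1, oracle_depends_on_all)
  lapply(which(keep), function(r) as.integer(tables[r, ]))
}

# restriction-set semantics of marker removal, by direct filtering
oracle_remove <- function(outputs, position) {
  K <- round(log2(length(outputs)))
  Kr <- K - 1
  full_index <- function(bits) sum(bits * 2^(seq_along(bits) - 1)) + 1
  candidates <- oracle_enumerate(Kr)
  Filter(function(g) {
    for (u in 0:(2^Kr - 1)) {
      bits <- as.integer(intToBits(u))[seq_len(max(Kr, 1))][seq_len(Kr)]
      opts <- c(outputs[full_index(append(bits, 0L, after = position - 1))],
                outputs[full_index(append(bits, 1L, after = position - 1))])
      if (!(g[u + 1] %in% opts)) return(FALSE)
    }
    TRUE
  }, candidates)
}

tt_string <- function(fn) paste(fn$outputs, collapse = "")

# --- Response model --------------------------------------------------------

# Pr(at least one response) by exhaustive enumeration of all outcome
# combinations of the chosen drugs
oracle_at_least_one <- function(p) {
  if (!length(p)) return(0)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), length(p))))
  probs <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= 1])
}

# --- Exhaustive assignment search ------------------------------------------

# every protocol a single drug can take under k_max = 1 (empty, or one
# marker with one of the two 1-input rules)
oracle_protocol_space_k1 <- function(m) {
  out <- list(drug_protocol())
  for (mk in seq_len(m)) {
    for (fn in enumerate_functions(1)) {
      out[[length(out) + 1]] <- drug_protocol(mk, fn)
    }
  }
  out
}

# global optimum O over the full cross-product of per-drug protocols
oracle_best_assignment <- function(coh, responses, c, min_group_size = 1) {
  d <- ncol(responses)
  space <- oracle_protocol_space_k1(coh$m)
  grid <- expand.grid(rep(list(seq_along(space)), d))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    protocols <- lapply(unlist(grid[r, ]), function(i) space[[i]])
    O <- evaluate_assignment(coh, responses, protocols, c,
                             min_group_size = min_group_size)$O
    if (O > best) best <- O
  }
  best
}

# --- Imputation ------------------------------------------------------------

# plain triple-loop implementation of the doubly-weighted average
oracle_drug_dist <- function(mat, j, l) {
  keep <- !is.na(mat[, j]) & !is.na(mat[, l])
  if (!any(keep)) return(NA_real_)
  mean((mat[keep, j] - mat[keep, l])^2)
}

oracle_sample_dist <- function(mat, i, k, j, alpha_drug) {
  num <- den <- 0
  for (l in seq_len(ncol(mat))) {
    if (l == j || is.na(mat[i, l]) || is.na(mat[k, l])) next
    djl <- oracle_drug_dist(mat, j, l)
    if (is.na(djl)) next
    w <- exp(-alpha_drug * djl)
    num <- num + w * (mat[i, l] - mat[k, l])^2
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}

oracle_impute_cell <- function(mat, i, j, alpha_sample, alpha_drug) {
  num <- den <- 0
  for (k in seq_len(nrow(mat))) {
    if (k == i || is.na(mat[k, j])) next
    dikj <- oracle_sample_dist(mat, i, k, j, alpha_drug)
    if (is.na(dikj)) next
    w <- exp(-alpha_sample * dikj)
    num <- num + w * mat[k, j]
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}

# --- Shared fixtures -------------------------------------------------------

# cohort + response matrix in which each drug responds (p ~ 1) only in its
# own marker-positive group; everything analytic apart from IC50 noise
planted_instance <- function(n_samples, n_markers, n_drugs, seed,
                             shift = -12, background = 6, noise_sd = 0.5,
                             sigma = 1, prevalence = 0.5) {
  coh <- generate_cohort(n_samples, n_markers, prevalence = prevalence,
                         seed = seed)
  eff <- planted_effects(drug = seq_len(n_drugs),
                         marker = seq_len(n_drugs), shift = shift)
  sim <- generate_ic50(coh, n_drugs, eff, background_mean = background,
                       noise_sd = noise_sd, missing_frac = 0,
                       seed = seed + 1000L)
  list(cohort = coh,
       responses = build_response_matrix(sim$complete, h = 2, sigma = sigma),
       effects = eff, sim = sim)
}

# tissue-like recovery fixture: three mutually exclusive covering markers
# (a tissue partition) plus iid noise markers; drug j responds only in
# tissue j, so the planted catalog is the strict optimum of the estimated
# overall response rate
recovery_instance <- function(n_samples, seed) {
  set.seed(seed)
  tissue <- sample.int(3, n_samples, replace = TRUE)
  profiles <- cbind(tissue == 1, tissue == 2, tissue == 3,
                    matrix(rbinom(2 * n_samples, 1, 0.3), n_samples, 2)) * 1L
  coh <- cohort(profiles)
  eff <- planted_effects(drug = 1:3, marker = 1:3, shift = -12)
  sim <- generate_ic50(coh, 3, eff, background_mean = 6, noise_sd = 0.5,
                       missing_frac = 0, seed = seed + 1000L)
  list(cohort = coh,
       responses = build_response_matrix(sim$complete, h = 2, sigma = 1),
       effects = eff)
}

random_protocols <- function(m, d, k_max = 1) {
  lapply(seq_len(d), function(j) {
    K <- sample(0:k_max, 1)
    if (K == 0) return(drug_protocol())
    fns <- enumerate_functions(K)
    drug_protocol(sample.int(m, K), fns[[sample.int(length(fns), 1)]])
  })
}
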