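# Response model: combination response probabilities, the response-by-marker
# approximation, the top-c treatment selection rule, and the overall
# response rate O.
#
# The probability that a patient responds to a combination of independent
# drugs is P_i = 1 - prod_j (1 - p_ij)^e_ij; pairwise interaction terms J_jk
# enter as P_i = 1 - exp(sum_j e_ij log(1-p_ij) + sum_{j<k} e_ij e_ik J_jk),
# with J < 0 synergy and J > 0 antagonism. Because per-patient response
# probabilities are unobservable in the clinic, p_ij is replaced by the
# group rate q(j, s): the mean response among patients sharing the same
# status on the drug's assigned markers.

#' Index of a patient group given marker statuses
#'
#' Groups are enumerated as `s = sum_k x_k 2^(k-1)` over the drug's assigned
#' markers; the empty marker list maps every sample to group 0.
#'
#' @param status 0/1 vector (possibly empty).
#' @return Integer in `[0, 2^K - 1]`.
#' @export
group_index <- function(status) {
  if (length(status) == 0L) return(0L)
  if (anyNA(status) || !all(status %in% c(0, 1))) {
    stop("marker status must be binary 0/1", call. = FALSE)
  }
  as.integer(sum(status * 2^(seq_along(status) - 1L)))
}

#' Construct a pairwise drug-interaction model
#'
#' @param J symmetric d x d matrix with zero diagonal; `J[j,k] < 0` raises
#'   the combination response above independence (synergy), `J[j,k] > 0`
#'   lowers it (antagonism).
#' @return An object of class `interaction_model`.
#' @export
interaction_model <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("J must be square", call. = FALSE)
  if (anyNA(J)) stop("J must be finite", call. = FALSE)
  if (!isTRUE(all.equal(J, t(J)))) stop("J must be symmetric", call. = FALSE)
  if (any(diag(J) != 0)) stop("J must have a zero diagonal", call. = FALSE)
  structure(list(J = J, d = nrow(J)), class = "interaction_model")
}

as_J_matrix <- function(interactions, d) {
  if (is.null(interactions)) return(NULL)
  J <- if (inherits(interactions, "interaction_model")) interactions$J
       else interaction_model(interactions)$J
  if (nrow(J) != d) stop("interaction matrix dimension must equal drug count",
                         call. = FALSE)
  J
}

# Per-drug columns of the suggestion and by-marker response matrices.
# Returns suggested (logical s), pbar (numeric s), q and n indexed by group,
# and the per-sample group index. `p_col` is the drug's column of the
# response matrix.
drug_response_columns <- function(profiles, p_col, protocol, min_group_size) {
  s <- nrow(profiles)
  K <- length(protocol$markers)
  if (K == 0L) {
    return(list(suggested = rep(FALSE, s), pbar = rep(0, s),
                q = numeric(0), n = integer(0), svec = NULL))
  }
  X <- profiles[, protocol$markers, drop = FALSE]
  svec <- as.integer(X %*% 2^(seq_len(K) - 1L))
  ngroups <- 2L^K
  n <- tabulate(svec + 1L, nbins = ngroups)
  q <- numeric(ngroups)
  rs <- rowsum(p_col, svec)
  idx <- as.integer(rownames(rs)) + 1L
  q[idx] <- rs[, 1L] / n[idx]
  q[n < min_group_size] <- 0
  list(suggested = protocol$fn$outputs[svec + 1L] == 1L,
       pbar = q[svec + 1L], q = q, n = n, svec = svec)
}

#' Estimate by-marker group response rates for every drug
#'
#' For each drug, samples are partitioned by the joint status of the drug's
#' assigned markers and the group rate `q(j, s)` is the mean response
#' probability within the group. Groups smaller than `min_group_size` are
#' shrunk to `q = 0` to avoid overfitting to tiny strata.
#'
#' @param x a `cohort`.
#' @param responses samples-by-drugs matrix of response probabilities.
#' @param protocols list of `drug_protocol`, one per drug (response column).
#' @param min_group_size smallest group size trusted for estimation
#'   (default 10).
#' @return An object of class `group_rate_table`: per drug the marker-list
#'   snapshot, `q` and group sizes `n` indexed by group `s + 1`.
#' @export
estimate_group_rates <- function(x, responses, protocols, min_group_size = 10L) {
  stopifnot(inherits(x, "cohort"))
  responses <- as.matrix(responses)
  if (nrow(responses) != x$s) stop("response rows must match cohort samples",
                                   call. = FALSE)
  if (length(protocols) != ncol(responses)) {
    stop("one protocol per drug (response column) required", call. = FALSE)
  }
  drugs <- lapply(seq_along(protocols), function(j) {
    cols <- drug_response_columns(x$profiles, responses[, j], protocols[[j]],
                                  min_group_size)
    list(markers = protocols[[j]]$markers, q = cols$q, n = cols$n)
  })
  structure(list(drugs = drugs, min_group_size = as.integer(min_group_size),
                 s = x$s),
            class = "group_rate_table")
}

#' Response-by-marker approximation for one sample and drug
#'
#' Looks up the group rate for the sample's status on the drug's assigned
#' markers: `q(j, s_j(X_i))`.
#'
#' @param table a `group_rate_table`.
#' @param profile full binary marker profile of the sample.
#' @param j drug index.
#' @return Estimated response probability.
#' @export
marker_response <- function(table, profile, j) {
  stopifnot(inherits(table, "group_rate_table"))
  entry <- table$drugs[[j]]
  if (length(entry$markers) == 0L) {
    stop("drug has no markers assigned; no by-marker estimate exists",
         call. = FALSE)
  }
  entry$q[group_index(profile[entry$markers]) + 1L]
}

# suggestion and pbar matrices (s x d) for a full protocol list
build_assignment_matrices <- function(x, responses, protocols, min_group_size) {
  s <- x$s
  d <- length(protocols)
  sug <- matrix(FALSE, s, d)
  pbar <- matrix(0, s, d)
  for (j in seq_len(d)) {
    cols <- drug_response_columns(x$profiles, responses[, j], protocols[[j]],
                                  min_group_size)
    sug[, j] <- cols$suggested
    pbar[, j] <- cols$pbar
  }
  list(sug = sug, pbar = pbar)
}

#' Select each sample's personalized combination (top-c rule)
#'
#' Among the drugs suggested for a sample, the `c` with the highest
#' by-marker response estimates are chosen (ties broken by lower drug
#' index); samples with fewer suggestions take all of them, samples with
#' none stay untreated.
#'
#' @param x a `cohort`.
#' @param protocols list of `drug_protocol`.
#' @param table a `group_rate_table` estimated on the same cohort with the
#'   same protocols.
#' @param c maximum combination size.
#' @return An object of class `treatment_plan`: binary inclusion matrix `e`
#'   (s x d), the per-sample chosen drug indices, and `c`.
#' @export
select_treatment <- function(x, protocols, table, c) {
  stopifnot(inherits(x, "cohort"), inherits(table, "group_rate_table"))
  if (length(c) != 1L || is.na(c) || c < 1L) {
    stop("c must be a positive integer", call. = FALSE)
  }
  d <- length(protocols)
  sug <- matrix(FALSE, x$s, d)
  pbar <- matrix(0, x$s, d)
  for (j in seq_len(d)) {
    prot <- protocols[[j]]
    if (length(prot$markers) == 0L) next
    X <- x$profiles[, prot$markers, drop = FALSE]
    svec <- as.integer(X %*% 2^(seq_along(prot$markers) - 1L))
    sug[, j] <- prot$fn$outputs[svec + 1L] == 1L
    pbar[, j] <- table$drugs[[j]]$q[svec + 1L]
  }
  e <- matrix(0L, x$s, d, dimnames = list(x$sample_ids, NULL))
  chosen <- vector("list", x$s)
  for (i in seq_len(x$s)) {
    cand <- which(sug[i, ])
    if (!length(cand)) { chosen[[i]] <- integer(0); next }
    ord <- cand[order(-pbar[i, cand])]  # stable order: ties -> lower index
    pick <- ord[seq_len(min(c, length(ord)))]
    e[i, pick] <- 1L
    chosen[[i]] <- sort(pick)
  }
  structure(list(e = e, chosen = chosen, c = as.integer(c),
                 pbar = pbar, sug = sug),
            class = "treatment_plan")
}

#' Probability of response to a drug combination
#'
#' Without interactions, the probability of responding to at least one of
#' the independent chosen drugs; with a pairwise interaction matrix `J`, the
#' log-linear correction `P = 1 - exp(sum e log(1-p) + sum_{j<k} e_j e_k
#' J_jk)` clamped to \[0,1\]. Any chosen drug with `p = 1` forces `P = 1`.
#'
#' @param p_row response probabilities for one sample (length d).
#' @param e_row 0/1 inclusion vector.
#' @param interactions optional `interaction_model` or symmetric matrix.
#' @return Probability in \[0,1\]; 0 for an empty combination.
#' @export
combination_response <- function(p_row, e_row, interactions = NULL) {
  if (anyNA(p_row) || any(p_row < 0 | p_row > 1)) {
    stop("response probabilities must lie in [0,1]", call. = FALSE)
  }
  sel <- which(e_row == 1)
  if (!length(sel)) return(0)
  p <- p_row[sel]
  if (is.null(interactions)) return(1 - prod(1 - p))
  J <- as_J_matrix(interactions, length(p_row))
  lg <- sum(log1p(-p))  # -Inf when some p = 1 -> P = 1
  jsum <- 0
  if (length(sel) > 1L) {
    pairs <- utils::combn(sel, 2L)
    jsum <- sum(J[cbind(pairs[1L, ], pairs[2L, ])])
  }
  min(max(1 - exp(lg + jsum), 0), 1)
}

#' Overall response rate of a cohort
#'
#' @param P vector of per-sample combination response probabilities.
#' @return Their arithmetic mean.
#' @export
overall_response <- function(P) {
  if (length(P) == 0L) stop("no samples", call. = FALSE)
  if (anyNA(P) || any(P < 0 | P > 1)) {
    stop("response probabilities must lie in [0,1]", call. = FALSE)
  }
  mean(P)
}

#' Evaluate a full marker-to-drug assignment
#'
#' Composes group-rate estimation, top-c treatment selection and the
#' combination response model (using the by-marker estimates, which is all
#' the optimizer is allowed to see), returning the overall response rate
#' with the plan and rate table. Deterministic given its inputs.
#'
#' @inheritParams estimate_group_rates
#' @param c maximum combination size.
#' @param interactions optional `interaction_model` or matrix.
#' @return An object of class `assignment_eval`: `O`, `P` (per sample),
#'   `plan`, `table`, `protocols`, `c`.
#' @export
evaluate_assignment <- function(x, responses, protocols, c,
                                interactions = NULL, min_group_size = 10L) {
  responses <- as.matrix(responses)
  table <- estimate_group_rates(x, responses, protocols, min_group_size)
  plan <- select_treatment(x, protocols, table, c)
  J <- as_J_matrix(interactions, length(protocols))
  P <- vapply(seq_len(x$s), function(i) {
    combination_response(plan$pbar[i, ], plan$e[i, ], if (is.null(J)) NULL else J)
  }, numeric(1))
  plan$P <- P
  structure(list(O = overall_response(P), P = P, plan = plan, table = table,
                 protocols = protocols, c = plan$c,
                 min_group_size = as.integer(min_group_size)),
            class = "assignment_eval")
}

#' @export
print.assignment_eval <- function(x, ...) {
  treated <- sum(lengths(x$plan$chosen) > 0)
  cat(sprintf("Assignment evaluation: O = %.4f (c = %d)\n", x$O, x$c))
  cat(sprintf("  %d/%d samples treated; %d drugs used\n",
              treated, length(x$P), sum(colSums(x$plan$e) > 0)))
  invisible(x)
}
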