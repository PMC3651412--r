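# Multi-restart simulated annealing over marker assignments and Boolean
# protocols, minimizing E = -s O.
#
# Each step draws a drug uniformly and proposes one of three moves on its
# protocol: add a marker (with a compatible extended function), remove a
# marker (with a compatible restricted function), or change the function at
# fixed markers. Worsening moves are accepted with probability
# exp(-beta dE); beta rises by dbeta every dt steps. A drug that carries
# markers but currently treats nobody only accumulates dead weight, so its
# proposals are forced to removals. Restarts differ only in their seed;
# the best state across restarts (minimum E, ties toward fewer assigned
# markers) is reported.

#' Annealing configuration
#'
#' @param c maximum personalized combination size.
#' @param k_max maximum markers per drug (default 2).
#' @param steps_per_drug steps per drug per restart; the schedule length is
#'   `T = steps_per_drug * d` (default 10000).
#' @param schedule_interval steps between increments of beta; defaults to
#'   the drug count `d`.
#' @param beta0 initial inverse temperature (default 0, i.e. free
#'   exploration).
#' @param dbeta inverse-temperature increment (default 0.01).
#' @param restarts number of annealing restarts (default 100).
#' @param base_seed seed of restart 0; restart r uses `base_seed + r`.
#' @param min_group_size smallest marker group trusted when estimating
#'   group response rates (default 10).
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(c = 1L, k_max = 2L, steps_per_drug = 10000L,
                          schedule_interval = NULL, beta0 = 0, dbeta = 0.01,
                          restarts = 100L, base_seed = 1L,
                          min_group_size = 10L) {
  stopifnot(c >= 1, k_max >= 1, steps_per_drug >= 1, dbeta >= 0,
            restarts >= 1, min_group_size >= 1, beta0 >= 0)
  if (!is.null(schedule_interval)) stopifnot(schedule_interval >= 1)
  structure(list(c = as.integer(c), k_max = as.integer(k_max),
                 steps_per_drug = as.integer(steps_per_drug),
                 schedule_interval = schedule_interval,
                 beta0 = beta0, dbeta = dbeta,
                 restarts = as.integer(restarts),
                 base_seed = as.integer(base_seed),
                 min_group_size = as.integer(min_group_size)),
            class = "anneal_config")
}

# Overall response rate, per-sample P and drug usage from cached
# suggestion/pbar matrices, applying the top-c selection rule. Iterated
# row-wise maxima keep this free of per-sample loops.
plan_objective <- function(pbar, sug, c, J = NULL) {
  s <- nrow(pbar)
  d <- ncol(pbar)
  B <- pbar
  B[!sug] <- -Inf
  L <- numeric(s)
  used <- logical(d)
  rows <- seq_len(s)
  prev_j <- list()
  prev_sel <- list()
  for (t in seq_len(min(c, d))) {
    jt <- max.col(B, ties.method = "first")  # ties -> lower drug index
    sel <- B[cbind(rows, jt)] > -Inf
    if (!any(sel)) break
    pj <- pbar[cbind(rows, jt)]
    L[sel] <- L[sel] + log1p(-pj[sel])
    used[unique(jt[sel])] <- TRUE
    if (!is.null(J) && length(prev_j)) {
      for (t0 in seq_along(prev_j)) {
        both <- sel & prev_sel[[t0]]
        if (any(both)) {
          L[both] <- L[both] + J[cbind(prev_j[[t0]][both], jt[both])]
        }
      }
    }
    prev_j[[t]] <- jt
    prev_sel[[t]] <- sel
    B[cbind(rows, jt)] <- -Inf
  }
  P <- pmin(pmax(1 - exp(L), 0), 1)
  list(O = mean(P), P = P, used = used)
}

#' Annealing energy of an assignment
#'
#' The optimizer minimizes `E = -s O`; this recomputes it from scratch for
#' a protocol list (used to cross-check the annealer's incremental
#' bookkeeping).
#'
#' @inheritParams evaluate_assignment
#' @return `-s * O`.
#' @export
assignment_energy <- function(x, responses, protocols, c,
                              interactions = NULL, min_group_size = 10L) {
  -x$s * evaluate_assignment(x, responses, protocols, c,
                             interactions, min_group_size)$O
}

#' Metropolis acceptance rule
#'
#' Moves that do not increase the energy are always accepted; worsening
#' moves are accepted with probability `exp(-beta * delta_E)`.
#'
#' @param delta_E energy change of the proposed move.
#' @param beta inverse temperature (>= 0).
#' @return `TRUE` to accept.
#' @export
accept_move <- function(delta_E, beta) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  delta_E <= 0 || stats::runif(1) < exp(-beta * delta_E)
}

#' Propose a random protocol move
#'
#' Draws a drug uniformly, then a move type uniformly among those feasible
#' for it: add a marker (if below `k_max` and unassigned markers remain),
#' remove a marker, or change the Boolean function. Additions append the
#' new marker at the last input position with a uniformly drawn compatible
#' extended function; removing the only marker empties the protocol;
#' removal at `K >= 2` draws a uniform position and a uniform compatible
#' restricted function. Drugs listed in `force_remove` are restricted to
#' removal moves (the dead-weight pruning rule).
#'
#' @param protocols list of `drug_protocol`.
#' @param m number of markers in the cohort.
#' @param k_max maximum markers per drug.
#' @param force_remove logical vector (length d): drugs whose markers are
#'   currently unused for treatment.
#' @return List with `drug`, `type` (`"add"`, `"remove"`, `"change"`) and
#'   the proposed `protocol`.
#' @export
propose_move <- function(protocols, m, k_max = 2L,
                         force_remove = logical(length(protocols))) {
  repeat {
    j <- sample.int(length(protocols), 1L)
    prot <- protocols[[j]]
    K <- length(prot$markers)
    if (force_remove[j] && K >= 1L) {
      types <- "remove"
    } else {
      types <- character(0)
      if (K < k_max && K < m) types <- c(types, "add")
      if (K >= 1L) types <- c(types, "remove", "change")
    }
    if (!length(types)) next  # no feasible move for this drug; redraw
    type <- types[sample.int(length(types), 1L)]
    cand <- switch(type,
      add = {
        free <- setdiff(seq_len(m), prot$markers)
        mk <- free[sample.int(length(free), 1L)]
        pool <- if (K == 0L) enumerate_functions(1L)
                else add_marker(prot$fn, k_max = k_max)
        if (!length(pool)) NULL
        else drug_protocol(c(prot$markers, mk),
                           pool[[sample.int(length(pool), 1L)]])
      },
      remove = {
        if (K == 1L) drug_protocol()
        else {
          pos <- sample.int(K, 1L)
          pool <- remove_marker(prot$fn, pos)
          if (!length(pool)) NULL
          else drug_protocol(prot$markers[-pos],
                             pool[[sample.int(length(pool), 1L)]])
        }
      },
      change = drug_protocol(prot$markers, change_function(prot$fn))
    )
    if (!is.null(cand)) return(list(drug = j, type = type, protocol = cand))
  }
}

#' Single simulated-annealing run
#'
#' Starts from all-empty protocols (no markers assigned to any drug) and
#' runs `T = steps_per_drug * d` proposal steps under the rising-beta
#' schedule, tracking the best state visited.
#'
#' @param x a [cohort()].
#' @param responses samples-by-drugs response-probability matrix.
#' @param config an [anneal_config()].
#' @param interactions optional `interaction_model` or matrix.
#' @param seed RNG seed for this run.
#' @param trace_energy record the energy after every step (for schedule
#'   diagnostics).
#' @return An object of class `anneal_fit` with `best` and `final` states
#'   (`protocols`, `O`, `E`), the seed, and optionally `energy_trace`.
#' @export
anneal <- function(x, responses, config, interactions = NULL, seed = 1L,
                   trace_energy = FALSE) {
  stopifnot(inherits(x, "cohort"), inherits(config, "anneal_config"))
  responses <- as.matrix(responses)
  d <- ncol(responses)
  if (nrow(responses) != x$s) stop("response rows must match cohort", call. = FALSE)
  J <- as_J_matrix(interactions, d)
  with_seed(seed, {
    protocols <- replicate(d, drug_protocol(), simplify = FALSE)
    pbar <- matrix(0, x$s, d)
    sug <- matrix(FALSE, x$s, d)
    obj <- plan_objective(pbar, sug, config$c, J)
    E <- -x$s * obj$O
    best <- list(protocols = protocols, O = obj$O, E = E, step = 0L)
    beta <- config$beta0
    dt <- config$schedule_interval %||% d
    n_steps <- config$steps_per_drug * d
    energy_trace <- if (trace_energy) numeric(n_steps) else NULL

    for (step in seq_len(n_steps)) {
      force_remove <- vapply(seq_len(d), function(j) {
        length(protocols[[j]]$markers) >= 1L && !obj$used[j]
      }, logical(1))
      move <- propose_move(protocols, x$m, config$k_max, force_remove)
      j <- move$drug
      cols <- drug_response_columns(x$profiles, responses[, j],
                                    move$protocol, config$min_group_size)
      pbar2 <- pbar; pbar2[, j] <- cols$pbar
      sug2 <- sug; sug2[, j] <- cols$suggested
      obj2 <- plan_objective(pbar2, sug2, config$c, J)
      E2 <- -x$s * obj2$O
      if (accept_move(E2 - E, beta)) {
        protocols[[j]] <- move$protocol
        pbar <- pbar2; sug <- sug2; obj <- obj2; E <- E2
        if (E < best$E) {
          best <- list(protocols = protocols, O = obj$O, E = E, step = step)
        }
      }
      if (trace_energy) energy_trace[step] <- E
      if (step %% dt == 0L) beta <- beta + config$dbeta
    }
    structure(list(best = best,
                   final = list(protocols = protocols, O = obj$O, E = E),
                   seed = seed, beta_final = beta, steps = n_steps,
                   energy_trace = energy_trace, config = config),
              class = "anneal_fit")
  })
}

#' Multi-restart simulated annealing
#'
#' Runs [anneal()] with seeds `base_seed + r`, `r = 0 .. restarts-1`, and
#' reports the best state across restarts (minimum energy; ties broken by
#' fewer assigned markers, favouring simpler catalogs). The trace records
#' each restart's best overall response rate and the running best-so-far,
#' which should flatten when enough initial conditions have been tried.
#'
#' @inheritParams anneal
#' @return An object of class `anneal_result` with `best` (protocols, `O`,
#'   `E`, restart), `eval` (full [evaluate_assignment()] of the best
#'   state), and `trace` (data frame: restart, seed, O_star, best_so_far).
#' @export
multi_start <- function(x, responses, config, interactions = NULL) {
  stopifnot(inherits(config, "anneal_config"))
  R <- config$restarts
  O_star <- numeric(R)
  seeds <- config$base_seed + seq_len(R) - 1L
  best <- NULL
  for (r in seq_len(R)) {
    fit <- anneal(x, responses, config, interactions, seed = seeds[r])
    O_star[r] <- fit$best$O
    n_mk <- sum(lengths(lapply(fit$best$protocols, `[[`, "markers")))
    if (is.null(best) || fit$best$E < best$E ||
        (fit$best$E == best$E && n_mk < best$n_markers)) {
      best <- list(protocols = fit$best$protocols, O = fit$best$O,
                   E = fit$best$E, restart = r, seed = seeds[r],
                   n_markers = n_mk)
    }
  }
  eval <- evaluate_assignment(x, responses, best$protocols, config$c,
                              interactions, config$min_group_size)
  structure(list(best = best, eval = eval,
                 trace = data.frame(restart = seq_len(R), seed = seeds,
                                    O_star = O_star,
                                    best_so_far = cummax(O_star)),
                 config = config),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("Simulated annealing over %d restart(s): best O* = %.4f (E = %.3f) at restart %d\n",
              nrow(x$trace), x$best$O, x$best$E, x$best$restart))
  assigned <- sum(lengths(lapply(x$best$protocols, `[[`, "markers")) > 0)
  cat(sprintf("  %d/%d drugs carry markers; %d used for treatment\n",
              assigned, length(x$best$protocols), used_drug_count(x$eval)))
  invisible(x)
}
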