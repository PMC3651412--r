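# Synthetic cohort and drug-screen generators.
#
# These emulate the structure of a large cell-line sensitivity screen — a
# binary marker matrix, a partially missing logIC50 matrix, and planted
# marker -> sensitivity effects — so that every other component can be
# exercised and validated without external data. Effects are additive on
# the natural-log IC50 scale, which keeps group means analytically
# checkable and matches the lognormal dose model.

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort of binary marker profiles
#'
#' Marker columns are independent Bernoulli draws with the stated
#' prevalences.
#'
#' @param n_samples,n_markers dimensions.
#' @param prevalence marker prevalence in (0,1); scalar or one value per
#'   marker.
#' @param seed RNG seed; the same seed reproduces the same cohort.
#' @return A [cohort()].
#' @export
generate_cohort <- function(n_samples, n_markers, prevalence = 0.3, seed = 1L) {
  prevalence <- rep_len(prevalence, n_markers)
  if (anyNA(prevalence) || any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must lie strictly in (0,1)", call. = FALSE)
  }
  profiles <- with_seed(seed, {
    vapply(seq_len(n_markers),
           function(l) stats::rbinom(n_samples, 1L, prevalence[l]),
           integer(n_samples))
  })
  dim(profiles) <- c(n_samples, n_markers)
  dimnames(profiles) <- list(sprintf("S%03d", seq_len(n_samples)),
                             sprintf("M%03d", seq_len(n_markers)))
  cohort(profiles)
}

#' Table of planted marker-to-drug sensitivity effects
#'
#' @param drug,marker,shift equal-length vectors: drug and marker indices
#'   and the logIC50 shift applied to marker-positive samples (negative =
#'   more sensitive).
#' @return A data frame usable as the `effects` argument of
#'   [generate_ic50()].
#' @export
planted_effects <- function(drug, marker, shift) {
  out <- data.frame(drug = as.integer(drug), marker = as.integer(marker),
                    shift = as.numeric(shift))
  if (anyNA(out) || any(!is.finite(out$shift))) {
    stop("effects must be finite and complete", call. = FALSE)
  }
  out
}

#' Generate a logIC50 matrix with planted marker effects and missingness
#'
#' Each entry is the drug's background mean, plus the shift of every
#' planted effect whose marker the sample carries, plus Gaussian noise;
#' entries are then masked missing uniformly at random.
#'
#' @param x a [cohort()].
#' @param n_drugs number of drugs.
#' @param effects data frame with columns `drug`, `marker`, `shift` (see
#'   [planted_effects()]), or `NULL` for no planted structure.
#' @param background_mean per-drug background logIC50 mean (recycled).
#' @param noise_sd standard deviation of the additive noise.
#' @param missing_frac fraction of entries masked `NA`, in \[0,1).
#' @param seed RNG seed.
#' @return List with elements `ic50` (masked matrix), `complete` (unmasked),
#'   and `truth` (effects, generator settings, seed).
#' @export
generate_ic50 <- function(x, n_drugs, effects = NULL, background_mean = 0,
                          noise_sd = 1, missing_frac = 0.2, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (missing_frac < 0 || missing_frac >= 1) {
    stop("missing_frac must lie in [0,1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  background_mean <- rep_len(background_mean, n_drugs)
  if (!is.null(effects)) {
    if (any(effects$drug < 1L | effects$drug > n_drugs) ||
        any(effects$marker < 1L | effects$marker > x$m)) {
      stop("effect indices out of range", call. = FALSE)
    }
  }
  base <- matrix(rep(background_mean, each = x$s), x$s, n_drugs)
  if (!is.null(effects)) {
    for (r in seq_len(nrow(effects))) {
      base[, effects$drug[r]] <- base[, effects$drug[r]] +
        effects$shift[r] * x$profiles[, effects$marker[r]]
    }
  }
  out <- with_seed(seed, {
    complete <- base + matrix(stats::rnorm(x$s * n_drugs, 0, noise_sd),
                              x$s, n_drugs)
    mask <- matrix(stats::runif(x$s * n_drugs) < missing_frac, x$s, n_drugs)
    list(complete = complete, mask = mask)
  })
  dimnames(out$complete) <- list(x$sample_ids, sprintf("D%02d", seq_len(n_drugs)))
  ic50 <- out$complete
  ic50[out$mask] <- NA_real_
  list(ic50 = ic50, complete = out$complete,
       truth = list(effects = effects, background_mean = background_mean,
                    noise_sd = noise_sd, missing_frac = missing_frac,
                    seed = seed))
}

#' Generate an iid response-probability matrix
#'
#' Used for null-model checks such as the iid expectation of the number of
#' used drugs.
#'
#' @param n_samples,n_drugs dimensions.
#' @param sampler function of `n` returning `n` draws in \[0,1\]
#'   (default uniform).
#' @param seed RNG seed.
#' @return Samples-by-drugs probability matrix.
#' @export
generate_iid_responses <- function(n_samples, n_drugs,
                                   sampler = stats::runif, seed = 1L) {
  p <- with_seed(seed, sampler(n_samples * n_drugs))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("sampler must return probabilities in [0,1]", call. = FALSE)
  }
  matrix(p, n_samples, n_drugs,
         dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                         sprintf("D%02d", seq_len(n_drugs))))
}
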