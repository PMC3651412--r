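# Imputation of missing logIC50 entries by a doubly-weighted average:
# a missing (i, j) is filled with a weighted mean of the other samples'
# values for drug j, weighted by exp(-alpha_sample * d_ikj), where the
# sample distance d_ikj is itself a weighted mean of squared differences
# across drugs, weighted by exp(-alpha_drug * d_jl) so that drugs behaving
# like the target drug dominate. Distances are mean squared differences
# over the entries present in both rows/columns.

#' Mean squared distance between two drug columns
#'
#' @param ic50 samples-by-drugs matrix with `NA` for missing values.
#' @param j,l distinct drug indices.
#' @return Mean of squared logIC50 differences over samples where both
#'   drugs are present; `NA` when there is no overlap.
#' @export
drug_distance <- function(ic50, j, l) {
  if (j == l) stop("j and l must differ", call. = FALSE)
  a <- ic50[, j]
  b <- ic50[, l]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NA_real_)
  mean((a[keep] - b[keep])^2)
}

# full drug-drug distance matrix (NA where no shared sample, 0 diagonal)
drug_distance_matrix <- function(ic50) {
  W <- !is.na(ic50)
  M0 <- ic50
  M0[!W] <- 0
  n <- crossprod(W)                    # shared-sample counts
  A <- crossprod(M0^2, W)              # sum over shared of m_ij^2
  S <- A + t(A) - 2 * crossprod(M0)
  D <- S / n
  D[n == 0] <- NA_real_
  diag(D) <- 0
  D
}

#' Weighted distance between two samples relative to a target drug
#'
#' Squared row differences over drugs `l != j` present in both samples,
#' weighted by `exp(-alpha_drug * d_jl)`. Drug pairs whose distance to the
#' target drug is undefined (no shared sample) get weight 0.
#'
#' @param ic50 samples-by-drugs matrix with `NA` for missing values.
#' @param i,k distinct sample indices.
#' @param j target drug index (excluded from the sum).
#' @param alpha_drug non-negative drug-weighting decay.
#' @return Weighted mean squared difference, or `NA` when the samples share
#'   no usable drug.
#' @export
sample_distance <- function(ic50, i, k, j, alpha_drug) {
  if (i == k) stop("i and k must differ", call. = FALSE)
  if (alpha_drug < 0) stop("alpha_drug must be >= 0", call. = FALSE)
  ddist <- drug_distance_matrix(ic50)
  sample_distance_matrix(ic50, j, alpha_drug, ddist)[i, k]
}

# all pairwise sample distances for one target drug
sample_distance_matrix <- function(ic50, j, alpha_drug, ddist) {
  W <- !is.na(ic50)
  M0 <- ic50
  M0[!W] <- 0
  w <- exp(-alpha_drug * ddist[j, ])
  w[is.na(w)] <- 0
  w[j] <- 0
  Ww <- sweep(W, 2L, w, `*`)
  A <- (M0^2 %*% t(Ww))                # sum_l w_l m_il^2 [k present]
  num <- A + t(A) - 2 * (sweep(M0, 2L, w, `*`) %*% t(M0))
  den <- Ww %*% t(W)
  D <- num / den
  D[den == 0] <- NA_real_
  diag(D) <- 0
  D
}

# Doubly-weighted estimates of column j for every row (self excluded).
# Donors are rows with the target drug present; rows whose distance to all
# donors is undefined get NA. Row-wise weight stabilization (subtracting
# the row minimum distance) leaves the weighted mean unchanged but avoids
# exp underflow at large alpha_sample.
column_estimates <- function(ic50, j, alpha_sample, alpha_drug, ddist) {
  s <- nrow(ic50)
  D <- sample_distance_matrix(ic50, j, alpha_drug, ddist)
  present <- !is.na(ic50[, j])
  A <- D
  A[is.na(A)] <- Inf
  diag(A) <- Inf
  A[, !present] <- Inf
  rowmin <- apply(A, 1L, min)
  usable <- is.finite(rowmin)
  Wgt <- exp(-alpha_sample * (A - rowmin))
  Wgt[!is.finite(Wgt)] <- 0
  v <- ic50[, j]
  v[!present] <- 0
  est <- as.numeric(Wgt %*% v) / rowSums(Wgt)
  est[!usable] <- NA_real_
  est
}

#' Impute missing logIC50 entries
#'
#' Fills each missing entry with the doubly-weighted average of the other
#' samples' values for that drug. When no neighbour with a defined distance
#' exists, the entry falls back to the mean of the drug's present values.
#' Present entries are never modified, and every imputed value lies within
#' the range of the column's present values (it is a convex combination of
#' them).
#'
#' @param ic50 samples-by-drugs matrix of natural-log IC50 values with `NA`
#'   for missing entries; every column needs at least one present value.
#' @param alpha_sample,alpha_drug non-negative decay parameters controlling
#'   how sharply near neighbours dominate (see [grid_search()] for their
#'   selection).
#' @return The completed matrix.
#' @export
impute_ic50 <- function(ic50, alpha_sample = 1, alpha_drug = 1) {
  ic50 <- as.matrix(ic50)
  if (alpha_sample < 0 || alpha_drug < 0) {
    stop("alpha parameters must be >= 0", call. = FALSE)
  }
  empty <- colSums(!is.na(ic50)) == 0L
  if (any(empty)) {
    stop(sprintf("drug column(s) with no present values: %s",
                 paste(which(empty), collapse = ", ")), call. = FALSE)
  }
  if (!anyNA(ic50)) return(ic50)
  ddist <- drug_distance_matrix(ic50)
  out <- ic50
  for (j in which(colSums(is.na(ic50)) > 0L)) {
    miss <- which(is.na(ic50[, j]))
    est <- column_estimates(ic50, j, alpha_sample, alpha_drug, ddist)[miss]
    est[is.na(est)] <- mean(ic50[, j], na.rm = TRUE)
    out[miss, j] <- est
  }
  out
}

#' Correlation between weighted-average estimates and observed logIC50s
#'
#' In the default `"direct"` mode, every present entry is re-estimated from
#' the other samples (self-exclusion is built into the estimator) and the
#' Pearson correlation with the observed values is returned. The
#' `"holdout"` mode masks a random fraction of present entries, imputes
#' them, and correlates at the masked cells only — a stricter validation.
#'
#' @inheritParams impute_ic50
#' @param method `"direct"` (default) or `"holdout"`.
#' @param holdout_frac fraction of present entries to mask in holdout mode.
#' @param seed RNG seed for the holdout mask.
#' @return Pearson correlation coefficient.
#' @export
evaluate_imputation <- function(ic50, alpha_sample = 1, alpha_drug = 1,
                                method = c("direct", "holdout"),
                                holdout_frac = 0.1, seed = 1L) {
  ic50 <- as.matrix(ic50)
  method <- match.arg(method)
  if (method == "holdout") {
    present <- which(!is.na(ic50))
    if (length(present) < 2L) stop("need at least two present entries", call. = FALSE)
    mask <- with_seed(seed, sample(present, max(2L, round(holdout_frac * length(present)))))
    masked <- ic50
    masked[mask] <- NA_real_
    completed <- impute_ic50(masked, alpha_sample, alpha_drug)
    pred <- completed[mask]
    actual <- ic50[mask]
  } else {
    ddist <- drug_distance_matrix(ic50)
    pred <- actual <- numeric(0)
    for (j in seq_len(ncol(ic50))) {
      present <- which(!is.na(ic50[, j]))
      if (!length(present)) next
      est <- column_estimates(ic50, j, alpha_sample, alpha_drug, ddist)[present]
      keep <- !is.na(est)
      pred <- c(pred, est[keep])
      actual <- c(actual, ic50[present, j][keep])
    }
  }
  if (length(actual) < 2L) stop("too few comparable entries", call. = FALSE)
  if (stats::sd(actual) == 0 || stats::sd(pred) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(pred, actual)
}

#' Select imputation parameters by correlation grid search
#'
#' Evaluates [evaluate_imputation()] on every `(alpha_sample, alpha_drug)`
#' grid point and returns the argmax (ties resolved toward smaller
#' `alpha_sample`, then smaller `alpha_drug`) together with the full
#' correlation surface. The default grid spans integers 1–22 in both
#' directions.
#'
#' @inheritParams evaluate_imputation
#' @param alpha_sample_grid,alpha_drug_grid numeric vectors of candidate
#'   values.
#' @return An object of class `imputation_grid`: `best` (named vector),
#'   `best_pcc`, and `surface` (data frame with one row per grid point).
#' @export
grid_search <- function(ic50, alpha_sample_grid = 1:22, alpha_drug_grid = 1:22,
                        method = c("direct", "holdout"),
                        holdout_frac = 0.1, seed = 1L) {
  method <- match.arg(method)
  if (!length(alpha_sample_grid) || !length(alpha_drug_grid)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  surface <- expand.grid(alpha_sample = alpha_sample_grid,
                         alpha_drug = alpha_drug_grid,
                         KEEP.OUT.ATTRS = FALSE)
  surface$pcc <- vapply(seq_len(nrow(surface)), function(r) {
    evaluate_imputation(ic50, surface$alpha_sample[r], surface$alpha_drug[r],
                        method = method, holdout_frac = holdout_frac,
                        seed = seed)
  }, numeric(1))
  best_row <- order(-surface$pcc, surface$alpha_sample, surface$alpha_drug)[1L]
  structure(
    list(best = c(alpha_sample = surface$alpha_sample[best_row],
                  alpha_drug = surface$alpha_drug[best_row]),
         best_pcc = surface$pcc[best_row],
         surface = surface),
    class = "imputation_grid"
  )
}

#' @export
print.imputation_grid <- function(x, ...) {
  cat(sprintf("Imputation grid search over %d points\n", nrow(x$surface)))
  cat(sprintf("  best PCC = %.4f at alpha_sample = %g, alpha_drug = %g\n",
              x$best_pcc, x$best["alpha_sample"], x$best["alpha_drug"]))
  invisible(x)
}
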