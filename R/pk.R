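# Pharmacokinetic response model.
#
# Drugs are dosed at y_j = mean(logIC50)_j + log h, where h is the fold
# change over the typical active concentration (h = 2 reflects tolerated
# high-dose therapy). The log-dose actually reaching the cancer cells is
# Z_j ~ Normal(y_j, sigma^2), sigma capturing patient-to-patient
# pharmacokinetic variation. A sample responds (>= 50% growth inhibition)
# when Z_j exceeds its logIC50, so
#   p_ij = 1/2 erfc((logIC50_ij - y_j) / (sqrt(2) sigma)).

#' Treatment log-dose for one drug
#'
#' @param logic50 the drug's logIC50 values across samples (natural log);
#'   `NA`s are ignored.
#' @param h dose fold-change relative to the mean activity concentration
#'   (default 2, the assumed highest tolerated dose).
#' @return `mean(logIC50) + log(h)`.
#' @export
treatment_dose <- function(logic50, h = 2) {
  if (h <= 0) stop("h must be positive", call. = FALSE)
  x <- logic50[!is.na(logic50)]
  if (!length(x)) stop("no logIC50 values available for this drug", call. = FALSE)
  mean(x) + log(h)
}

#' Probability that a sample responds to a drug at a given dose
#'
#' Survival probability of the lognormally dispersed dose above the
#' sample's logIC50: `1/2 erfc((logIC50 - dose)/(sqrt(2) sigma))`, equal to
#' `Pr(Z > logIC50)` for `Z ~ Normal(dose, sigma^2)`. `sigma` is the
#' standard deviation of the log-dose. Strictly decreasing in logIC50.
#'
#' @param logic50 sample logIC50 (natural log); vectorized.
#' @param dose treatment log-dose `y_j`.
#' @param sigma log-dose standard deviation (> 0).
#' @return Probability in \[0,1\].
#' @export
response_probability <- function(logic50, dose, sigma) {
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  0.5 * pracma::erfc((logic50 - dose) / (sqrt(2) * sigma))
}

#' Build the response-probability matrix from a completed logIC50 matrix
#'
#' @param ic50 samples-by-drugs matrix of natural-log IC50 values with no
#'   missing entries (impute first, see [impute_ic50()]).
#' @param h dose fold-change (default 2).
#' @param sigma log-dose standard deviation (default 1).
#' @return Samples-by-drugs matrix of response probabilities.
#' @export
build_response_matrix <- function(ic50, h = 2, sigma = 1) {
  ic50 <- as.matrix(ic50)
  if (anyNA(ic50)) {
    stop("logIC50 matrix has missing entries; run impute_ic50() first",
         call. = FALSE)
  }
  doses <- colMeans(ic50) + log(h)
  p <- response_probability(sweep(ic50, 2L, doses), 0, sigma)
  dimnames(p) <- dimnames(ic50)
  p
}

#' Number of drugs used to treat at least one sample
#'
#' @param plan a `treatment_plan` (or an `assignment_eval`, whose plan is
#'   used).
#' @return Integer count d*.
#' @export
used_drug_count <- function(plan) {
  if (inherits(plan, "assignment_eval")) plan <- plan$plan
  stopifnot(inherits(plan, "treatment_plan"))
  sum(colSums(plan$e) > 0)
}

#' Expected number of used drugs under iid random selection
#'
#' If every sample independently picked `c` of the `d` drugs uniformly, a
#' drug would treat at least one sample with probability `1 - (1 - c/d)^s`,
#' so `E[d*] = d (1 - (1 - c/d)^s)`; increasing in both `c` and `s`. The
#' optimizer's departure from this null reflects correlated drug
#' preferences across samples.
#'
#' @param d number of drugs in the catalog.
#' @param c combination size per sample.
#' @param s number of samples.
#' @return Expected count of drugs used at least once.
#' @export
expected_used_drugs <- function(d, c, s) {
  if (c < 1 || c > d) stop("need 1 <= c <= d", call. = FALSE)
  if (s < 1) stop("need s >= 1", call. = FALSE)
  d * (1 - (1 - c / d)^s)
}
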