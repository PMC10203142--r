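# Cohort-size and sampling-error calculators for in-silico trials.
#
# Error models for estimating statistical moments from a virtual cohort of
# N patients: plain Monte Carlo ~ 1/sqrt(N); variance-reduced (Latin
# hypercube) ~ C/sqrt(N) with C <= 1; quasi-random (Sobol-type) ~ 1/N^a
# with a in [1/2, 1]; rare events of probability p ~ 1/sqrt(pN) for plain
# MC; Subset Simulation ~ sqrt(log10(1/p)^2 / N) (base-10 logarithm, which
# reproduces the canonical 400-vs-10000 rare-event comparison exactly).

#' Define a cohort sampling model
#'
#' @param method One of `"MC"`, `"LHS"`, `"QMC"`, `"MC_RARE"`, `"SUBSET"`.
#' @param C Variance-reduction constant for LHS, in (0, 1].
#' @param alpha Quasi-random convergence exponent for QMC, in [1/2, 1].
#' @param p Rare-event probability for MC_RARE/SUBSET, in (0, 1).
#' @return Object of class `sampling_model`.
#' @export
sampling_model <- function(method = c("MC", "LHS", "QMC", "MC_RARE", "SUBSET"),
                           C = 1, alpha = 0.5, p = NULL) {
  method <- match.arg(method)
  if (method == "LHS" && !(C > 0 && C <= 1))
    stop("LHS constant C must be in (0, 1]")
  if (method == "QMC" && !(alpha >= 0.5 && alpha <= 1))
    stop("QMC exponent alpha must be in [1/2, 1]")
  if (method %in% c("MC_RARE", "SUBSET")) {
    if (is.null(p) || !(p > 0 && p < 1))
      stop(method, " requires a rare-event probability p in (0, 1)")
  }
  structure(list(method = method, C = C, alpha = alpha, p = p),
            class = "sampling_model")
}

#' Sampling error of a cohort of size N
#'
#' @param model A `sampling_model`.
#' @param N Cohort size(s), >= 1.
#' @return Error (fraction); vectorized over `N`.
#' @export
sampling_error <- function(model, N) {
  stopifnot(all(N >= 1))
  switch(model$method,
         MC = 1 / sqrt(N),
         LHS = model$C / sqrt(N),
         QMC = 1 / N^model$alpha,
         MC_RARE = 1 / sqrt(model$p * N),
         SUBSET = sqrt(log10(1 / model$p)^2 / N))
}

#' Smallest cohort meeting a target error
#'
#' Exact inverse of [sampling_error]: the smallest integer `N` with
#' `sampling_error(model, N) <= target_error`.
#'
#' @param model A `sampling_model`.
#' @param target_error Fraction in (0, 1).
#' @return Integer cohort size.
#' @export
cohort_size <- function(model, target_error) {
  stopifnot(target_error > 0, target_error < 1)
  N_real <- switch(model$method,
                   MC = 1 / target_error^2,
                   LHS = (model$C / target_error)^2,
                   QMC = (1 / target_error)^(1 / model$alpha),
                   MC_RARE = 1 / (model$p * target_error^2),
                   SUBSET = log10(1 / model$p)^2 / target_error^2)
  N <- ceiling(N_real - 1e-9)
  # guard the exact-inverse contract against floating-point edges
  while (sampling_error(model, N) > target_error) N <- N + 1
  while (N > 1 && sampling_error(model, N - 1) <= target_error) N <- N - 1
  as.integer(N)
}

#' Error-versus-N sweep table
#'
#' @param model A `sampling_model`.
#' @param N Vector of cohort sizes.
#' @return data.frame(N, error).
#' @export
sampling_error_table <- function(model, N = 10^(seq(0, 5, by = 0.25))) {
  data.frame(N = round(N), error = sampling_error(model, round(N)))
}
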