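## Retinol isotope dilution: time-variant coefficients, TBS prediction and
## outcome evaluation.
##
## The RID estimate is TBS = Fa * S / SA_p, where Fa is the fraction of the
## dose residing in the storage pool at time t, S the plasma-to-store
## specific-activity ratio, and SA_p the plasma retinol specific activity
## (fraction of dose per umol).  With model-consistent coefficients the
## composite Fa * S equals M(6) * F(5)(t) / M(5), so a subject evaluated
## with their own coefficients recovers their own stores exactly.

#' Time-variant RID coefficients from a model
#'
#' Computes `Fa(t) = F(6)(t)` (tracer in the storage pool), the
#' specific-activity ratio `S(t) = [F(5)/M(5)] / [F(6)/M(6)]`, and the
#' composite coefficient `Fa * S`, which algebraically equals
#' `M(6) * F(5)(t) / M(5)`.
#'
#' @param object a [model_spec()] (then `steady` is required) or a
#'   [fit_population()] result (its own steady state is used).
#' @param times evaluation times in days; must exceed the pre-plasma lag so
#'   that the storage pool contains tracer.
#' @param steady a [steady_state()] giving `M(5)` and `M(6)`; ignored when
#'   `object` is a fit.
#' @return A data frame of class `rid_coefficients` with columns `time_d`,
#'   `Fa`, `S`, `FaS`.
#' @export
rid_coefficients <- function(object, times, steady = NULL) {
  if (inherits(object, "population_fit")) {
    spec <- object$spec
    steady <- object$steady
  } else if (inherits(object, "model_spec")) {
    spec <- object
    if (is.null(steady))
      stop("supply a steady_state when passing a bare model_spec",
           call. = FALSE)
  } else stop("object must be a model_spec or population_fit", call. = FALSE)
  sim <- simulate_compartments(spec, times)
  M5 <- steady$masses[["5"]]
  M6 <- steady$masses[["6"]]
  if (any(sim$f6 <= 0))
    stop("undefined coefficient: storage pool holds no tracer at t = ",
         paste(times[sim$f6 <= 0], collapse = ", "), " d", call. = FALSE)
  Fa <- sim$f6
  S <- (sim$f5 / M5) / (sim$f6 / M6)
  structure(data.frame(time_d = times, Fa = Fa, S = S, FaS = Fa * S),
            class = c("rid_coefficients", "data.frame"))
}

#' Plasma retinol specific activity
#'
#' `SA_p = FD_p / M(5)`: fraction of dose in plasma divided by the plasma
#' retinol pool size.
#'
#' @param fdp fraction of dose in plasma (>= 0).
#' @param M5 plasma retinol pool size, µmol (> 0).
#' @return Specific activity, fraction of dose per µmol.
#' @examples
#' sap(0.00153, 1.02)
#' @export
sap <- function(fdp, M5) {
  if (any(M5 <= 0)) stop("M5 must be > 0", call. = FALSE)
  if (any(fdp < 0)) stop("fdp must be >= 0", call. = FALSE)
  fdp / M5
}

#' RID prediction of total body stores
#'
#' `TBS = Fa * S / SA_p` (Eq. coefficients times the reciprocal plasma
#' specific activity).
#'
#' @param FaS composite coefficient `Fa * S` (dimensionless).
#' @param sap plasma specific activity, per µmol (> 0).
#' @return Predicted TBS, µmol.
#' @examples
#' rid_predict(1, 1 / 538)  # 538
#' @export
rid_predict <- function(FaS, sap) {
  if (any(sap <= 0)) stop("sap must be > 0", call. = FALSE)
  FaS / sap
}

#' RID predictions for every cohort child at one time
#'
#' Applies a population composite coefficient to each child's own plasma
#' specific activity at the evaluation time.
#'
#' @param fas_pop population composite coefficient `Fa * S` at `time`.
#' @param cohort a [generate_cohort()] result.
#' @param time evaluation time, days (single value).
#' @param fdp optional vector of each child's fraction of dose in plasma at
#'   `time` (simulated from the children's own models if omitted).
#' @return Named numeric vector of predicted TBS (µmol), one per child.
#' @export
rid_predict_cohort <- function(fas_pop, cohort, time, fdp = NULL) {
  stopifnot(inherits(cohort, "cohort"), length(time) == 1)
  if (is.null(fdp)) fdp <- as.vector(cohort_curves(cohort, time))
  preds <- rid_predict(fas_pop, sap(fdp, cohort$children$m5_umol))
  stats::setNames(preds, cohort$children$id)
}

# Spearman rank correlation with a t-approximation p-value (exact algorithm
# for small tie-free samples)
.spearman <- function(x, y) {
  n <- length(x)
  rs <- stats::cor(rank(x), rank(y))
  if (n <= 12 && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    tt <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rs = rs, p = p)
}

#' Evaluate RID predictions against assigned values
#'
#' Computes, per child, the predicted/assigned ratio; the percentages of
#' children whose prediction lies within 25%, 50% and 75% of the assigned
#' value (on `|predicted - assigned| / assigned`); the arithmetic mean and
#' range of the ratios; the geometric mean of the predictions; the Spearman
#' rank correlation between predicted and assigned; and the least-squares
#' regression (slope, intercept, R^2) of predicted on assigned.  The
#' adequacy flag records whether at least 75% of children fall within 25%.
#'
#' @param predicted,assigned equal-length positive vectors of TBS (µmol).
#' @return An object of class `rid_evaluation` (a list; see Details).
#' @examples
#' ev <- rid_evaluate(c(130, 190), c(100, 200))
#' ev$pct_within_25  # 50
#' @export
rid_evaluate <- function(predicted, assigned) {
  if (length(predicted) != length(assigned))
    stop("predicted and assigned must have equal length", call. = FALSE)
  if (any(assigned <= 0))
    stop("assigned values must be > 0", call. = FALSE)
  rel <- (predicted - assigned) / assigned
  ratio <- predicted / assigned
  pct <- function(b) 100 * mean(abs(rel) <= b)
  sp <- .spearman(predicted, assigned)
  fit <- stats::lm(predicted ~ assigned)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(per_child = data.frame(assigned = assigned, predicted = predicted,
                                ratio = ratio, rel_err_pct = 100 * rel),
         pct_within_25 = pct(0.25), pct_within_50 = pct(0.50),
         pct_within_75 = pct(0.75),
         mean_ratio = mean(ratio), ratio_range = range(ratio),
         geo_mean_predicted = exp(mean(log(pmax(predicted,
                                                .Machine$double.xmin)))),
         spearman_rs = sp$rs, spearman_p = sp$p,
         r_squared = r2,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         adequate = pct(0.25) >= 75),
    class = "rid_evaluation")
}

#' @export
print.rid_evaluation <- function(x, ...) {
  cat(sprintf(
    "<rid_evaluation> n = %d children\n  within 25/50/75%%: %.0f / %.0f / %.0f%%%s\n",
    nrow(x$per_child), x$pct_within_25, x$pct_within_50, x$pct_within_75,
    if (x$adequate) "  (meets the 75%-within-25% criterion)" else ""))
  cat(sprintf("  mean ratio %.2f (range %.2f-%.2f); geometric mean predicted %.0f umol\n",
              x$mean_ratio, x$ratio_range[1], x$ratio_range[2],
              x$geo_mean_predicted))
  cat(sprintf("  Spearman Rs = %.3f (P = %.2g); R^2 = %.3f\n",
              x$spearman_rs, x$spearman_p, x$r_squared))
  invisible(x)
}

#' Per-child composite coefficients across the cohort
#'
#' The true composite coefficient of each child at each time, computed from
#' the child's own generating model and assigned masses
#' (`FaS = M(6) * F(5)(t) / M(5)`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param times evaluation times, days.
#' @param fdp optional precomputed [cohort_curves()] matrix at `times`.
#' @return Matrix (children x times) of composite coefficients.
#' @export
cohort_fas <- function(cohort, times, fdp = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(fdp)) fdp <- cohort_curves(cohort, times)
  ch <- cohort$children
  out <- fdp * (ch$tbs_umol / ch$m5_umol)
  dimnames(out) <- list(ch$id, times)
  out
}

#' Dispersion of the composite RID coefficient over time
#'
#' Coefficient of variation (arithmetic SD / mean) of the per-child
#' composite coefficient `Fa * S` at each time, overall and within the
#' one-pool and two-pool subgroups, with the time of minimum overall CV.
#'
#' @inheritParams cohort_fas
#' @return A list with `table` (columns `time_d`, `cv_all`, `cv_pool1`,
#'   `cv_pool2`) and `argmin_time` (day of lowest overall CV).
#' @export
coefficient_cv_over_time <- function(cohort, times, fdp = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort$children) < 2)
    stop("at least 2 children are required", call. = FALSE)
  fas <- cohort_fas(cohort, times, fdp)
  pool <- cohort$children$variant_pools
  cv <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x) / mean(x)
  tab <- data.frame(
    time_d = times,
    cv_all = apply(fas, 2, cv),
    cv_pool1 = apply(fas[pool == 1L, , drop = FALSE], 2, cv),
    cv_pool2 = apply(fas[pool == 2L, , drop = FALSE], 2, cv))
  rownames(tab) <- NULL
  list(table = tab, argmin_time = times[which.min(tab$cv_all)])
}

#' Write an RID evaluation as delimited text plus a structured summary
#'
#' Per-child rows go to a tab-separated file; the summary (band coverage,
#' ratios, correlations) to `<path>.summary.json`.
#'
#' @param eval an [rid_evaluate()] result.
#' @param path file path for the per-child table.
#' @return `path`, invisibly.
#' @export
write_rid_evaluation <- function(eval, path) {
  stopifnot(inherits(eval, "rid_evaluation"))
  con <- file(path, "w")
  writeLines("# per-child RID outcome; TBS umol", con)
  utils::write.table(eval$per_child, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  jsonlite::write_json(
    eval[c("pct_within_25", "pct_within_50", "pct_within_75", "mean_ratio",
           "ratio_range", "geo_mean_predicted", "spearman_rs", "spearman_p",
           "r_squared", "slope", "intercept", "adequate")],
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
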