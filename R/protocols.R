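## Sampling protocols and composite geometric-mean data sets.

#' Sampling schedules
#'
#' `reduced11` is the 11-time schedule used in field studies: 6, 9 and 12 h
#' and 1, 2, 4, 7, 11, 16, 22 and 28 d.  `extensive36` spans 6 h to 56 d
#' with 36 times, contains `reduced11` as a subset, and is dense through the
#' early absorptive phase and the terminal slope.
#'
#' @param name `"reduced11"` or `"extensive36"`.
#' @return Numeric vector of sampling times in days.
#' @export
schedule_times <- function(name = c("reduced11", "extensive36")) {
  name <- match.arg(name)
  reduced <- c(0.25, 0.375, 0.5, 1, 2, 4, 7, 11, 16, 22, 28)
  if (name == "reduced11") return(reduced)
  sort(c(reduced,
         c(0.75, 1.5, 2.5, 3, 3.5, 5, 6, 8, 9, 10, 12, 14, 18, 20, 24, 26,
           30, 32, 35, 38, 42, 46, 50, 53, 56)))
}

#' Geometric mean of positive tracer observations
#'
#' The antilog of the mean log value, the averaging rule used to form all
#' composite population data sets.
#'
#' @param values positive numeric vector.
#' @return The geometric mean.
#' @examples
#' geometric_mean_fdp(c(0.01, 0.0001))  # 0.001
#' @export
geometric_mean_fdp <- function(values) {
  if (length(values) == 0) stop("no values supplied", call. = FALSE)
  if (any(values <= 0))
    stop("geometric mean undefined: all values must be > 0", call. = FALSE)
  exp(mean(log(values)))
}

# composite curve from a children x times fdp matrix and a per-time list of
# contributing row indices
.composite <- function(fdp, times, contributors) {
  g <- vapply(seq_along(times), function(j)
    geometric_mean_fdp(fdp[contributors[[j]], j]), 0)
  tracer_curve(times, g, n = vapply(contributors, length, 0L))
}

#' Composite geometric-mean data sets for the three sampling protocols
#'
#' Protocol 1 pools all children at the extensive 36-time schedule; protocol
#' 2 pools all children at the reduced 11-time schedule; protocol 3 mimics
#' the sparse super-child field design: every child is sampled at 4 d, and
#' each child's single second sample is randomly assigned so that exactly 5
#' children contribute at each of the 10 remaining reduced times.  The
#' protocol-3 randomization is repeated `n_scenarios` times.
#'
#' @param cohort a [generate_cohort()] result.
#' @param fdp optional precomputed children-by-times tracer matrix from
#'   [cohort_curves()] at the appropriate schedule (computed if omitted).
#' @return For protocols 1 and 2, a composite [tracer_curve()].  For
#'   protocol 3, a list of `n_scenarios` elements, each with `assignment`
#'   (data frame `scenario`, `child_id`, `second_time_d`) and `curve`
#'   (composite `tracer_curve`).
#' @examples
#' coh <- generate_cohort(seed = 1)
#' p2 <- build_protocol2(coh)
#' head(p2)
#' @export
build_protocol1 <- function(cohort, fdp = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$children)
  if (n == 0) stop("empty cohort", call. = FALSE)
  times <- schedule_times("extensive36")
  if (is.null(fdp)) fdp <- cohort_curves(cohort, times)
  .composite(fdp, times, rep(list(seq_len(n)), length(times)))
}

#' @rdname build_protocol1
#' @export
build_protocol2 <- function(cohort, fdp = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$children)
  if (n == 0) stop("empty cohort", call. = FALSE)
  times <- schedule_times("reduced11")
  if (is.null(fdp)) fdp <- cohort_curves(cohort, times)
  .composite(fdp, times, rep(list(seq_len(n)), length(times)))
}

#' @rdname build_protocol1
#' @param n_scenarios number of randomized super-child scenarios (default 5).
#' @param seed integer seed for the randomization (required).
#' @export
build_protocol3 <- function(cohort, n_scenarios = 5L, seed, fdp = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the scenario randomization", call. = FALSE)
  n <- nrow(cohort$children)
  times <- schedule_times("reduced11")
  other <- setdiff(times, 4)
  per_time <- n / length(other)
  if (per_time != round(per_time))
    stop("cohort size must divide evenly into the ", length(other),
         " non-4-d times", call. = FALSE)
  if (is.null(fdp)) fdp <- cohort_curves(cohort, times)
  ids <- cohort$children$id
  day4 <- which(times == 4)

  .with_seed(seed, {
    lapply(seq_len(n_scenarios), function(s) {
      perm <- sample.int(n)
      second <- rep(other, each = per_time)[order(perm)]
      contributors <- lapply(seq_along(times), function(j) {
        if (j == day4) seq_len(n) else which(second == times[j])
      })
      list(assignment = data.frame(scenario = s, child_id = ids,
                                   second_time_d = second),
           curve = .composite(fdp, times, contributors))
    })
  })
}
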