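## Synthetic cohort of "theoretical children" with known kinetic values.
##
## Free quantities (TBS, plasma pool, intake, exchange coefficients, delay,
## upstream rates, absorption, body weight) are assigned from truncated
## log-normal distributions calibrated so that the cohort geometric means and
## ranges match the published physiologic targets; dependent quantities
## (disposal coefficient, mobilisation coefficient, fast-pool mass) are then
## derived from the steady-state balance, with out-of-range draws redrawn.

# retinol molar mass equivalence: 1 umol retinol = 286.45 ug RAE
.UG_RAE_PER_UMOL <- 286.45

# calibration targets: geometric mean and admissible range per quantity
.param_table <- function(preset) {
  high <- list(
    tbs    = c(gm = 538,  lo = 92,    hi = 1904),
    m5     = c(gm = 1.02, lo = 0.345, hi = 2.62),
    intake = c(gm = 4.07, lo = 2.34,  hi = 16.8),   # umol/d
    l65    = c(gm = 30.1, lo = 20.1,  hi = 39.9),
    l75    = c(gm = 31.9, lo = 5.40,  hi = 60.9),
    l57    = c(gm = 1.67, lo = 0.401, hi = 3.75),
    dt3    = c(gm = 0.18, lo = 0.09,  hi = 0.24),
    l21    = c(gm = 50,   lo = 25,    hi = 100),
    l32    = c(gm = 50,   lo = 25,    hi = 100),
    l54    = c(gm = 3.33, lo = 1.2,   hi = 10))
  if (preset == "low_intake_10") {
    high$tbs    <- c(gm = 85,   lo = 54,    hi = 114)
    high$intake <- c(gm = 1.29, lo = 0.817, hi = 2.042)  # 234-585 ug RAE/d
    high$m5     <- c(gm = 0.70, lo = 0.35,  hi = 1.40)
  }
  high
}

# derived-quantity admissible ranges (high-intake preset: published ranges)
.derived_ranges <- function(preset) {
  if (preset == "high_intake_50")
    list(l106 = c(0.00201, 0.210), l56 = c(0.0156, 0.122),
         m7 = c(5.24, 38.6), mst = c(0.364, 1.08))
  else  # low-intake preset: positivity plus the same sojourn-time window
    list(l106 = c(1e-6, Inf), l56 = c(1e-6, Inf),
         m7 = c(1e-6, Inf), mst = c(0.364, 1.08))
}

# run code under a given seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# location of a truncated normal on [llo, lhi] with sd s whose mean is mtarget
.trunc_mu <- function(mtarget, s, llo, lhi) {
  f <- function(mu) {
    al <- (llo - mu) / s; be <- (lhi - mu) / s
    mu + s * (stats::dnorm(al) - stats::dnorm(be)) /
      (stats::pnorm(be) - stats::pnorm(al)) - mtarget
  }
  stats::uniroot(f, lower = llo, upper = lhi, tol = 1e-12)$root
}

# one quantile of the truncated log-normal (u in (0,1))
.qtrunclnorm <- function(u, mu, s, llo, lhi) {
  plo <- stats::pnorm((llo - mu) / s)
  phi <- stats::pnorm((lhi - mu) / s)
  exp(mu + s * stats::qnorm(plo + u * (phi - plo)))
}

# stratified sample of size n from the calibrated truncated log-normal:
# one draw per equal-probability slice, slices randomly permuted, so each
# value is a truncated log-normal draw while the cohort geometric mean sits
# on the calibration target for every seed.
.sample_param <- function(n, target) {
  gm <- target[["gm"]]; lo <- target[["lo"]]; hi <- target[["hi"]]
  llo <- log(lo); lhi <- log(hi)
  s <- (lhi - llo) / (2 * stats::qnorm(0.995))   # ~99% of mass in range
  mu <- .trunc_mu(log(gm), s, llo, lhi)
  u <- (seq_len(n) - stats::runif(n)) / n
  x <- .qtrunclnorm(u, mu, s, llo, lhi)
  list(x = x[sample.int(n)], mu = mu, s = s, llo = llo, lhi = lhi)
}

# Conditional draw: keep x when it lies in the feasible interval, otherwise
# redraw from the calibrated distribution restricted to that interval (the
# interval is intersected with the support; empty intersections return NA).
.draw_restricted <- function(par, x, lo2 = -Inf, hi2 = Inf) {
  lo2 <- max(lo2, exp(par$llo)); hi2 <- min(hi2, exp(par$lhi))
  if (lo2 > hi2) return(NA_real_)
  if (x >= lo2 && x <= hi2) return(x)
  plo <- stats::pnorm((log(lo2) - par$mu) / par$s)
  phi <- stats::pnorm((log(hi2) - par$mu) / par$s)
  exp(par$mu + par$s * stats::qnorm(plo + stats::runif(1) * (phi - plo)))
}

#' Generate a synthetic cohort of theoretical children
#'
#' Builds the database of "known values": each child receives a full-variant
#' compartmental model with assigned total body stores (TBS), plasma retinol
#' pool, dietary vitamin A intake and kinetic coefficients, with the
#' disposal coefficient `L(10,6) = absorption * intake / TBS` and the
#' mobilisation coefficient `L(5,6) = L(6,5) * M5 / TBS - L(10,6)` derived
#' from the steady-state balance.  In the `high_intake_50` preset 23 children
#' carry one extravascular pool and 27 carry two; the `low_intake_10` preset
#' gives 10 children with low-to-moderate intakes and low stores (5/5 split).
#'
#' @param preset `"high_intake_50"` (default) or `"low_intake_10"`.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical and the caller's RNG state is left untouched.
#' @return An object of class `cohort`: a list with `children` (one row per
#'   child), `preset` and `seed`.
#' @examples
#' coh <- generate_cohort("high_intake_50", seed = 1)
#' table(coh$children$variant_pools)
#' exp(mean(log(coh$children$tbs_umol)))
#' @export
generate_cohort <- function(preset = c("high_intake_50", "low_intake_10"),
                            seed) {
  preset <- match.arg(preset)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for cohort generation", call. = FALSE)
  .with_seed(seed, .generate_cohort_impl(preset, seed))
}

.generate_cohort_impl <- function(preset, seed) {
  n <- if (preset == "high_intake_50") 50L else 10L
  n_two <- if (preset == "high_intake_50") 27L else 5L
  tab <- .param_table(preset)
  rng <- .derived_ranges(preset)
  m5_rng <- tab$m5[c("lo", "hi")]
  l75_rng <- tab$l75[c("lo", "hi")]

  # stratified first-pass draws; fast-pool coefficients are assigned (and
  # stratified) over the two-pool children only
  pars <- lapply(tab[setdiff(names(tab), c("l75", "l57"))],
                 .sample_param, n = n)
  draw <- lapply(pars, `[[`, "x")
  pars$l75 <- .sample_param(n_two, tab$l75)
  pars$l57 <- .sample_param(n_two, tab$l57)
  absorption <- stats::runif(n, 0.70, 0.90)
  bw <- stats::runif(n, 8.5, 20.5)
  two_pool <- seq_len(n) %in% sample.int(n, n_two)
  l75_all <- l57_all <- rep(NA_real_, n)
  l75_all[two_pool] <- pars$l75$x
  l57_all[two_pool] <- pars$l57$x

  kids <- vector("list", n)
  for (i in seq_len(n)) {
    tbs <- draw$tbs[i]; a <- absorption[i]
    dt3 <- draw$dt3[i]; l21 <- draw$l21[i]; l32 <- draw$l32[i]
    # intake such that the derived disposal coefficient stays in range
    intake <- .draw_restricted(pars$intake, draw$intake[i],
                               rng$l106[1] * tbs / a, rng$l106[2] * tbs / a)
    l106 <- a * intake / tbs
    # plasma exchange: restrict L(6,5), then M(5), so that the derived
    # mobilisation coefficient L(5,6) falls in range
    l65 <- .draw_restricted(pars$l65, draw$l65[i],
                            (l106 + rng$l56[1]) * tbs / m5_rng[["hi"]],
                            (l106 + rng$l56[2]) * tbs / m5_rng[["lo"]])
    m5 <- .draw_restricted(pars$m5, draw$m5[i],
                           (l106 + rng$l56[1]) * tbs / l65,
                           (l106 + rng$l56[2]) * tbs / l65)
    l56 <- l65 * m5 / tbs - l106
    # fast pool: restrict L(5,7), then L(7,5), so M(7) falls in range
    if (two_pool[i]) {
      l57 <- .draw_restricted(pars$l57, l57_all[i],
                              l75_rng[["lo"]] * m5 / rng$m7[2],
                              l75_rng[["hi"]] * m5 / rng$m7[1])
      l75 <- .draw_restricted(pars$l75, l75_all[i],
                              rng$m7[1] * l57 / m5, rng$m7[2] * l57 / m5)
      m7 <- l75 * m5 / l57
    } else {
      l57 <- l75 <- NA_real_; m7 <- 0
    }
    # hepatic turnover completes the sojourn-time window
    lag <- dt3 + 1 / l21 + 1 / l32
    l54 <- .draw_restricted(pars$l54, draw$l54[i],
                            1 / (rng$mst[2] - lag),
                            if (rng$mst[1] > lag) 1 / (rng$mst[1] - lag)
                            else Inf)
    mst <- lag + 1 / l54
    vals <- c(intake, l65, m5, l54, if (two_pool[i]) c(l57, l75))
    if (anyNA(vals))
      stop("could not assign steady-state-consistent values for child ", i)
    kids[[i]] <- data.frame(
      id = i, variant_pools = if (two_pool[i]) 2L else 1L,
      tbs_umol = tbs, m5_umol = m5, m7_umol = m7,
      intake_umol_d = intake,
      intake_ug_rae = intake * .UG_RAE_PER_UMOL,
      body_weight_kg = bw[i], absorption = a,
      dt3_d = dt3, l21 = l21, l32 = l32, l54 = l54, l65 = l65,
      l56 = l56, l106 = l106,
      l75 = if (two_pool[i]) l75 else NA_real_,
      l57 = if (two_pool[i]) l57 else NA_real_,
      mst_rbp_d = mst,
      liver_umol_g = liver_concentration(tbs, bw[i]))
  }
  structure(list(children = do.call(rbind, kids),
                 preset = preset, seed = as.integer(seed)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ch <- x$children
  cat(sprintf("<cohort> preset %s, %d children (seed %d)\n",
              x$preset, nrow(ch), x$seed))
  cat(sprintf("  pools: %d one-pool / %d two-pool\n",
              sum(ch$variant_pools == 1), sum(ch$variant_pools == 2)))
  cat(sprintf("  TBS gm %.0f umol (range %.0f-%.0f); intake gm %.0f ug RAE/d\n",
              exp(mean(log(ch$tbs_umol))), min(ch$tbs_umol), max(ch$tbs_umol),
              exp(mean(log(ch$intake_ug_rae)))))
  invisible(x)
}

#' Model specification of one cohort child
#'
#' Returns the full-variant [model_spec()] carrying the child's assigned
#' transfer coefficients (the generating, "known-value" model).
#'
#' @param cohort a [generate_cohort()] result.
#' @param id child identifier (row of `cohort$children`).
#' @return A `model_spec`.
#' @export
child_spec <- function(cohort, id) {
  stopifnot(inherits(cohort, "cohort"))
  ch <- cohort$children[cohort$children$id == id, ]
  if (nrow(ch) != 1) stop("unknown child id ", id, call. = FALSE)
  two <- ch$variant_pools == 2L
  model_spec("full", DT3 = ch$dt3_d, absorption = ch$absorption,
             L21 = ch$l21, L32 = ch$l32, L54 = ch$l54, L65 = ch$l65,
             L56 = ch$l56, L106 = ch$l106,
             L75 = if (two) ch$l75, L57 = if (two) ch$l57)
}

#' Simulate one child's true ("observed") tracer curve
#'
#' Delegates to [simulate_tracer()] with the child's own generating model.
#'
#' @inheritParams child_spec
#' @param times sampling times in days.
#' @return A [tracer_curve()].
#' @export
child_truth_curve <- function(cohort, id, times) {
  simulate_tracer(child_spec(cohort, id), times)
}

#' Per-child tracer curves as a matrix
#'
#' Simulates the true plasma tracer response of every child in the cohort at
#' the given times.
#'
#' @inheritParams child_truth_curve
#' @return A numeric matrix, children x times, of fractions of dose in
#'   plasma; row names are child ids.
#' @export
cohort_curves <- function(cohort, times) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- cohort$children$id
  out <- vapply(ids, function(id)
    simulate_tracer(child_spec(cohort, id), times)$fdp,
    numeric(length(times)))
  out <- if (length(times) == 1L) matrix(out, ncol = 1L) else t(out)
  dimnames(out) <- list(ids, times)
  out
}

#' Liver vitamin A concentration implied by total body stores
#'
#' Assumes the liver is 3% of body weight and holds 80% of total body
#' vitamin A.
#'
#' @param TBS total body stores, µmol (>= 0).
#' @param body_weight body weight, kg (> 0).
#' @return Liver vitamin A concentration, µmol per g liver.
#' @examples
#' liver_concentration(538, 12)
#' @export
liver_concentration <- function(TBS, body_weight) {
  if (any(TBS < 0) || any(body_weight <= 0))
    stop("TBS must be >= 0 and body_weight > 0", call. = FALSE)
  0.80 * TBS / (0.03 * body_weight * 1000)
}

#' Write or read a cohort as delimited text plus a manifest
#'
#' The children table is written as tab-separated text (one row per child,
#' one column per parameter or state variable) and a small JSON manifest
#' records the preset, seed and generator version.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path path of the children table; the manifest is written next to
#'   it as `<path>.manifest.json`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  con <- file(path, "w")
  writeLines(paste("# theoretical-child cohort; masses umol, intake umol/d",
                   "and ug RAE/d, times d, coefficients /d"), con)
  utils::write.table(cohort$children, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  jsonlite::write_json(
    list(preset = cohort$preset, seed = cohort$seed,
         n_children = nrow(cohort$children),
         generator = paste0("superchild ",
                            as.character(utils::packageVersion("superchild")))),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  ch <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  structure(list(children = ch, preset = man$preset,
                 seed = as.integer(man$seed)),
            class = "cohort")
}
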