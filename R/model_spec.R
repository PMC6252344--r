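#' Compartmental model specification for whole-body retinol kinetics
#'
#' Defines the linear compartmental system used throughout the package: an
#' oral dose enters a pre-hepatic processing chain (gut compartment 1,
#' chylomicron compartment 2, a pure transport delay, hepatic compartment 4),
#' is secreted into plasma (compartment 5, bound to retinol-binding protein),
#' and exchanges with one or two extravascular pools: the slowly turning-over
#' storage pool (compartment 6, vitamin A total body stores, the site of
#' irreversible disposal) and optionally a faster turning-over tissue pool
#' (compartment 7).  The `simplified` variant omits compartments 1 and 2 and
#' places the oral input directly into the delay; it is the form used to fit
#' reduced data sets in which early (<1 d) samples are sparse.
#'
#' Fractional transfer coefficients follow the `L(I,J)` convention: the
#' fraction of compartment J's content transferred to compartment I per day.
#' Disposal is `L(10,6)`, with "compartment" 10 a notational sink.  The delay
#' is exact (content entering the delay re-emerges `DT3` days later); the
#' unabsorbed fraction `1 - absorption` of the dose is discarded at delay
#' exit.
#'
#' @param variant `"full"` (compartments 1, 2, delay, 4, 5, 6, optional 7) or
#'   `"simplified"` (delay, 4, 5, 6, optional 7).
#' @param L optionally, a named numeric vector of transfer coefficients using
#'   names such as `"L(6,5)"`; overrides the individual arguments below.
#' @param DT3 delay time of the transport delay, days (> 0).
#' @param absorption fraction of the oral dose absorbed, in (0, 1].
#' @param L21,L32 gut-to-chylomicron and chylomicron-to-delay coefficients,
#'   per day (full variant only).
#' @param L54 hepatic secretion coefficient, per day.
#' @param L65 plasma-to-stores coefficient, per day.
#' @param L56 stores-to-plasma mobilisation coefficient, per day.
#' @param L106 fractional catabolic (disposal) coefficient of the storage
#'   pool, per day.
#' @param L75,L57 plasma/fast-pool exchange coefficients, per day; supply
#'   both for a two-extravascular-pool model, omit both (or set both to
#'   zero) for a one-pool model.
#'
#' @return An object of class `model_spec` with elements `variant`,
#'   `n_extravascular` (1 or 2), `L` (named coefficient vector), `DT3`,
#'   `absorption` and `input_site` (compartment 1 for the full variant,
#'   the delay component 3 for the simplified one).
#' @examples
#' spec <- model_spec("simplified", DT3 = 0.3, L54 = 5, L65 = 30.1,
#'                    L56 = 0.0502, L106 = 0.00597)
#' spec
#' @seealso [simulate_tracer()], [steady_state()], [mst_rbp()]
#' @export
model_spec <- function(variant = c("full", "simplified"),
                       L = NULL, DT3, absorption = 0.80,
                       L21 = NULL, L32 = NULL, L54 = NULL, L65 = NULL,
                       L56 = NULL, L106 = NULL, L75 = NULL, L57 = NULL) {
  variant <- match.arg(variant)
  if (!is.null(L)) {
    lget <- function(nm) if (nm %in% names(L)) unname(L[[nm]]) else NULL
    L21 <- lget("L(2,1)"); L32 <- lget("L(3,2)"); L54 <- lget("L(5,4)")
    L65 <- lget("L(6,5)"); L56 <- lget("L(5,6)"); L106 <- lget("L(10,6)")
    L75 <- lget("L(7,5)"); L57 <- lget("L(5,7)")
  }
  # both zero encodes an absent fast pool (avoids an ill-conditioned system)
  if (!is.null(L75) && !is.null(L57) && L75 == 0 && L57 == 0) {
    L75 <- NULL; L57 <- NULL
  }
  two_pool <- !is.null(L75) || !is.null(L57)
  if (two_pool && (is.null(L75) || is.null(L57)))
    stop("a two-pool model requires both L(7,5) and L(5,7)", call. = FALSE)

  req <- c("L(5,4)" = "L54", "L(6,5)" = "L65", "L(5,6)" = "L56",
           "L(10,6)" = "L106")
  if (variant == "full") req <- c("L(2,1)" = "L21", "L(3,2)" = "L32", req)
  vals <- list(L21 = L21, L32 = L32, L54 = L54, L65 = L65, L56 = L56,
               L106 = L106, L75 = L75, L57 = L57)
  for (nm in names(req)) {
    v <- vals[[req[[nm]]]]
    if (is.null(v) || is.na(v))
      stop("missing required transfer coefficient ", nm, call. = FALSE)
  }
  coefs <- c("L(5,4)" = L54, "L(6,5)" = L65, "L(5,6)" = L56, "L(10,6)" = L106)
  if (variant == "full") coefs <- c("L(2,1)" = L21, "L(3,2)" = L32, coefs)
  if (two_pool) coefs <- c(coefs, "L(7,5)" = L75, "L(5,7)" = L57)
  if (any(coefs <= 0))
    stop("all transfer coefficients must be > 0; offending: ",
         paste(names(coefs)[coefs <= 0], collapse = ", "), call. = FALSE)
  if (missing(DT3) || is.null(DT3) || !is.finite(DT3) || DT3 <= 0)
    stop("DT3 (delay time, days) must be > 0", call. = FALSE)
  if (!is.finite(absorption) || absorption <= 0 || absorption > 1)
    stop("absorption must lie in (0, 1]", call. = FALSE)

  structure(
    list(variant = variant,
         n_extravascular = if (two_pool) 2L else 1L,
         L = coefs, DT3 = DT3, absorption = absorption,
         input_site = if (variant == "full") 1L else 3L),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s variant, %d extravascular pool(s)\n",
              x$variant, x$n_extravascular))
  cat(sprintf("  DT3 = %g d, absorption = %g, oral input into compartment %d\n",
              x$DT3, x$absorption, x$input_site))
  cat("  ", paste(sprintf("%s = %g/d", names(x$L), x$L), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# internal accessor: coefficient by "L(I,J)" name, default if absent
.lc <- function(spec, nm, default = NA_real_) {
  if (nm %in% names(spec$L)) unname(spec$L[[nm]]) else default
}

.is_two_pool <- function(spec) spec$n_extravascular == 2L

#' Serialise or read a model specification as structured text
#'
#' Writes `key: value` lines (coefficient keys in the `L(I,J)` style, values
#' per day) so that specifications can be exchanged between pipeline stages
#' as plain text.
#'
#' @param spec a [model_spec()].
#' @param path file path.
#' @return `write_model_spec()` returns `path` invisibly; `read_model_spec()`
#'   returns a `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  lines <- c(paste0("variant: ", spec$variant),
             paste0("DT3: ", format(spec$DT3, digits = 17)),
             paste0("absorption: ", format(spec$absorption, digits = 17)),
             paste0(names(spec$L), ": ", vapply(spec$L, format, "",
                                                digits = 17)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.+?)\\s*$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  variant <- vals[keys == "variant"]
  num <- function(k) as.numeric(vals[keys == k])
  Lks <- grep("^L\\(", keys, value = TRUE)
  L <- stats::setNames(vapply(Lks, num, 0), Lks)
  model_spec(variant = variant, L = L, DT3 = num("DT3"),
             absorption = num("absorption"))
}

#' Plasma tracer response container
#'
#' A `tracer_curve` holds the fraction of the administered oral dose present
#' in plasma (`fdp`) at a set of sampling times, together with the number of
#' subjects contributing at each time (`n`, 1 for an individual curve, the
#' contributing subject count for a composite geometric-mean curve).
#'
#' @param times sampling times in days, strictly increasing and > 0.
#' @param fdp fraction of dose in plasma at each time, in `[0, 1)`.
#' @param n integer subjects per time (recycled).
#' @return A data frame of class `tracer_curve` with columns `time_d`,
#'   `fdp`, `n`.
#' @export
tracer_curve <- function(times, fdp, n = 1L) {
  if (length(times) == 0 || any(diff(times) <= 0) || any(times <= 0))
    stop("times must be strictly increasing and > 0", call. = FALSE)
  if (length(fdp) != length(times))
    stop("times and fdp must have equal length", call. = FALSE)
  if (any(fdp < 0 | fdp >= 1))
    stop("fdp must satisfy 0 <= fdp < 1", call. = FALSE)
  n <- rep_len(as.integer(n), length(times))
  if (any(n < 1L)) stop("n must be >= 1 at every time", call. = FALSE)
  structure(data.frame(time_d = times, fdp = fdp, n = n),
            class = c("tracer_curve", "data.frame"))
}

#' Write or read a tracer curve as delimited text
#'
#' Columns `time_d`, `fdp`, `n`, tab-separated, with a comment header naming
#' units.
#'
#' @param curve a [tracer_curve()].
#' @param path file path.
#' @return `write_tracer_curve()` returns `path` invisibly;
#'   `read_tracer_curve()` returns a `tracer_curve`.
#' @export
write_tracer_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_d: days post dose; fdp: fraction of dose in plasma; n: subjects per time",
             con)
  utils::write.table(as.data.frame(curve), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracer_curve
#' @export
read_tracer_curve <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  tracer_curve(d$time_d, d$fdp, d$n)
}
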