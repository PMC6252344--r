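# Canonical model specifications built from the published geometric-mean
# kinetic values, used across the test files.

gm <- function(x) exp(mean(log(x)))

spec_simplified_1p <- function() {
  model_spec("simplified", DT3 = 0.3, L54 = 5, L65 = 30.1,
             L56 = 0.0502, L106 = 0.00597, absorption = 0.8)
}

spec_simplified_2p <- function() {
  model_spec("simplified", DT3 = 0.3, L54 = 5, L65 = 30.1,
             L56 = 0.0502, L106 = 0.00597, L75 = 31.9, L57 = 1.67,
             absorption = 0.8)
}

spec_full_2p <- function() {
  model_spec("full", DT3 = 0.3, L21 = 50, L32 = 50, L54 = 5, L65 = 30.1,
             L56 = 0.0502, L106 = 0.00597, L75 = 31.9, L57 = 1.67,
             absorption = 0.8)
}

# random valid specification drawn from broad physiologic ranges
random_spec <- function(variant = sample(c("full", "simplified"), 1),
                        two_pool = sample(c(TRUE, FALSE), 1)) {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  model_spec(variant,
             DT3 = stats::runif(1, 0.08, 0.4),
             absorption = stats::runif(1, 0.7, 0.9),
             L21 = if (variant == "full") r(20, 100),
             L32 = if (variant == "full") r(20, 100),
             L54 = r(1.2, 10), L65 = r(20, 40),
             L56 = r(0.015, 0.12), L106 = r(0.002, 0.05),
             L75 = if (two_pool) r(5, 60),
             L57 = if (two_pool) r(0.4, 3.75))
}

reduced11 <- function() schedule_times("reduced11")
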