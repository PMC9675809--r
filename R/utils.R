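#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt sd cov aov anova lm rnorm runif rbinom rlnorm quantile
#'   cor t.test plogis qlogis
#' @importFrom utils combn write.table read.table
NULL

# condition constructor used throughout so callers can test on error class
.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "megseqmem_error")))
}

.assert <- function(cond, msg, class = "megseqmem_invalid") {
  if (!isTRUE(cond)) .err(msg, class)
}

#' Derive a stream of child seeds from a master seed
#'
#' Deterministic seed spawning: child seeds are drawn once from the master
#' seed's RNG stream, so adding subjects or stages never perturbs earlier ones.
#'
#' @param master_seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` distinct seeds in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# vectorised paired / one-sample t over arrays: x is subjects x cells
# returns list(t, p, df, degenerate) with degenerate = zero-variance cells
.mass_t <- function(x) {
  n <- nrow(x)
  .assert(n >= 2, "at least 2 subjects are required for a t-test",
          "too_few_subjects")
  m <- colMeans(x)
  s <- sqrt(colSums(sweep(x, 2, m)^2) / (n - 1))
  degen <- s == 0
  tval <- ifelse(degen, ifelse(m == 0, 0, NA_real_), m / (s / sqrt(n)))
  pval <- ifelse(is.na(tval), NA_real_, 2 * pt(-abs(tval), df = n - 1))
  pval[degen & m == 0] <- 1
  list(t = tval, p = pval, df = n - 1, degenerate = degen)
}

# condition labels used across the package
.conditions <- c("memorized_tonal", "novel_tonal",
                 "memorized_atonal", "novel_atonal")
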