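# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

hk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hyperkin_error", "error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_nonneg <- function(x, name) {
  if (!is_number(x) || x < 0)
    hk_stop(sprintf("'%s' must be a single finite non-negative number", name),
            "hyperkin_param_error")
  x
}

check_pos <- function(x, name) {
  if (!is_number(x) || x <= 0)
    hk_stop(sprintf("'%s' must be a single finite positive number", name),
            "hyperkin_param_error")
  x
}

#' Standard error of the mean
#' @param x numeric vector
#' @return numeric scalar; `NA` for length-1 input
#' @export
se <- function(x) stats::sd(x) / sqrt(length(x))

# Henderson-Hasselbalch deprotonated fraction of a fluorophore with the
# given pKa; only the deprotonated state is taken as fluorescent.
protonation_factor <- function(pH, pKa) 1 / (1 + 10^(pKa - pH))

# Evaluate a block with a locally-set RNG seed, restoring the caller's RNG
# state afterwards so simulation calls do not perturb the session stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lognormal multipliers with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
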