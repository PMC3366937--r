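#' @importFrom stats aggregate anova as.formula binomial coef cor dnorm glm
#'   glm.fit lm median pchisq pnorm qbeta qchisq quantile rbinom rmultinom
#'   rnorm runif sd setNames uniroot var vcov
#' @importFrom utils combn read.table write.table head
NULL

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed_ <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hapghost <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hapghost_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# population-variance (denominator n)
var_pop <- function(x) mean((x - mean(x))^2)

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "g")
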