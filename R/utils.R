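#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov dist mad mahalanobis median prcomp predict qchisq
#'   pchisq quantile rbeta rbinom rnorm rpois runif sd setNames var aov TukeyHSD
#'   complete.cases qlogis plogis cmdscale coef lm resid
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kilometres per degree of arc on the reference sphere (R = 6371 km)
#' @noRd
KM_PER_DEG <- pi * 6371 / 180

abort_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

#' Evaluate code with a locally seeded RNG, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed and a stage label (stays below 2^31)
#' @noRd
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}
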