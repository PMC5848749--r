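#' @importFrom rlang .data abort warn inform
#' @importFrom stats median quantile rnorm runif rbinom rpois rlnorm rgamma
#'   pnorm qnorm cor setNames complete.cases
#' @importFrom utils modifyList
NULL

# Deterministic sub-seed for a named random substream. All generator
# randomness flows from config$seed through these, so partial reruns of a
# single generator reproduce exactly. Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

stop_dietcost <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dietcost_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
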