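# Shared numeric helpers. All sequence scoring is done in log space;
# logsumexp uses the usual max-shift for stability.

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) {
  stop(structure(class = c("harkit_contract_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("harkit_degenerate_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("harkit_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_that <- function(cond, ...) if (!isTRUE(cond)) stop_contract(...)

# deterministic RNG scoping: run `expr` under a seed without clobbering the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
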