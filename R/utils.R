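#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers can distinguish validation from
# runtime failures.
fc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fjordconnect_error")))
}

fc_assert <- function(cond, msg, class = "fc_validation_error") {
  if (!isTRUE(cond)) fc_stop(msg, class)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a child RNG seed from a base seed and a stream label, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Canonical unordered pair key "a|b" with a < b lexicographically.
pair_key <- function(a, b) {
  swap <- a > b
  key <- paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
  key
}
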