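# internal helpers shared across modules

# deterministic sub-seed derivation; result always in [1, 2^31 - 2] so it is
# a valid 32-bit seed for set.seed()
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (abs(as.double(seed)) * 2654435761 + as.double(index) * 40503 + 11) %%
    2147483646
  as.integer(s) + 1L
}

# evaluate expr with a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# locale-independent ordering: descending score, ties by identifier
order_desc_ties_by_id <- function(score, id) {
  order(-score, id, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable 31-bit hash of a string (polynomial rolling hash); used to key
# permutation sub-streams on set identity rather than evaluation order
string_hash <- function(x) {
  h <- 7
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_fmt("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}
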