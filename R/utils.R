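# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(code)
}

# Derive a child seed from a base seed and a label; kept below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 1103L + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical undirected edge key "a|b" with a < b lexicographically.
edge_key <- function(a, b) {
  swap <- a > b
  ifelse(swap, paste(b, a, sep = "\r"), paste(a, b, sep = "\r"))
}

# Top-fraction selection: rank by value descending (direction "top") or
# ascending ("bottom"); ties broken by id ascending; exactly ceiling(f*n) ids.
top_fraction_ids <- function(ids, values, fraction, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  stopifnot(length(ids) == length(values))
  keep <- !is.na(values)
  ids <- ids[keep]; values <- values[keep]
  if (length(ids) == 0L) return(character(0))
  ord <- if (direction == "top") {
    order(-values, ids)
  } else {
    order(values, ids)
  }
  n_sel <- ceiling(fraction * length(ids))
  ids[ord][seq_len(n_sel)]
}

# Empirical p-value with +1 correction: r exceedances out of n_rand draws.
empirical_p <- function(r, n_rand) (r + 1) / (n_rand + 1)
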