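# Seed handling: every stochastic entry point takes one integer seed and
# derives independent child streams from it, so sequence masking, point
# masking, cropping etc. are reproducible yet decoupled.

# splitmix-style integer mixer; keeps results in [0, 2^31 - 1]
.mix_seed <- function(seed, stream) {
  x <- (as.double(seed) * 2654435761 + as.double(stream) * 40503 + 97) %%
    2147483647
  as.integer(x)
}

#' Derive a child seed for a named stream
#' @param seed Integer run seed.
#' @param stream Character stream label (hashed into the child seed).
#' @export
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  .mix_seed(seed, h)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a serialized object, as 8 hex chars; used to stamp configs
# into checkpoints and score-table metadata.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# ---- small tree (nested list of numeric arrays) utilities for parameters ----

tree_map <- function(f, tree, ...) {
  if (is.list(tree)) {
    others <- list(...)
    out <- vector("list", length(tree))
    names(out) <- names(tree)
    for (i in seq_along(tree)) {
      sub_others <- lapply(others, `[[`, i)
      out[[i]] <- do.call(tree_map, c(list(f, tree[[i]]), sub_others))
    }
    out
  } else {
    do.call(f, c(list(tree), list(...)))
  }
}

tree_sum <- function(f, tree) {
  if (is.list(tree)) sum(vapply(tree, function(t) tree_sum(f, t), 0.0))
  else f(tree)
}

# zero tree with the same shapes
tree_zeros <- function(tree) tree_map(function(a) a * 0, tree)

tree_add <- function(a, b) tree_map(function(x, y) x + y, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

tree_global_norm <- function(tree) sqrt(tree_sum(function(a) sum(a^2), tree))
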