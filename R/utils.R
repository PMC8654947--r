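# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stopf(...)

# Union-find over 1..n; returns component id per element.
components_from_pairs <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Cosine distance between rows of X with pairwise-complete handling of NAs.
# Rows with fewer than `min_obs` observed values are not usable.
cosine_dist <- function(x, min_obs = 2L) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      if (sum(ok) < min_obs) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      a <- x[i, ok]; b <- x[j, ok]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      d[i, j] <- d[j, i] <- if (na == 0 || nb == 0) NA_real_ else {
        1 - sum(a * b) / (na * nb)
      }
    }
  }
  d
}

# Euclidean pairwise-complete distance (scaled to full length like stats::dist).
euclidean_dist <- function(x) {
  as.matrix(stats::dist(x))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}
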