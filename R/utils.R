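# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed (if any) is restored afterwards so generators do not disturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# All permutations of 1..n as an n! x n integer matrix, lexicographic order.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, unname(out))
}

# Bit index (0-based) of vertex pair (i, j), i < j, within a k-node mask.
# Pairs are ordered column-wise: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4),...
pair_bit <- function(i, j) {
  ifelse(i < j, (j - 1L) * (j - 2L) / 2L + i - 1L, (i - 1L) * (i - 2L) / 2L + j - 1L)
}

# Pair table for subgraphs on k nodes: rows (i, j, bit).
pair_table <- function(k) {
  ij <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  ij <- ij[order(ij[, 2L], ij[, 1L]), , drop = FALSE]
  cbind(i = ij[, 1L], j = ij[, 2L], w = 2^(seq_len(nrow(ij)) - 1L))
}

# Apply a vertex permutation to an adjacency bitmask on k nodes.
permute_mask <- function(mask, perm, pt) {
  bits <- bitwAnd(mask %/% pt[, "w"], 1L)
  m <- 0
  for (r in which(bits == 1L)) {
    a <- perm[pt[r, "i"]]; b <- perm[pt[r, "j"]]
    m <- m + 2^pair_bit(min(a, b), max(a, b))
  }
  m
}

mask_to_edges <- function(mask, k) {
  pt <- pair_table(k)
  bits <- bitwAnd(mask %/% pt[, "w"], 1L)
  cbind(pt[bits == 1L, "i"], pt[bits == 1L, "j"])
}

mask_is_connected <- function(mask, k) {
  e <- mask_to_edges(mask, k)
  if (k == 1L) return(TRUE)
  seen <- rep(FALSE, k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  all(seen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
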