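# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# expected species count in a random m-subset of individuals, by exhaustive
# enumeration of all C(n, m) subsets
brute_rarefy <- function(x, m) {
  ind <- rep(seq_along(x), x)
  subs <- utils::combn(length(ind), m)
  mean(apply(subs, 2, function(ix) length(unique(ind[ix]))))
}

# class-pair adjacency tally by looping over every unordered cell pair
brute_adjacency <- function(grid, K, zone = NULL) {
  nr <- nrow(grid); nc <- ncol(grid)
  if (is.null(zone)) zone <- matrix(TRUE, nr, nc)
  tal <- matrix(0, K, K)
  cells <- which(!is.na(grid) & zone)
  if (length(cells) < 2) return(tal)
  for (a in seq_along(cells)) {
    for (b in seq_along(cells)) {
      if (b <= a) next
      i <- cells[a]; j <- cells[b]
      ri <- (i - 1) %% nr + 1; ci <- (i - 1) %/% nr + 1
      rj <- (j - 1) %% nr + 1; cj <- (j - 1) %/% nr + 1
      if (abs(ri - rj) + abs(ci - cj) == 1) {
        p <- min(grid[i], grid[j]); q <- max(grid[i], grid[j])
        tal[p, q] <- tal[p, q] + 1
      }
    }
  }
  tal + t(tal) - diag(diag(tal), K)
}

# all integer partitions of n (abundance vectors, order-free)
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - k, k)) out[[length(out) + 1]] <- c(k, rest)
  }
  out
}

# tiny land_raster with legend A, B, C, ... over the codes present
toy_raster <- function(m, K = max(m, na.rm = TRUE), cell_size = 100) {
  land_raster(m, stats::setNames(LETTERS[seq_len(K)], seq_len(K)), cell_size)
}

# random abundance sample with guaranteed singletons/doubletons variety
random_sample <- function(S = 20, lambda = 3) {
  x <- stats::rpois(S, lambda) + 1L
  stats::setNames(x, sprintf("sp%02d", seq_len(S)))
}
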