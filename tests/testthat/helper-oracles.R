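# Independent oracles, kept deliberately naive.

# Strip everything but dim so matrices compare on content alone.
bare <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# Brute-force queue-based flood fill. Labels are numbered by first occurrence
# in column-major order, the same canonical order the package uses, so label
# matrices can be compared directly.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  nbr <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      k <- k + 1L
      queue <- list(c(i, j))
      lab[i, j] <- k
      while (length(queue) > 0) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in seq_len(nrow(nbr))) {
          r <- p[1] + nbr[d, 1]; c <- p[2] + nbr[d, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- k
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Monte-Carlo permutation p-value for a one-way ANOVA F statistic.
perm_anova_p <- function(y, g, B = 2000) {
  fstat <- function(yy) {
    summary(stats::aov(yy ~ g))[[1]]$`F value`[1]
  }
  f0 <- fstat(y)
  hits <- sum(replicate(B, fstat(sample(y))) >= f0)
  (hits + 1) / (B + 1)
}
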