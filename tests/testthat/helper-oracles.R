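# independent brute-force oracles used across tests; deliberately naive
# O(n^2) / enumeration implementations that never touch the package's own
# code paths

# per-query best overlap fraction against every subject interval
# (all-pairs O(n^2); the inner comparison is vectorised over subjects)
oracle_best_overlap <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- query$chrom[i] == subject$chrom
    if (!is.null(query$strand) && !is.null(subject$strand)) {
      same <- same & query$strand[i] == subject$strand
    }
    ov <- pmax(0, pmin(query$end[i], subject$end) -
                 pmax(query$start[i], subject$start))
    ov[!same] <- 0
    if (nrow(subject) == 0) 0 else
      max(ov) / (query$end[i] - query$start[i])
  }, numeric(1))
}

# earliest prior stage with overlap > cutoff, else own stage
oracle_origin <- function(stage_peaks, cutoff = 0.5) {
  stages <- names(stage_peaks)
  out <- list()
  for (i in seq_along(stages)) {
    pk <- stage_peaks[[i]]
    origin <- rep(stages[i], nrow(pk))
    for (r in seq_len(nrow(pk))) {
      for (j in seq_len(i - 1)) {
        if (oracle_best_overlap(pk[r, , drop = FALSE],
                                stage_peaks[[j]]) > cutoff) {
          origin[r] <- stages[j]
          break
        }
      }
    }
    out[[stages[i]]] <- origin
  }
  out
}

# exact Mann-Whitney by enumeration of all group assignments (small n)
oracle_mann_whitney <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_of)
  mu <- nx * ny / 2
  # two-sided p: probability of a U at least as extreme (about the mean)
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# least-squares decay rate by brute-force grid search with free intercept
oracle_grid_k <- function(times, abundances, k_grid = seq(0, 5, 1e-4)) {
  y <- log(abundances / abundances[match(0, times)])
  sse <- vapply(k_grid, function(k) {
    b <- mean(y + k * times)
    sum((y - (b - k * times)) ^ 2)
  }, numeric(1))
  k_grid[which.min(sse)]
}

# OLS slope/intercept via explicit normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# all DRACH 5-mer start positions by exhaustive enumeration
oracle_drach <- function(seq) {
  seq <- chartr("Uu", "TT", toupper(seq))
  D <- c("A", "G", "T"); R <- c("A", "G"); H <- c("A", "C", "T")
  chars <- strsplit(seq, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(max(0, length(chars) - 4))) {
    w <- chars[i:(i + 4)]
    if (w[1] %in% D && w[2] %in% R && w[3] == "A" && w[4] == "C" &&
        w[5] %in% H) {
      hits <- c(hits, i)
    }
  }
  hits
}

# random peak tibble on a small genome
random_peaks <- function(n, chroms = c("chr1", "chr2"), span = 1e5,
                         width = c(50, 300)) {
  w <- sample(width[1]:width[2], n, replace = TRUE)
  s <- sample.int(span, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = s, end = s + w,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = sprintf("g%04d", sample.int(500, n, replace = TRUE))
  )
}
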