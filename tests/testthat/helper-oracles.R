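# Independent oracles used across the suite. Each re-derives a result
# by a different route than the implementation under test.

# Brute-force trypsin rule: walk the sequence, cut after K/R unless the
# next residue is P, then assemble peptides for every missed-cleavage
# count by direct concatenation.
oracle_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut_after <- logical(n)
  for (i in seq_len(n)) {
    cut_after[i] <- chars[i] %in% c("K", "R") &&
      (i == n || chars[i + 1] != "P")
  }
  cut_after[n] <- TRUE
  ends <- which(cut_after)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (m in 0:max_missed) {
    for (i in seq_along(starts)) {
      j <- i + m
      if (j > length(ends)) next
      out[[length(out) + 1]] <- data.frame(
        peptide = paste(chars[starts[i]:ends[j]], collapse = ""),
        start = starts[i], end = ends[j], missed_cleavages = m)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$missed_cleavages), ]
}

# Textbook pooled-variance two-sample t-test.
oracle_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t_stat), df = nx + ny - 2)
}

# Closed-form rigid-body fit via unit quaternions (Horn 1987), an
# independent route to the optimal rotation used by Kabsch/SVD.
oracle_rigid_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  M <- crossprod(P0, Q0)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- P0 %*% t(R)
  sqrt(mean(rowSums((fitted - Q0)^2)))
}

# Bayes-optimal classification accuracy for two isotropic Gaussian
# clouds, measured by Monte Carlo on supplied samples: the optimal rule
# assigns a point to the nearer true mean.
oracle_bayes_accuracy <- function(Xa, Xb, mu_a, mu_b) {
  da <- function(X, mu) rowSums(sweep(X, 2, mu)^2)
  acc_a <- mean(da(Xa, mu_a) < da(Xa, mu_b))
  acc_b <- mean(da(Xb, mu_b) < da(Xb, mu_a))
  mean(c(acc_a, acc_b))
}

rigid_rotate_z90 <- function(X, translation = c(5, -3, 2)) {
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(X %*% t(R), 2, translation, "+")
}
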