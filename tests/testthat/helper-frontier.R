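# Independent exhaustive-search oracle for the monotone staircase frontier.
# Enumerates every monotone non-increasing threshold sequence over the same
# candidate set (mid-gaps plus infinite sentinels) and scores it directly:
# minimize misclassified points, break ties by maximal total margin, then
# by the reverse-lexicographically highest staircase.

oracle_frontier <- function(points) {
  cols <- sort(unique(points$precipitant))
  p <- sort(unique(points$protein))
  mids <- if (length(p) >= 2) (p[-1] + p[-length(p)]) / 2 else numeric(0)
  tvals <- c(-Inf, mids, Inf)
  K <- length(tvals)
  n <- length(cols)

  mis <- matrix(0, n, K)
  mar <- matrix(0, n, K)
  for (i in seq_len(n)) {
    sel <- points$precipitant == cols[i]
    pr <- points$protein[sel]
    sd <- points$side[sel]
    for (j in seq_len(K)) {
      t <- tvals[j]
      mis[i, j] <- sum(sd == "below" & pr > t) + sum(sd == "above" & pr < t)
      mar[i, j] <- if (!is.finite(t) || length(pr) == 0) 0 else min(abs(pr - t))
    }
  }

  # non-increasing sequences of length n over 1..K via combinations
  combs <- utils::combn(K + n - 1, n)
  Jnd <- combs - (seq_len(n) - 1)          # non-decreasing
  J <- Jnd[n:1, , drop = FALSE]            # reversed: non-increasing
  S <- ncol(J)
  idx <- cbind(rep(seq_len(n), S), as.vector(J))
  mtot <- colSums(matrix(mis[idx], n, S))
  gtot <- colSums(matrix(mar[idx], n, S))

  cand <- which(mtot == min(mtot))
  cand <- cand[gtot[cand] == max(gtot[cand])]
  if (length(cand) > 1) {
    Jc <- J[, cand, drop = FALSE]
    ord <- do.call(order, lapply(n:1, function(i) -Jc[i, ]))
    cand <- cand[ord[1]]
  }
  list(precipitant = cols, protein = tvals[J[, cand]],
       misclassified = as.integer(mtot[cand]))
}

random_frontier_points <- function(rows, cols, flip = 0.1) {
  # labels drawn from a random monotone ground-truth staircase, then
  # corrupted with label flips
  pr <- seq_len(rows)
  cc <- seq_len(cols)
  thresh <- sort(runif(cols, 0, rows + 1), decreasing = TRUE)
  pts <- expand.grid(protein = pr, precipitant = cc)
  pts$side <- ifelse(pts$protein < thresh[pts$precipitant], "below", "above")
  nf <- rbinom(1, nrow(pts), flip)
  if (nf > 0) {
    i <- sample(nrow(pts), nf)
    pts$side[i] <- ifelse(pts$side[i] == "below", "above", "below")
  }
  pts
}
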