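# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Brute-force two-tailed Fisher p by explicit enumeration of all tables with
# the observed margins, using plain factorial arithmetic (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lfact <- lgamma(seq_len(n + 1)) # lfact[k+1] = log(k!)
  ptab <- function(x) {
    y <- c1 - x
    exp(lfact[r1 + 1] - lfact[x + 1] - lfact[r1 - x + 1] +
          lfact[r2 + 1] - lfact[y + 1] - lfact[r2 - y + 1] -
          (lfact[n + 1] - lfact[c1 + 1] - lfact[n - c1 + 1]))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, ptab, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Quaternion-based rigid superposition (SVD-free; Horn 1987): returns the
# RMS over the given point sets after optimal rotation/translation.
quaternion_rms <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  S <- t(Pc) %*% Qc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- Pc %*% t(R)
  sqrt(mean(rowSums((fitted - Qc)^2)))
}

# Naive per-atom RMS oracle: double loop over elements and matched atoms.
naive_element_rms <- function(reference, member, element_map) {
  out <- list()
  combos <- unique(element_map[, c("chain", "element")])
  for (i in seq_len(nrow(combos))) {
    ch <- combos$chain[i]; el <- combos$element[i]
    res <- element_map$resno[element_map$chain == ch &
                               element_map$element == el]
    sc2 <- bb2 <- numeric()
    for (j in seq_len(nrow(reference))) {
      if (reference$chain[j] != ch || !(reference$resno[j] %in% res)) next
      kk <- which(member$chain == reference$chain[j] &
                    member$resno == reference$resno[j] &
                    member$elety == reference$elety[j])
      if (!length(kk)) next
      d2 <- (reference$x[j] - member$x[kk[1]])^2 +
        (reference$y[j] - member$y[kk[1]])^2 +
        (reference$z[j] - member$z[kk[1]])^2
      if (reference$elety[j] %in% c("N", "CA", "C", "O")) {
        bb2 <- c(bb2, d2)
      } else if (!grepl("^[0-9]*H", reference$elety[j])) {
        sc2 <- c(sc2, d2)
      }
    }
    out[[length(out) + 1]] <- data.frame(
      chain = ch, element = el,
      sidechain_rms = if (length(sc2)) sqrt(mean(sc2)) else NA_real_,
      secondary_structure_rms = if (length(bb2)) sqrt(mean(bb2)) else NA_real_)
  }
  do.call(rbind, out)
}

# Synthetic two-component decay trace on the standard 10 kHz grid.
decay_trace <- function(a = c(3, 1), tau = c(2, 50), C = 0, noise_sd = 0,
                        t_max = 300, seed = NULL) {
  t <- seq(0, t_max, by = 0.1)
  y <- C + rowSums(vapply(seq_along(a),
                          function(i) a[i] * exp(-t / tau[i]),
                          numeric(length(t))))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), sd = noise_sd)
  }
  new_current_trace(t, y)
}
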