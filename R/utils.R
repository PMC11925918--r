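# Shared numeric helpers.

# Truncated moving-window sum over a matrix (square window of half-width
# `half`), via summed-area tables. NA must be pre-coded as 0 by the caller.
box_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  top <- pmax(seq_len(nr) - half - 1L, 0L) + 1L
  bot <- pmin(seq_len(nr) + half, nr) + 1L
  rows <- cs[bot, , drop = FALSE] - cs[top, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rows, 1, cumsum)))
  left <- pmax(seq_len(nc) - half - 1L, 0L) + 1L
  right <- pmin(seq_len(nc) + half, nc) + 1L
  cs2[, right + 0L, drop = FALSE] - cs2[, left, drop = FALSE]
}

# Number of valid (non-NA) cells in each truncated window.
box_count <- function(valid, half) {
  box_sum(matrix(as.numeric(valid), nrow(valid), ncol(valid)), half)
}

# Round a nonnegative real vector to integers preserving its (integral) sum:
# largest-remainder method.
round_preserving_sum <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - fl)
    take <- ord[fl[ord] > 0][seq_len(-rem)]
    fl[take] <- fl[take] - 1
  }
  as.integer(fl)
}

# min-max rescale of a numeric vector/matrix to [0, 1] over non-NA entries
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0)
    stop("cannot rescale a constant (or empty) surface")
  (x - r[1]) / (r[2] - r[1])
}
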