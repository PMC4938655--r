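# Independent oracles, deliberately implemented differently from the
# package: a queue-based flood fill for connected components and R's own
# t.test for the Welch p-value.

# 8-connected components by explicit breadth-first flood fill
flood_fill_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  current <- 0L
  for (c0 in seq_len(w)) {
    for (r0 in seq_len(h)) {
      if (!mask[r0, c0] || labels[r0, c0] != 0L) next
      current <- current + 1L
      queue <- list(c(r0, c0))
      labels[r0, c0] <- current
      while (length(queue) > 0) {
        px <- queue[[1]]
        queue <- queue[-1]
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- px[1] + dr
            cc <- px[2] + dc
            if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
                mask[rr, cc] && labels[rr, cc] == 0L) {
              labels[rr, cc] <- current
              queue[[length(queue) + 1]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  n <- current
  areas <- if (n > 0) tabulate(labels[labels > 0], n) else numeric()
  cent <- t(vapply(seq_len(n), function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    c(x = mean(idx[, "col"]), y = mean(idx[, "row"]))
  }, numeric(2)))
  list(n = n, areas = areas, centroids = cent, labels = labels)
}

# one-tailed Welch p-value via stats::t.test (alternative applies to x vs y)
welch_oracle <- function(x, y, alternative) {
  stats::t.test(x, y, alternative = alternative, var.equal = FALSE)$p.value
}

# canonical partition signature so label numbering differences don't matter
partition_signature <- function(labels) {
  groups <- split(which(labels > 0), labels[labels > 0])
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, min, numeric(1)))])
}
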