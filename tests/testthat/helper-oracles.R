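# Independent oracles used by the property tests. These deliberately share
# no code with the implementation they check.

# 8-connected labelling by breadth-first flood fill.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L
      c <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Blob summaries from a label matrix, ordered top-left first like
# blob_analysis (bounding-box y, then x; 0-based coordinates).
flood_fill_blobs <- function(mask, min_area = 0) {
  lab <- flood_fill_label(mask)
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k)
    if (length(idx) < min_area) next
    rows <- ((idx - 1L) %% nrow(mask))
    cols <- ((idx - 1L) %/% nrow(mask))
    out[[length(out) + 1]] <- data.frame(
      area = length(idx), cx = mean(cols), cy = mean(rows),
      x = min(cols), y = min(rows),
      w = max(cols) - min(cols) + 1L, h = max(rows) - min(rows) + 1L
    )
  }
  if (length(out) == 0) {
    return(data.frame(area = integer(), cx = numeric(), cy = numeric(),
                      x = integer(), y = integer(), w = integer(), h = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$y, df$x), , drop = FALSE]
}

# Exhaustive minimiser of the assignment-with-non-assignment problem: tries
# every injective partial matching of tracks to detections.
brute_force_assignment <- function(cost, cost_unassigned = 20) {
  nt <- nrow(cost); nd <- ncol(cost)
  best <- list(total = Inf, pairs = NULL)
  recurse <- function(ti, used, pairs, acc) {
    if (acc >= best$total) return()
    if (ti > nt) {
      total <- acc + cost_unassigned * (nd - length(used))
      if (total < best$total) best <<- list(total = total, pairs = pairs)
      return()
    }
    recurse(ti + 1L, used, pairs, acc + cost_unassigned)  # track unassigned
    for (dj in seq_len(nd)) {
      if (!(dj %in% used)) {
        recurse(ti + 1L, c(used, dj), rbind(pairs, c(ti, dj)),
                acc + cost[ti, dj])
      }
    }
  }
  recurse(1L, integer(0), NULL, 0)
  best
}

# Per-sample (ungrouped) expected calibration error, in percent.
ece_per_sample <- function(confidences, correct, n_bins = 10) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- findInterval(confidences, edges, left.open = TRUE, all.inside = TRUE)
  total <- 0
  for (b in unique(bin)) {
    i <- bin == b
    total <- total + sum(i) * abs(mean(correct[i]) - mean(confidences[i]))
  }
  100 * total / length(confidences)
}

# A rendered test scene shared by segmentation tests.
disc_scene <- function(radius = 20, size = 256, gradient = 0, seed = 7) {
  scene_spec(c(size, size),
             cell_spec("D", size / 2, size / 2, base_radius = radius),
             illumination_gradient = gradient, seed = seed)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
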