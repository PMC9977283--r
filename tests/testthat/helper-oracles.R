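# Independent oracles used to check the implementation from first principles.

# Average ranks computed directly from the definition: the rank of a value is
# the mean of the sorted positions it occupies.
avg_ranks_oracle <- function(x) {
  # a tie group occupies sorted positions (#smaller + 1) .. (#smaller + #tied)
  vapply(x, function(v) mean(seq(sum(x < v) + 1, sum(x <= v))), 0)
}

# Definitional Spearman: Pearson product-moment on average ranks, written out
# as explicit sums (no call to cor()).
spearman_oracle <- function(x, y) {
  rx <- avg_ranks_oracle(x); ry <- avg_ranks_oracle(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# Quadratic all-pairs overlap counter: one if-test per fragment x window pair.
count_fragments_oracle <- function(fragments, windows, samples) {
  counts <- matrix(0L, nrow = length(windows), ncol = length(samples),
                   dimnames = list(vapply(windows, `[[`, "", "id"), samples))
  for (i in seq_len(nrow(fragments))) {
    if (fragments$genome[i] != "primary") next
    for (w in seq_along(windows)) {
      win <- windows[[w]]
      if (fragments$chrom[i] == win$chrom &&
          fragments$start[i] < win$end && fragments$end[i] > win$start) {
        s <- match(fragments$sample[i], samples)
        counts[w, s] <- counts[w, s] + 1L
      }
    }
  }
  counts
}

# Random fragment/window instance for counting checks.
random_overlap_instance <- function(n_frags, n_windows, n_samples = 2,
                                    span = 1e5) {
  windows <- lapply(seq_len(n_windows), function(i) {
    s <- sample.int(span - 2000, 1)
    list(chrom = "chr1", start = s, end = s + sample.int(2000, 1),
         id = sprintf("w%03d", i))
  })
  start <- sample.int(span, n_frags, replace = TRUE)
  frags <- data.frame(
    chrom = "chr1", start = start,
    end = start + sample.int(300, n_frags, replace = TRUE),
    sample = sprintf("s%d", sample.int(n_samples, n_frags, replace = TRUE)),
    genome = sample(c("primary", "spike"), n_frags, replace = TRUE,
                    prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
  list(fragments = frags, windows = windows,
       samples = sprintf("s%d", seq_len(n_samples)))
}

make_timecourse <- function(values, timepoints = seq_along(values[1, ]),
                            genes = sprintf("g%d", seq_len(nrow(values)))) {
  rownames(values) <- genes
  list(gene_ids = genes, timepoints = timepoints, values = values)
}
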