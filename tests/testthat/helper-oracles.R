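# Independent oracles used across the suite.  These deliberately use plain
# double loops so they share no code path with the implementation.

# cross-correlation with toroidal wrap: r[i,j] = sum_ab k[a,b] x[i+a, j+b]
oracle_conv_wrap <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  kh <- nrow(k); kw <- ncol(k)
  oy <- (kh - 1) / 2; ox <- (kw - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- ((i - 1 + a - 1 - oy) %% h) + 1
      jj <- ((j - 1 + b - 1 - ox) %% w) + 1
      acc <- acc + k[a, b] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

wrap_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# brute-force single-cell information from first principles
oracle_information <- function(responses, elements, n_bins = 10) {
  cells <- sort(unique(responses$cell))
  cats <- unique(elements$element)
  out <- NULL
  for (cl in cells) {
    rc <- responses[responses$cell == cl, ]
    bins <- pmin(pmax(ceiling(rc$rate * n_bins), 1), n_bins)
    p_all <- tabulate(bins, n_bins) / length(bins)
    for (ct in cats) {
      objs <- elements$object_id[elements$element == ct]
      sel <- rc$object_id %in% objs
      bs <- bins[sel]
      p_s <- tabulate(bs, n_bins) / length(bs)
      info <- 0
      for (b in seq_len(n_bins)) {
        if (p_s[b] > 0) info <- info + p_s[b] * log2(p_s[b] / p_all[b])
      }
      out <- rbind(out, data.frame(cell = cl, element = ct, info = info))
    }
  }
  out
}

# brute-force strict selectivity counting
oracle_selective <- function(responses, elements, hi = 0.99995, lo = 0.00005) {
  cats <- unique(elements$element)
  cells <- sort(unique(responses$cell))
  counts <- setNames(integer(length(cats)), cats)
  for (ct in cats) {
    objs <- elements$object_id[elements$element == ct]
    for (cl in cells) {
      rc <- responses[responses$cell == cl, ]
      pos <- rc$rate[rc$object_id %in% objs]
      neg <- rc$rate[!(rc$object_id %in% objs)]
      if (length(pos) > 0 && all(pos >= hi & pos <= 1) &&
          (length(neg) == 0 || all(neg < lo & neg >= 0))) {
        counts[ct] <- counts[ct] + 1L
      }
    }
  }
  counts
}

# small random response table fixture
random_response_table <- function(n_cells, shapes_tbl, seed) {
  set.seed(seed)
  frames <- shapes_tbl$object_id
  do.call(rbind, lapply(seq_len(n_cells), function(cl) {
    data.frame(cell = cl, object_id = frames,
               rate = round(runif(length(frames)), 3))
  }))
}
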