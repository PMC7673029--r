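# Shared fixture builders; everything is generated in code at test time.

# Small, fast simulation config for spatial tests.
tiny_config <- function(..., noise = 0, crosstalk = 0) {
  sim_config(field = c(256L, 256L), n_cells = 30L, noise = noise,
             crosstalk = crosstalk, ...)
}

# Row-standardized ring graph on n nodes (each node linked to its 2 ring
# neighbors); closed form for Moran's I test cases.
ring_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1L] <- 1
    W[i, ((i - 2L) %% n) + 1L] <- 1
  }
  as_embedding_graph(W)
}

# Dense double-sum Moran's I, the independent oracle for the sparse path.
dense_morans_i <- function(x, graph) {
  W <- as.matrix(graph$W)
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# One-hot spot intensity row for a barcode, as decode_spots expects it.
spot_row <- function(spot_id, barcode, x = 0, y = 0, amplitude = 1) {
  alphabet <- c("A", "C", "G", "T")
  row <- data.frame(spot_id = spot_id, x = x, y = y)
  bases <- strsplit(barcode, "")[[1]]
  for (c in seq_along(bases)) for (k in 0:3)
    row[[sprintf("cycle%d_ch%d", c, k)]] <-
      if (alphabet[k + 1L] == bases[c]) amplitude else 0
  row
}

# Disk image fixture with known centers/radii.
disk_image <- function(centers, radius, dim = c(128L, 128L),
                       fg = 0.9, bg = 0.05) {
  img <- matrix(bg, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    for (cc in seq_len(dim[2])) {
      dy2 <- radius^2 - (cc - 1 - cx)^2
      if (dy2 < 0) next
      rows <- which((seq_len(dim[1]) - 1 - cy)^2 <= dy2)
      img[rows, cc] <- fg
    }
  }
  img
}

# Adjusted Rand index between two labelings (closed-form contingency version).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- si * sj / ch2(n)
  (sij - expected) / ((si + sj) / 2 - expected)
}
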