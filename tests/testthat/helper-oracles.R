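# Independent oracles used to check the implementation by a different route.

# brute-force flood-fill connected-component labeling (BFS, column-major
# scan order for label assignment)
flood_fill_labels <- function(mask, connectivity = 8L) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  qr <- integer(nr * nc); qc <- integer(nr * nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    head <- 1L; tail <- 1L
    qr[1L] <- i; qc[1L] <- j
    lab[i, j] <- cur
    while (head <= tail) {
      pi <- qr[head]; pj <- qc[head]; head <- head + 1L
      for (o in offs) {
        r <- pi + o[1L]; c2 <- pj + o[2L]
        if (r >= 1L && r <= nr && c2 >= 1L && c2 <= nc &&
            mask[r, c2] && lab[r, c2] == 0L) {
          lab[r, c2] <- cur
          tail <- tail + 1L
          qr[tail] <- r; qc[tail] <- c2
        }
      }
    }
  }
  lab
}

# do two label maps define the same partition of the foreground?
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  fa <- a > 0L; fb <- b > 0L
  if (!identical(fa, fb)) return(FALSE)
  if (!any(fa)) return(TRUE)
  pairs <- unique(cbind(a[fa], b[fa]))
  !anyDuplicated(pairs[, 1L]) && !anyDuplicated(pairs[, 2L])
}

# noise-free 4PL responses in % of control
fourpl_response <- function(conc_uM, pIC50, bottom, hill, top = 100) {
  l50 <- 6 - pIC50
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc_uM) - l50)))
}
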