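# Shared fixtures: tiny networks and small random masks built in code.

tiny_config <- function(name = "elanres-msca-unet", widths = c(4, 6, 8, 10)) {
  network_preset(name, stage_channels = widths)
}

tiny_net <- function(name = "elanres-msca-unet", widths = c(4, 6, 8, 10),
                     seed = 1) {
  set.seed(seed)
  build_network(tiny_config(name, widths))
}

random_mask <- function(dim3, p = 0.3) {
  array(stats::runif(prod(dim3)) < p, dim = dim3)
}

# brute-force all-pairs average symmetric surface distance (the oracle the
# distance-transform implementation must match exactly)
asd_bruteforce <- function(A, B, spacing = c(1, 1, 1)) {
  sa <- extract_surface(A, spacing)$points
  sb <- extract_surface(B, spacing)$points
  dmat <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)),
                function(i, j) sqrt((sa[i, 1] - sb[j, 1])^2 +
                                    (sa[i, 2] - sb[j, 2])^2 +
                                    (sa[i, 3] - sb[j, 3])^2))
  (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) /
    (nrow(sa) + nrow(sb))
}

# flood-fill component labeling oracle (26-connectivity)
label_bruteforce <- function(m) {
  d <- dim(m)
  lab <- array(0L, dim = d)
  cur <- 0L
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (v in which(m)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      ui <- arrayInd(u, d)
      for (r in seq_len(nrow(nb))) {
        w <- ui + nb[r, ]
        if (any(w < 1) || any(w > d)) next
        wi <- w[1] + d[1] * (w[2] - 1) + d[1] * d[2] * (w[3] - 1)
        if (m[wi] && lab[wi] == 0L) {
          lab[wi] <- cur
          queue <- c(queue, wi)
        }
      }
    }
  }
  lab
}
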