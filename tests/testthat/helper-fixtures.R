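# Shared fixtures, generated once per test run and cached. All randomness
# flows through fixed seeds so the suite is deterministic.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fix_phantoms <- function() cached("phantoms", generate_phantoms())

fix_separated <- function() cached("separated",
                                   synth_preset("separated", seed = 42))

fix_separated_caught <- function() cached("separated_caught",
                                          catch_cells(fix_separated()$image))

fix_ghosted <- function() cached("ghosted", synth_preset("ghosted", seed = 11))

fix_edge <- function() cached("edge", synth_preset("edge", seed = 13))

# map generator truth labels to detected nucleus labels by mask overlap
map_truth_labels <- function(truth, nuclei_labels) {
  vapply(sort(unique(truth$cells$label)), function(l) {
    ov <- nuclei_labels[truth$nuclei_labels == l]
    ov <- ov[ov > 0]
    if (!length(ov)) NA_integer_ else
      as.integer(names(which.max(table(ov))))
  }, integer(1))
}

# grow a mask by one pixel in every direction (8-neighbourhood)
dilate_grow <- function(mask) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- out[rs, cs] | mask[rs - dr, cs - dc]
  }
  out
}

# a 96x96 nuclear channel holding one bright filled ellipse
make_blank_nucleus <- function() {
  m <- matrix(0, 96, 96)
  d2 <- outer((1:96 - 48)^2 / 121, (1:96 - 48)^2 / 64, "+")
  m[d2 <= 1] <- 210
  m
}

# brute-force 8-connected flood fill, the labeling oracle
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (px - 1L) %% nr + 1L; cc <- (px - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccn <- cc + dc
        if (rr < 1 || rr > nr || ccn < 1 || ccn > nc) next
        q <- (ccn - 1L) * nr + rr
        if (mask[q] != 0 && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# random small blob mask for property tests
random_blob <- function(seed, n = 60, size = 40) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  pos <- c(size / 2, size / 2)
  for (i in seq_len(n)) {
    pos <- pmin(pmax(pos + sample(-1:1, 2, replace = TRUE), 2), size - 1)
    m[pos[1], pos[2]] <- TRUE
    m[pos[1] + 1, pos[2]] <- TRUE
  }
  keep <- label_components(m)
  keep == keep[which(keep > 0)[1]]  # largest-ish single component
}
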