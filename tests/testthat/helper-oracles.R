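# Independent brute-force oracles, deliberately naive: these re-derive the
# shell/overlap/component definitions from first principles and are only run
# on small volumes.

# Exhaustive nearest-nucleus shell construction: for every background voxel,
# compute the Euclidean distance (voxel units) to EVERY foreground voxel; the
# voxel belongs to the shell of the nearest nucleus iff that distance is
# <= radius, ties resolved to the smallest label id.
brute_shells <- function(labels_arr, radius) {
  d <- dim(labels_arr)
  fg <- which(labels_arr > 0, arr.ind = TRUE)
  out <- array(0L, d)
  if (nrow(fg) == 0L) return(out)
  fg_lab <- labels_arr[fg]
  bg <- which(labels_arr == 0, arr.ind = TRUE)
  for (i in seq_len(nrow(bg))) {
    d2 <- (fg[, 1] - bg[i, 1])^2 + (fg[, 2] - bg[i, 2])^2 + (fg[, 3] - bg[i, 3])^2
    m <- min(d2)
    if (m <= radius^2) {
      out[bg[i, 1], bg[i, 2], bg[i, 3]] <- min(fg_lab[d2 == m])
    }
  }
  out
}

# Exhaustive per-label overlap counts
brute_overlap <- function(shells_arr, mask_arr) {
  ids <- sort(setdiff(unique(as.vector(shells_arr)), 0L))
  data.frame(
    label_id = ids,
    shell_voxel_count = vapply(ids, function(id) sum(shells_arr == id), integer(1)),
    overlap_voxels = vapply(ids, function(id) sum(shells_arr == id & mask_arr),
                            integer(1))
  )
}

# Independent 26-connected flood fill (plain R, queue-based)
brute_component_sizes <- function(mask_arr) {
  d <- dim(mask_arr)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(idx_all <- which(mask_arr & !seen, arr.ind = TRUE)) > 0) {
    queue <- idx_all[1, , drop = FALSE]
    seen[queue] <- TRUE
    size <- 0L
    while (nrow(queue) > 0) {
      v <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      nb <- sweep(offs, 2, v, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      hit <- mask_arr[nb] & !seen[nb]
      if (any(hit)) {
        nb <- nb[hit, , drop = FALSE]
        seen[nb] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Small fast phantom for unit tests (layer boundary inside the 40 um stack)
small_phantom <- function(seed = 1L, n_nuclei = 60L, transduction_prob = 0.7,
                          ...) {
  generate_phantom(phantom_config(
    volume_shape = c(40L, 64L, 64L),
    geometry = voxel_geometry(211 / 256, 211 / 256, 1),
    n_nuclei = n_nuclei,
    transduction_prob = transduction_prob,
    layer_boundary_um = 20,
    seed = seed,
    ...
  ))
}

mask_f1 <- function(pred, truth) {
  tp <- sum(pred & truth)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

# Deterministic random label volume: a few small spheres on a small grid
random_label_volume <- function(seed, side_range = c(16L, 32L), n_range = c(2L, 5L)) {
  set.seed(seed)
  side <- sample(side_range[1]:side_range[2], 1)
  d <- c(side, side, side)
  a <- array(0L, d)
  n <- sample(n_range[1]:n_range[2], 1)
  for (id in seq_len(n)) {
    c0 <- runif(3, 3, side - 2)
    r <- runif(1, 1.2, 3)
    box <- expand.grid(z = 1:side, y = 1:side, x = 1:side)
    inside <- (box$z - c0[1])^2 + (box$y - c0[2])^2 + (box$x - c0[3])^2 <= r^2
    sel <- as.matrix(box[inside & a[as.matrix(box)] == 0L, ])
    if (nrow(sel) > 0) a[sel] <- id
  }
  label_volume(a, voxel_geometry(1, 1, 1))
}
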