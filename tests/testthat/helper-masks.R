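# shared fixture builders; everything is generated in code

disc_mask <- function(nr, nc, centers, radii) {
  # centers: matrix of (x, y); pixel centers at (c - 0.5, r - 0.5) in
  # 1-based matrix indices
  m <- matrix(FALSE, nr, nc)
  cx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  cy <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc)
  for (i in seq_len(nrow(centers)))
    m <- m | (cx - centers[i, 1L])^2 + (cy - centers[i, 2L])^2 <= radii[i]^2
  m
}

# two discs merged into one component by a thin bridge
dumbbell_mask <- function(radius = 20, center_dist = 60,
                          bridge_px = 4, nr = 120, nc = 180) {
  c1 <- c(60, 60); c2 <- c(60 + center_dist, 60)
  m <- disc_mask(nr, nc, rbind(c1, c2), c(radius, radius))
  rows <- 60 + seq_len(bridge_px) - ceiling(bridge_px / 2)
  m[rows, 60:(60 + center_dist)] <- TRUE
  m
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# simple star-shaped polygon: angles sorted, radii jittered
random_polygon <- function(n = 8, center = c(30, 30), rmin = 5, rmax = 20) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(x = center[1L] + r * cos(th), y = center[2L] + r * sin(th))
}

small_scene <- function(seed, n_ftu = 5, size = 400) {
  generate_scene(scene_spec(n_ftu = n_ftu, ftu_kind = "glomerulus",
                            image_shape = c(size, size), pixel_size_um = 4,
                            seed = seed))
}
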