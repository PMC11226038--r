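# Small programmatic fixtures shared across test files.

# logical mask of one or more spheres on a small grid; centers/radii in
# voxel units (1-based voxel coordinates)
sphere_mask <- function(dm, centers, radii) {
  co <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                    z = seq_len(dm[3]))
  m <- rep(FALSE, nrow(co))
  for (i in seq_len(nrow(centers))) {
    m <- m | ((co$x - centers[i, 1])^2 + (co$y - centers[i, 2])^2 +
                (co$z - centers[i, 3])^2) <= radii[i]^2
  }
  array(m, dm)
}

# a voxel image whose bone voxels are exactly `mask`
mask_image <- function(mask, spacing = 17.5, bone = 4000, tissue = 200) {
  voxel_image(array(ifelse(mask, bone, tissue), dim(mask)), spacing)
}

# single-voxel seed set from 1-based voxel coordinates
point_seeds <- function(dm, coords_1based, labels, spacing = 17.5) {
  seeds_from_coords(
    data.frame(x = coords_1based[, 1] - 1L, y = coords_1based[, 2] - 1L,
               z = coords_1based[, 3] - 1L, label = labels),
    dm, spacing)
}

# block-world truth label map: `n_bones` cubes of side `side`, laid out on a
# coarse grid with 2-voxel background gaps; returns a label_map
block_truth <- function(n_bones = 8L, side = 5L, per_row = 4L) {
  rows <- ceiling(n_bones / per_row)
  dm <- c(per_row * (side + 2L) + 2L, rows * (side + 2L) + 2L, side + 4L)
  v <- array(0L, dm)
  for (b in seq_len(n_bones)) {
    r <- (b - 1L) %/% per_row
    cidx <- (b - 1L) %% per_row
    x0 <- 3L + cidx * (side + 2L)
    y0 <- 3L + r * (side + 2L)
    v[x0:(x0 + side - 1L), y0:(y0 + side - 1L), 3L:(2L + side)] <- b
  }
  label_map(v, 17.5)
}

# default phantom objects, built once per test run (moderately expensive)
phantom_cache <- local({
  env <- new.env()
  function(what = c("atlas", "truth", "image", "seg"),
           variant = "unfused", seed = 7L) {
    what <- match.arg(what)
    key <- paste(what, variant, seed, sep = "_")
    if (is.null(env[[key]])) {
      env[[key]] <- switch(what,
        atlas = build_bone_atlas(variant),
        truth = rasterize_atlas(phantom_cache("atlas", variant)),
        image = render_image(phantom_cache("atlas", variant),
                             rng_seed = seed),
        seg = segment_hindpaw(phantom_cache("image", variant, seed)))
    }
    env[[key]]
  }
})
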