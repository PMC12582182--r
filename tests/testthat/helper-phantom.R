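# Shared fixtures, built once per test run.

phantom_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function(shape = c(24L, 24L, 24L), seed = 1L) {
    key <- paste(c(shape, seed), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- make_template(shape, seed = seed)
    cache[[key]]
  }
})

# PET-like registration template: noise-free CN uptake painting
pet_template_fixture <- function(tp) {
  volume3d(petnorm:::.paint_pet(tp$template, tp$atlas,
                                petnorm:::.label_levels(tp$atlas,
                                                        stage_profile("CN"))),
           spacing = tp$template$spacing)
}

# Naive per-voxel trilinear interpolation with zero padding: the independent
# resampling oracle (deliberately loop-based, never shares code with warp()).
oracle_trilinear <- function(vol, px, py, pz) {
  d <- dim(vol)
  vapply(seq_along(px), function(i) {
    x0 <- floor(px[i]); y0 <- floor(py[i]); z0 <- floor(pz[i])
    fx <- px[i] - x0; fy <- py[i] - y0; fz <- pz[i] - z0
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
      cv <- if (ix >= 0 && ix < d[1] && iy >= 0 && iy < d[2] &&
                iz >= 0 && iz < d[3]) vol[ix + 1, iy + 1, iz + 1] else 0
      v <- v + cv * (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
    }
    v
  }, numeric(1))
}
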