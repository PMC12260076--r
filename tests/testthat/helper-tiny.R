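# Shared builders for desk-size test instances.  Everything is generated in
# code; nothing is read from disk.

tiny_dataset <- function(n = 6, size = 16, seed = 7, noise_sd = 0.05,
                         split = "train", kind = "blob") {
  generate_shape_dataset(shape_dataset_config(
    n = n, image_size = size, shape_kind = kind,
    noise_sd = noise_sd, seed = seed, split = split))
}

# crop pairs to 8x8 for the smallest pipeline instances
crop_pairs <- function(ds, size = 8L) {
  ds$pairs <- lapply(ds$pairs, function(p) {
    mask_image_pair(p$image[seq_len(size), seq_len(size)],
                    p$mask[seq_len(size), seq_len(size)], p$id)
  })
  ds
}

# the smallest full trilevel instance: 8x8, depth-1 models
tiny_mlo_setup <- function(seed = 3, n = 6, logits_sd = 0.3) {
  ds <- crop_pairs(tiny_dataset(n = n, size = 16, seed = 7, noise_sd = 0.05))
  ga <- build_searchable_generator(8L, depth = 1L, base_width = 1L,
                                   label_count = 2L, seed = seed)
  arch <- ga$arch
  if (logits_sd > 0) {
    arch$logits <- with_seed_(seed + 1, matrix(
      stats::rnorm(length(arch$logits), sd = logits_sd), nrow(arch$logits)))
  }
  list(gen = ga$generator, arch = arch,
       disc = build_discriminator(8L, base_width = 2L, seed = seed + 1),
       seg = build_unet(8L, label_count = 2L, base_width = 2L, depth = 1L,
                        seed = seed + 2),
       batches = list(gan = ds$pairs[1:3],
                      aug_masks = lapply(ds$pairs[1:3], `[[`, "mask"),
                      train = ds$pairs[1:3],
                      val = ds$pairs[4:min(6, n)]))
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# direct-loop convolution oracle (independent of the package's im2col path);
# x: (C, H, W) array, w: (Cout, Cin, k, k), returns (Cout, Ho, Wo)
conv_oracle <- function(x, w, bias, stride, pad) {
  k <- dim(w)[3]; Cin <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Cout <- dim(w)[1]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, dim = c(Cout, Ho, Wo))
  for (o in seq_len(Cout)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- bias[o]
    for (ci in seq_len(Cin)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      hi <- (ho - 1) * stride + ki - pad
      wi <- (wo - 1) * stride + kj - pad
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + w[o, ci, ki, kj] * x[ci, hi, wi]
      }
    }
    out[o, ho, wo] <- acc
  }
  out
}

# nearest-neighbour coordinate-rotation oracle for masks (0-based doc
# convention; independent per-pixel loop)
rotate_oracle <- function(mask, angle_degrees) {
  H <- nrow(mask); W <- ncol(mask)
  th <- angle_degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    sr <- round(cos(th) * (r - cy) - sin(th) * (cc - cx) + cy)
    sc <- round(sin(th) * (r - cy) + cos(th) * (cc - cx) + cx)
    if (sr >= 1 && sr <= H && sc >= 1 && sc <= W) out[r, cc] <- mask[sr, sc]
  }
  out
}
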