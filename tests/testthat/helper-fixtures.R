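# Shared small fixtures and numeric helpers.

rand_map <- function(H, W, C, N, seed = 1, scale = 1) {
  set.seed(seed)
  array(rnorm(H * W * C * N) * scale, dim = c(H, W, C, N))
}

max_rel_err <- function(gc) {
  max(vapply(gc, function(g)
    max(abs(g$analytic - g$numeric)) / max(1e-8, max(abs(g$numeric))),
    numeric(1)))
}

tiny_c3frn_cfg <- function(n_repeats = 1L)
  c3f_rn_config(8L, 8L, n_repeats = n_repeats,
                swin = swin_config(depth = 2L, n_heads = 2L, win_size = 2L,
                                   patch_size = 2L))

# berries enlarged so objects are anchor-sized at small test resolutions
tiny_scene_set <- function(n, img = 96L, seed = 5L, umbels = 3L)
  generate_scenes(n, scene_spec(img_size = img, n_umbels = umbels,
                                berry_radius = c(8, 14), seed = seed))
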