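# Shared fixture builders: everything is generated in code, seeded.

rand_fm <- function(H, W, C, seed = 1) {
  set.seed(seed)
  feature_map(array(stats::rnorm(H * W * C), c(H, W, C)))
}

tiny_specs <- function() {
  list(a = backbone_spec("tiny", output_channels = 8L, depth = 2L),
       b = backbone_spec("tiny", output_channels = 12L, depth = 3L))
}

tiny_model <- function(seed = 1, d = 64L, input_size = c(16L, 16L), ...) {
  sp <- tiny_specs()
  build_model(sp$a, sp$b, d = d, K = 5L, r = 4L, seed = seed,
              input_size = input_size, ...)
}

small_dataset_spec <- function(counts = c(60L, 10L, 20L, 5L, 5L), seed = 7L) {
  synthetic_dataset_spec(class_counts = counts, seed = seed)
}

random_simplex <- function(K) {
  p <- stats::rgamma(K, 1)
  p / sum(p)
}
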