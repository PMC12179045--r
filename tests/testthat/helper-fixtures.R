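# Shared fixtures: random probability maps and masks under fixed seeds,
# and a tiny on-disk dataset for pipeline tests.

random_prob_map <- function(n = 25, seed = 1) {
  set.seed(seed)
  matrix(runif(n), nrow = floor(sqrt(n)))
}

random_mask <- function(n = 25, seed = 1, p = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n, 1, p), nrow = floor(sqrt(n)))
  m
}

# tiny fast dataset for pipeline tests: 32x32, low branch depth
tiny_dataset <- function(root = tempfile("tinyds"), seed = 5,
                         n_train = 4, n_val = 2, n_test = 2) {
  params <- scene_params(image_height = 32, image_width = 32, n_trees = 1,
                         branch_depth = 2, vessel_contrast = 0.7,
                         background_noise_sd = 0, seed = seed)
  make_dataset(root, n_train, n_val, n_test, params)
}

tiny_unet <- function() unet_config(in_channels = 1, base_width = 4, depth = 2)

tiny_train <- function(seed = 1, epochs = 2) {
  train_config(batch_size = 2, epochs = epochs, seed = seed)
}

# independent scalar reference for the binary KL divergence
kl_ref <- function(pt, ps) pt * log(pt / ps) + (1 - pt) * log((1 - pt) / (1 - ps))
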