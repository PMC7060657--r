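# Shared fixtures: small phantoms and toy datasets built in code.

table1_bvals <- petivim::default_b_values()

# a compact noiseless lesion phantom used across modules
small_phantom_spec <- function(noise_sigma = 0, seed = 1L, ...) {
  phantom_spec(grid_shape = c(24L, 24L, 12L), voxel_size = c(2, 2, 2),
               lesion_center = c(24, 24, 12), lesion_radii = c(9, 9, 7),
               noise_sigma = noise_sigma, seed = seed, ...)
}

# brute-force AUC over all positive/negative pairs (ties count 1/2)
pairwise_auc <- function(marker, labels) {
  pos <- marker[labels == 1]
  neg <- marker[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# direct log-likelihood of an intercept + single-slope logistic model
logistic_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}
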