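# shared fixtures: random spike trains and small configs built in code

# random sorted spike train on [0, duration); times snapped to a 0.1 ms grid
# so that exact pre/post coincidences (dt = 0) actually occur now and then
rand_train <- function(n, duration = 1, grid = 1e-4) {
  sort(unique(round(runif(n, 0, duration), -log10(grid))))
}

# a pre/post pair of trains, occasionally sharing exact spike times
rand_train_pair <- function(n_pre = 20, n_post = 20, duration = 1,
                            share = 0.1) {
  pre <- rand_train(n_pre, duration)
  post <- rand_train(n_post, duration)
  if (share > 0 && length(pre)) {
    k <- rbinom(1, length(post), share)
    if (k > 0 && length(pre) >= k)
      post <- sort(unique(c(post[-seq_len(k)], sample(pre, k))))
  }
  list(pre = pre, post = post)
}

all_rules <- c("DP", "PP", "UP", "DU")

quiet_neuron <- function(...) neuron_params(noise_mean = 0, ...)
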