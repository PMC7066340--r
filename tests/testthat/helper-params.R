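# Shared fixtures: the published reference parameter vector and random
# nonnegative parameter draws for property-style tests.

ref_params <- reference_parameters()

random_params <- function() {
  model_parameters(mu = runif(1, 1e-4, 1), a = runif(1), b = runif(1),
                   c = runif(1), delta = runif(1, 0, 2),
                   epsilon = runif(1, 0, 2), alpha = runif(1, 0, 2),
                   beta = runif(1, 0, 2))
}
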