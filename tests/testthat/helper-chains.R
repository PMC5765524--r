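# Fulmar vital rates typed independently of the packaged CSV, so fixture
# loading and hand-built construction cross-check each other.
uh1_rates <- function() vital_rates(
  sigma = c(1.00, 0.93, 0.94, 0.88),
  beta  = c(0.10, 0.96, 0.81, 0.42),
  gamma = c(0.81, 0.80, 0.65, 0.66),
  label = "UH-1"
)
uh2_rates <- function() vital_rates(
  sigma = c(0.92, 0.99, 0.93, 0.88),
  beta  = c(0.01, 0.80, 0.80, 0.55),
  gamma = c(0.69, 0.85, 0.64, 0.66),
  label = "UH-2"
)
uh3_rates <- function() vital_rates(
  sigma = c(1.00, 0.89, 0.93, 0.88),
  beta  = c(0.16, 0.97, 0.80, 0.55),
  gamma = c(1.00, 0.99, 0.66, 0.66),
  label = "UH-3"
)

fulmar_mixture <- function() {
  mixture_model(list(uh1_rates(), uh2_rates(), uh3_rates()),
                mixing = c(0.14, 0.67, 0.19))
}

# Uniform random valid rates for property-style tests.
random_rates <- function(label = "rand") {
  vital_rates(runif(4), runif(4), runif(4), label = label)
}

# A chain where every rate is constant across stages, so outcomes have
# geometric closed forms.
flat_rates <- function(sigma, beta = 1, gamma = 1, label = "flat") {
  vital_rates(rep(sigma, 4), rep(beta, 4), rep(gamma, 4), label = label)
}
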