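# shared fixtures, built once per test run
the_registry <- default_registry()
the_draw <- base_draw(the_registry)
the_model <- mortality_model(draw = the_draw)

stat_of <- function(res, metric) res$stats$mean[res$stats$metric == metric]

# closed-form mean of a normal truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  mu + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}
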