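# Shared fixtures: a hand-picked slow-ish twitch and synthetic moderately
# fused study cases (frequency chosen per unit, as in the experimental
# protocol, so the tetanus peaks near 50% of the fused-tetanus force).

std_twitch <- function(f_max = 20, t_lead = 2, t_hc = 12, t_c = 22,
                       t_hr = 48, t_tw = 180) {
  twitch_params(f_max, t_lead, t_hc, t_c, t_hr, t_tw)
}

std_mu <- function(ratio = 5, mu_type = "FR", ...) {
  tw <- std_twitch(...)
  motor_unit("MU1", mu_type, tw, ratio * tw$f_max)
}

moderate_case <- function(mu_type, seed, n = 41) {
  mu <- generate_motor_unit(mu_type, seed = seed)
  freq <- choose_mean_frequency(mu, seed = seed + 1000L, n = n)
  pattern <- generate_pattern(freq, n = n, seed = seed + 1000L)
  list(mu = mu, pattern = pattern, freq = freq)
}
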