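# Shared fixtures, all built in code.

# the device-like drive used throughout: strong field at 25 deg, weak field
# at 115 deg (orthogonal), magnitudes in the ratio used for the highest
# resolution runs
paper_protocol <- function(f_Hz = 2, E1 = 59.5, E2 = 22.4, duty = 0.5) {
  field_protocol(E1, E2, theta1_deg = 25, theta2_deg = 115,
                 f_Hz = f_Hz, duty = duty)
}

five_fragments <- c(500, 1000, 2000, 5000, 10000)

# exact Gaussian profile with a given integrated area
gauss_profile <- function(area, sigma = 40, center = 0,
                          grid = seq(center - 8 * sigma, center + 8 * sigma,
                                     length.out = 401)) {
  stream_profile(grid, area * dnorm(grid, center, sigma))
}

# synthetic peak pair with an exact resolution value
peaks_with_rs <- function(rs, sigma = 10) {
  list(a = list(center_um = 0, sigma_um = sigma),
       b = list(center_um = 4 * rs * sigma, sigma_um = sigma))
}
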