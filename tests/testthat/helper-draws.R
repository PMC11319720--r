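# Random valid parameter draws used by the property-style tests.
# Ranges cover the regimes the standard studies sweep (moderate Hartmann and
# Brinkman numbers, both buoyancy signs); draws violating the thermal
# resonance guard are rejected and redrawn.

randomValidParams <- function() {
  repeat {
    p <- try(flowParams(
      eps = runif(1, 0.1, 0.6),
      M = runif(1, 0.3, 2.5),
      beta = runif(1, 0, 1.2),
      alpha = runif(1, 0, pi / 2),
      lambda1 = runif(1, 0, 1.5),
      Br = runif(1, 0.5, 3),
      eta = runif(1, 0.02, 0.6),
      c1 = runif(1, 0, 2),
      c2 = runif(1, -2, 2)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

randomDraw <- function() {
  list(params = randomValidParams(),
       x = runif(1), dpdx = runif(1, -2, 2), F = runif(1, -1, 0.5))
}
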