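# Shared fixtures. Noiseless test-profile phantoms are cheap; build them
# lazily and cache within the session.

.fixtureCache <- new.env(parent = emptyenv())

testPhantom <- function(theta, noiseSD = 0, profile = "test", seed = 1L) {
  key <- paste("ph", theta, noiseSD, profile, seed, sep = "_")
  if (!exists(key, .fixtureCache)) {
    assign(key,
           generatePhantom(phantomSpec(rotationDeg = theta, profile = profile,
                                       noiseSD = noiseSD, seed = seed)),
           .fixtureCache)
  }
  get(key, .fixtureCache)
}

# regular n-gon approximation of an ellipse centered at (cx, cy) px
ellipsePoly <- function(cx, cy, a, b, n = 360L) {
  phi <- 2 * pi * (0:(n - 1)) / n
  cbind(cx + a * cos(phi), cy + b * sin(phi))
}
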