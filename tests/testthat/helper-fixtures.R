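# Shared fixtures: polygon builders and control-point generators.

circlePoly <- function(center, r, n = 48) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

squarePoly <- function(center, half) {
  rbind(center + c(-half, -half), center + c(half, -half),
        center + c(half, half), center + c(-half, half))
}

# well-spread source points in a [0, size]^2 domain
spreadPoints <- function(n, size = 50, margin = 5, seed = 7) {
  withr::with_seed(seed, {
    repeat {
      p <- cbind(runif(n, margin, size - margin),
                 runif(n, margin, size - margin))
      if (min(dist(p)) > 2) return(p)
    }
  })
}

rotationMat <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2,
         byrow = TRUE)

# two-nucleus plate used by the pipeline tests (px coordinates)
testPlate <- function(id = "P1", ap = 8) {
  AtlasPlate(id, ap, list(
    VPLo = circlePoly(c(26, 30), 7, 40),
    VPLc = circlePoly(c(40, 26), 5, 40)))
}
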