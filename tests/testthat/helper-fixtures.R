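# Shared fixtures, all generated in code.

# A random unlabeled stack of n side x side images.
randomStack <- function(n, side = 8L, seed = 1L) {
  set.seed(seed)
  imageStack(array(runif(side * side * n), c(side, side, n)))
}

# A spherically symmetric single-Gaussian phantom built directly (bypasses
# makePhantom's random anisotropic components).
sphericalPhantom <- function(side = 64L, sd = 8) {
  ctr <- (side + 1) / 2
  ax <- seq_len(side)
  p <- rbind(rep(ax, times = side^2),
             rep(rep(ax, each = side), times = side),
             rep(ax, each = side^2))
  g <- array(exp(-0.5 * colSums(((p - ctr) / sd)^2)), rep(side, 3L))
  new("PhantomVolume", grid = g / max(g), side = as.integer(side),
      components = list(list(type = "gaussian", center = rep(ctr, 3),
                             axes = rep(sd, 3), rotation = diag(3),
                             amplitude = 1)))
}

# An off-center anisotropic Gaussian phantom (deterministic).
offCenterPhantom <- function(side = 32L) {
  ax <- seq_len(side)
  p <- rbind(rep(ax, times = side^2),
             rep(rep(ax, each = side), times = side),
             rep(ax, each = side^2))
  ctr <- c(side * 0.62, side * 0.44, side * 0.5)
  q <- (p - ctr) / c(3, 5, 4)
  g <- array(exp(-0.5 * colSums(q^2)), rep(side, 3L))
  new("PhantomVolume", grid = g / max(g), side = as.integer(side),
      components = list(list(type = "gaussian", center = ctr,
                             axes = c(3, 5, 4), rotation = diag(3),
                             amplitude = 1)))
}

# A small tiered dataset shared by cascade-level unit tests.
tinyPlan <- function(nPerClass = 12L, side = 32L, seed = 11L)
  simulationPlan(nPerClass = nPerClass, imageSide = side, seed = seed)

# Light architecture + short training for unit tests.
tinySpec <- function(channels = 4L) blockSpec(channels = channels)
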