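# Shared fixtures, built in code at test time.

randMap <- function(dims = c(16, 16, 16), cell = dims, seed = 1,
                    origin = c(0, 0, 0)) {
  set.seed(seed)
  mapGrid(array(rnorm(prod(dims)), dims), cell = cell, originShift = origin)
}

# layout with bins assigned, for coefficient-level tests
binnedLayout <- function(dims = c(20, 20, 20), cell = 20, dMin = 2,
                         nBins = 5) {
  lay <- fourierLayout(dims, cell, dMin = dMin)
  assignBins(lay, makeBins(lay, nBins))
}

# complex white Gaussian coefficients on a layout (respecting self-conjugacy)
randCoeffs <- function(lay, sd = 1, seed = 1) {
  set.seed(seed)
  n <- length(lay@coeffs)
  x <- complex(real = rnorm(n, sd = sd / sqrt(2)),
               imaginary = rnorm(n, sd = sd / sqrt(2)))
  x[lay@selfConj] <- complex(real = rnorm(sum(lay@selfConj), sd = sd),
                             imaginary = 0)
  setCoeffs(lay, x)
}

# a small simulated half-map dataset shared across several files
sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- makeToyModel(8, box = 20, seed = 4)
      cache <<- list(model = model,
                     sim = simulateHalfMaps(model, bBlur = 30, dMin = 1.8,
                                            seed = 3))
    }
    cache
  }
})
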