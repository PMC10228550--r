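#' Construct a fragment length mixture configuration
#'
#' Defaults encode the canonical cfDNA length profile: a dominant
#' mononucleosomal component at 167 +/- 10 bp (weight 0.85), a dinucleosomal
#' component at 334 +/- 20 bp (weight 0.15), and a shorter tumor-derived
#' component at 145 +/- 15 bp reflecting the aberrantly short fragments shed
#' by tumor cells.
#'
#' @param healthyModes,healthySds,healthyWeights parameters of the two
#'   healthy components (bp / bp / unitless, weights summing to 1).
#' @param tumorMode,tumorSd tumor component location and spread (bp).
#' @param range admissible fragment length range in bp (inclusive); draws
#'   outside it are rejected and redrawn.
#' @return A [LengthMixtureConfig].
#' @examples
#' cfg <- lengthMixtureConfig()
#' @export
lengthMixtureConfig <- function(healthyModes = c(167, 334),
                                healthySds = c(10, 20),
                                healthyWeights = c(0.85, 0.15),
                                tumorMode = 145, tumorSd = 15,
                                range = c(50, 500)) {
  new("LengthMixtureConfig", healthyModes = healthyModes,
      healthySds = healthySds, healthyWeights = healthyWeights,
      tumorMode = tumorMode, tumorSd = tumorSd, range = range)
}

# Draw integer lengths from the theta-mixture using the *current* RNG stream.
# `component`, if given, is a logical vector (TRUE = tumor) overriding the
# Bernoulli(theta) component assignment.
drawLengths <- function(n, theta, cfg, component = NULL) {
  if (is.null(component)) component <- stats::runif(n) < theta
  len <- numeric(n)
  nh <- sum(!component)
  if (nh > 0) {
    comp <- sample.int(2L, nh, replace = TRUE, prob = cfg@healthyWeights)
    len[!component] <- stats::rnorm(nh, cfg@healthyModes[comp], cfg@healthySds[comp])
  }
  nt <- sum(component)
  if (nt > 0) len[component] <- stats::rnorm(nt, cfg@tumorMode, cfg@tumorSd)
  len <- round(len)
  ## truncation by rejection: redraw anything outside the admissible range
  bad <- which(len < cfg@range[1] | len > cfg@range[2])
  while (length(bad)) {
    len[bad] <- round(ifelse(component[bad],
      stats::rnorm(length(bad), cfg@tumorMode, cfg@tumorSd),
      {
        comp <- sample.int(2L, length(bad), replace = TRUE, prob = cfg@healthyWeights)
        stats::rnorm(length(bad), cfg@healthyModes[comp], cfg@healthySds[comp])
      }))
    bad <- bad[len[bad] < cfg@range[1] | len[bad] > cfg@range[2]]
  }
  as.integer(len)
}

#' Sample cfDNA fragment lengths from the tumor-fraction mixture
#'
#' Lengths are drawn from \eqn{(1-\theta)} times the healthy two-component
#' mixture plus \eqn{\theta} times the tumor component, truncated to the
#' admissible range, and rounded to integer bp. At \eqn{\theta = 0} the modal
#' length is the mononucleosomal ~167 bp; increasing \eqn{\theta} shifts mass
#' into the short 100–150 bp window, so the mean length decreases in
#' \eqn{\theta}.
#'
#' @param n number of lengths to draw.
#' @param theta tumor fraction in \[0,1\].
#' @param cfg a [LengthMixtureConfig].
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return Integer vector of fragment lengths (bp).
#' @examples
#' len <- sampleFragmentLengths(1000, theta = 0, seed = 1)
#' @export
sampleFragmentLengths <- function(n, theta, cfg = lengthMixtureConfig(), seed) {
  checkScalar(n, "n", min = 1, integer = TRUE)
  checkScalar(theta, "theta", min = 0, max = 1)
  withSeed(seed, drawLengths(n, theta, cfg))
}
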