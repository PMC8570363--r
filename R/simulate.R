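# Synthetic benchmark generators: n = 120 samples in 3 equal clusters, 10
# informative features per view, optional 5% outliers per class, Gaussian /
# Poisson / Bernoulli views and three-interlocking-half-moon geometry with
# copula-transformed count and proportion views.

.sim_n <- 120L
.sim_k <- 3L

.class_means_gauss <- function() {
  rbind(c(rep(-2.5, 5), rep(0, 5)),
        c(rep(0, 5), rep(2.5, 5)),
        c(rep(2.5, 5), rep(0, 5)))
}

# Three interlocking half moons: two upward arcs at x-offsets 0 and 2 and
# one downward arc between them, unit radius, i.i.d. Gaussian jitter.
.moons3 <- function(labels, noise_sd) {
  t <- stats::runif(length(labels), 0, pi)
  x <- ifelse(labels == 2L, 1 - cos(t),
              cos(t) + ifelse(labels == 3L, 2, 0))
  y <- ifelse(labels == 2L, 0.5 - sin(t), sin(t))
  cbind(x + stats::rnorm(length(labels), 0, noise_sd),
        y + stats::rnorm(length(labels), 0, noise_sd))
}

# 10 informative moon features = 5 independent coordinate pairs
.moon_block <- function(labels, noise_sd) {
  do.call(cbind, lapply(1:5, function(i) .moons3(labels, noise_sd)))
}

.pick_outliers <- function(labels) {
  unlist(lapply(split(seq_along(labels), labels), function(idx)
    sample(idx, round(0.05 * length(idx)))))
}

# rank-based copula transform: empirical CDF then a target quantile function
.copula <- function(Z, qfun) {
  apply(Z, 2L, function(z) qfun((rank(z) - 0.5) / length(z)))
}

#' Single-view benchmark scenarios
#'
#' Generates n = 120 samples in 3 equal clusters of 40 with 10 informative
#' features and \code{p_noise} noise features:
#' \describe{
#'   \item{S1A/S1B/S1C}{spherical Gaussian classes N(mu_k, I_10) with class
#'     means (-2.5,0), (0,2.5), (2.5,0) on the first/last five informative
#'     coordinates; 5\% of each class replaced by outliers from
#'     N(mu_k, 25 I_10); noise features N(0, noise_sd^2). The variants only
#'     differ in how p_noise / noise_sd are swept.}
#'   \item{S2}{three interlocking half moons: five independent coordinate
#'     pairs trace the moon geometry; 5\% outliers per class get the moon
#'     jitter inflated five-fold; Gaussian noise features.}
#'   \item{S3}{Poisson counts with informative class means 1, 4 and 7;
#'     noise features Poisson with per-feature means drawn once as random
#'     integers in 1..10 (no outliers).}
#' }
#'
#' @param scenario one of "S1A", "S1B", "S1C", "S2", "S3".
#' @param p_noise number of noise features (>= 0).
#' @param noise_sd noise-feature standard deviation for the Gaussian
#'   scenarios; also scales the moon jitter (default 0.1 for S2).
#' @param seed integer RNG seed.
#' @return list with \code{views} (list of one matrix), \code{labels},
#'   \code{informative} (list of one logical mask), \code{outliers} (row
#'   indices), \code{scenario}, \code{seed}.
#' @export
simSingleView <- function(scenario = c("S1A", "S1B", "S1C", "S2", "S3"),
                          p_noise = 25L, noise_sd = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (p_noise < 0) .stop("icclust_contract", "p_noise must be >= 0")
  set.seed(seed)
  labels <- rep(1:3, each = .sim_n / .sim_k)
  out_idx <- integer()
  if (scenario %in% c("S1A", "S1B", "S1C")) {
    if (is.null(noise_sd)) noise_sd <- 1
    mu <- .class_means_gauss()
    X10 <- mu[labels, ] + matrix(stats::rnorm(.sim_n * 10), .sim_n)
    out_idx <- .pick_outliers(labels)
    X10[out_idx, ] <- mu[labels[out_idx], ] +
      matrix(stats::rnorm(length(out_idx) * 10, 0, 5), length(out_idx))
    noise <- matrix(stats::rnorm(.sim_n * p_noise, 0, noise_sd), .sim_n)
  } else if (scenario == "S2") {
    if (is.null(noise_sd)) noise_sd <- 1
    moon_sd <- 0.1
    X10 <- .moon_block(labels, moon_sd)
    out_idx <- .pick_outliers(labels)
    X10[out_idx, ] <- .moon_block(labels, 5 * moon_sd)[out_idx, ]
    noise <- matrix(stats::rnorm(.sim_n * p_noise, 0, noise_sd), .sim_n)
  } else {  # S3
    mu_inf <- c(1, 4, 7)[labels]
    X10 <- matrix(stats::rpois(.sim_n * 10, rep(mu_inf, 10)), .sim_n)
    lam <- sample(1:10, p_noise, replace = TRUE)
    noise <- matrix(stats::rpois(.sim_n * p_noise,
                                 rep(lam, each = .sim_n)), .sim_n)
  }
  X <- cbind(X10, noise)
  list(views = list(X), labels = labels,
       informative = list(seq_len(ncol(X)) <= 10L),
       outliers = sort(out_idx), scenario = scenario, seed = seed)
}

.mv_dims <- list(S1 = c(10L, 10L, 10L), S2 = c(10L, 10L, 10L),
                 S3 = c(200L, 100L, 50L), S4 = c(50L, 200L, 100L),
                 S5 = c(200L, 100L, 50L), S6 = c(50L, 200L, 100L))

#' Multi-view benchmark scenarios
#'
#' Three views sharing n = 120 samples in 3 equal clusters, 10 informative
#' features per view, view dimensions per scenario (S1/S2: 10,10,10; S3/S5:
#' 200,100,50; S4/S6: 50,200,100). Spherical scenarios (S1, S3, S4):
#' Gaussian view N(mu_k, 3 I_10), Poisson view with class means 2/4/6,
#' Bernoulli view with class means 0.5/0.2/0.8; noise features are drawn
#' from the null version of each distribution (N(0,1), Poisson with random
#' integer means in 1..10, Bernoulli with uniform(0.2, 0.8) rates, drawn
#' once per feature). Half-moon scenarios (S2, S5, S6): the continuous view
#' traces the three-moon geometry with jitter sd 0.2; the count and
#' proportion views are rank-preserving copula transforms of independent
#' moon draws through Poisson(4) and Beta(2,2) quantile functions; noise
#' features as in the spherical case (Beta(2,2) noise for the proportion
#' view).
#'
#' @param scenario one of "S1".."S6".
#' @param seed integer RNG seed.
#' @return list with \code{views} (3 matrices), \code{labels},
#'   \code{informative} (3 masks), \code{scenario}, \code{seed}.
#' @export
simMultiView <- function(scenario = c("S1", "S2", "S3", "S4", "S5", "S6"),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  dims <- .mv_dims[[scenario]]
  labels <- rep(1:3, each = .sim_n / .sim_k)
  moons <- scenario %in% c("S2", "S5", "S6")
  gen_noise <- list(
    gauss = function(p) matrix(stats::rnorm(.sim_n * p), .sim_n),
    count = function(p) {
      lam <- sample(1:10, p, replace = TRUE)
      matrix(stats::rpois(.sim_n * p, rep(lam, each = .sim_n)), .sim_n)
    },
    binary = function(p) {
      pr <- stats::runif(p, 0.2, 0.8)
      matrix(stats::rbinom(.sim_n * p, 1, rep(pr, each = .sim_n)), .sim_n)
    },
    beta = function(p) matrix(stats::rbeta(.sim_n * p, 2, 2), .sim_n))
  views <- vector("list", 3L)
  if (!moons) {
    mu <- .class_means_gauss()
    inf1 <- mu[labels, ] + matrix(stats::rnorm(.sim_n * 10, 0, sqrt(3)),
                                  .sim_n)
    inf2 <- matrix(stats::rpois(.sim_n * 10, rep(c(2, 4, 6)[labels], 10)),
                   .sim_n)
    inf3 <- matrix(stats::rbinom(.sim_n * 10, 1,
                                 rep(c(0.5, 0.2, 0.8)[labels], 10)), .sim_n)
    views[[1]] <- cbind(inf1, gen_noise$gauss(dims[1] - 10L))
    views[[2]] <- cbind(inf2, gen_noise$count(dims[2] - 10L))
    views[[3]] <- cbind(inf3, gen_noise$binary(dims[3] - 10L))
  } else {
    moon_sd <- 0.2
    inf1 <- .moon_block(labels, moon_sd)
    inf2 <- .copula(.moon_block(labels, moon_sd),
                    function(u) stats::qpois(u, 4))
    inf3 <- .copula(.moon_block(labels, moon_sd),
                    function(u) stats::qbeta(u, 2, 2))
    views[[1]] <- cbind(inf1, gen_noise$gauss(dims[1] - 10L))
    views[[2]] <- cbind(inf2, gen_noise$count(dims[2] - 10L))
    views[[3]] <- cbind(inf3, gen_noise$beta(dims[3] - 10L))
  }
  list(views = views, labels = labels,
       informative = lapply(dims, function(p) seq_len(p) <= 10L),
       scenario = scenario, seed = seed)
}

#' Wrap simulated views with their conventional losses
#'
#' Continuous views get the Euclidean loss, count views the Manhattan loss
#' and binary/proportion views the Bernoulli log-likelihood - the loss
#' assignment used throughout the multi-view benchmarks.
#'
#' @param sim output of \code{\link{simMultiView}}.
#' @return list of \linkS4class{DataView}.
#' @export
simViewsAsData <- function(sim) {
  losses <- c("euclidean", "manhattan", "bernoulli_ll")
  lapply(seq_along(sim$views), function(k)
    dataView(sim$views[[k]], losses[k]))
}
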