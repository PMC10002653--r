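# Intra- vs inter-animal variability: hierarchical Gaussian observation
# model, population vs mean-of-individual occupancy distributions, Sarle's
# bimodality coefficient (critical value 5/9), and a permutation /
# bootstrap comparison of BC between conditions.

#' Hierarchical Gaussian observation model
#'
#' Each animal i has a latent mean `mu_i` drawn from the inter-animal law
#' (a single Gaussian around `mu_pop` with sd `sigma_inter`, or a 50/50
#' two-component Gaussian mixture at `mu_pop +- delta` for the bimodal
#' regime) and emits `n_obs` observations Gaussian(`mu_i`, `sigma_intra`).
#' The defaults are scaled to a navigation-index-like observable.
#'
#' @param mu_pop population-level mean (default 0.1).
#' @param sigma_inter sd of per-animal means (default 0.03 in the unimodal
#'   regime; the per-component sd in the bimodal regime).
#' @param sigma_intra within-animal observation sd (default 0.15).
#' @param n_animals number of animals (default 40).
#' @param n_obs observations per animal (default 100).
#' @param bimodal if `TRUE`, per-animal means come from the two-component
#'   mixture.
#' @param delta half-separation of the mixture components; defaults to
#'   `2 * sigma_intra`.
#' @return an object of class `hierarchical_model`.
#' @export
hierarchical_model <- function(mu_pop = 0.1, sigma_inter = 0.03,
                               sigma_intra = 0.15, n_animals = 40L,
                               n_obs = 100L, bimodal = FALSE,
                               delta = NULL) {
  stopifnot(sigma_inter >= 0, sigma_intra > 0, n_animals >= 1, n_obs >= 1)
  if (is.null(delta)) delta <- 2 * sigma_intra
  structure(list(mu_pop = mu_pop, sigma_inter = sigma_inter,
                 sigma_intra = sigma_intra, n_animals = as.integer(n_animals),
                 n_obs = as.integer(n_obs), bimodal = isTRUE(bimodal),
                 delta = delta),
            class = "hierarchical_model")
}

#' Simulate observations from a hierarchical model
#'
#' @param model a [hierarchical_model()].
#' @param seed RNG seed.
#' @return data.frame `animal_id, value` with `n_animals * n_obs` rows and
#'   attribute `mu_i` (the latent per-animal means).
#' @export
simulate_hierarchical <- function(model, seed = 1L) {
  stopifnot(inherits(model, "hierarchical_model"))
  with_preserved_rng({
    set.seed(seed)
    centers <- if (model$bimodal) {
      model$mu_pop + sample(c(-1, 1), model$n_animals, replace = TRUE) *
        model$delta
    } else rep(model$mu_pop, model$n_animals)
    mu_i <- stats::rnorm(model$n_animals, centers, model$sigma_inter)
    out <- data.frame(
      animal_id = rep(seq_len(model$n_animals), each = model$n_obs),
      value = stats::rnorm(model$n_animals * model$n_obs,
                           rep(mu_i, each = model$n_obs),
                           model$sigma_intra))
    attr(out, "mu_i") <- mu_i
    out
  })
}

#' Population vs mean-of-individual occupancy distributions
#'
#' The population distribution is the normalized histogram of all pooled
#' observations; the mean-of-individual distribution averages per-animal
#' normalized histograms with equal weight per animal. Both sum to 1 on the
#' common grid. With equal observation counts per animal the two coincide;
#' they differ exactly by the per-animal weighting otherwise.
#'
#' @param obs data.frame `animal_id, value`.
#' @param breaks histogram break points covering all values (default: 41
#'   equal bins over the data range).
#' @return list with `breaks`, `mids`, `population`, `mean_individual`,
#'   `n_animals`, `excluded` (ids of empty animals).
#' @export
occupancy_distributions <- function(obs, breaks = NULL) {
  obs <- obs[!is.na(obs$value), , drop = FALSE]
  ids <- unique(obs$animal_id)
  counts <- table(obs$animal_id)
  excluded <- names(counts)[counts == 0]
  if (length(ids) < 1) stop("no observations")
  if (is.null(breaks)) {
    r <- range(obs$value)
    breaks <- seq(r[1] - 1e-9, r[2] + 1e-9, length.out = 42L)
  }
  pop <- graphics::hist(obs$value, breaks = breaks, plot = FALSE)$counts
  pop <- pop / sum(pop)
  per <- vapply(ids, function(id) {
    v <- obs$value[obs$animal_id == id]
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
    h / sum(h)
  }, numeric(length(breaks) - 1L))
  mean_ind <- if (is.matrix(per)) rowMeans(per) else per
  list(breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       population = pop, mean_individual = mean_ind,
       n_animals = length(ids), excluded = excluded)
}

# Bias-corrected sample skewness (G1) and excess kurtosis (G2).
sample_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  list(n = n, g1 = G1, g2 = G2)
}

#' Sarle's bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with `g1` the
#' bias-corrected sample skewness and `g2` the bias-corrected excess
#' kurtosis. The uniform distribution attains the critical value
#' `BC_crit = 5/9`; larger values indicate bimodality, a Gaussian gives
#' 1/3, and a symmetric two-point distribution approaches 1. BC is
#' invariant under affine transformation of the sample.
#'
#' @param x numeric sample, `n >= 4`, non-zero variance (otherwise an
#'   error).
#' @param corrected use the sample-corrected form (default); `FALSE` gives
#'   the asymptotic form `(skew^2 + 1) / (kurt + 3)` on uncorrected
#'   moments.
#' @return an object of class `bimodality_result`: list with `bc`,
#'   `bc_crit = 5/9`, `n`, `skewness`, `excess_kurtosis`, `is_bimodal`.
#' @examples
#' bimodality_coefficient(runif(1e4))   # about 5/9
#' bimodality_coefficient(rnorm(1e4))   # about 1/3
#' @export
bimodality_coefficient <- function(x, corrected = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("bimodality coefficient requires n >= 4")
  if (stats::var(x) == 0) stop("zero-variance sample")
  if (corrected) {
    mo <- sample_moments(x)
    bc <- (mo$g1^2 + 1) /
      (mo$g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
    g1 <- mo$g1; g2 <- mo$g2
  } else {
    m <- mean(x); m2 <- mean((x - m)^2)
    g1 <- mean((x - m)^3) / m2^1.5
    g2 <- mean((x - m)^4) / m2^2 - 3
    bc <- (g1^2 + 1) / (g2 + 3)
  }
  structure(list(bc = bc, bc_crit = 5 / 9, n = n,
                 skewness = g1, excess_kurtosis = g2,
                 is_bimodal = bc > 5 / 9),
            class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat(sprintf("BC = %.4f (n = %d, crit = 5/9 = %.4f) -> %s\n",
              x$bc, x$n, 5 / 9,
              if (x$is_bimodal) "bimodal" else "not bimodal"))
  invisible(x)
}

#' Asymptotic bimodality coefficient from distribution moments
#'
#' `(skewness^2 + 1) / (excess_kurtosis + 3)`: the large-n limit of
#' [bimodality_coefficient()], evaluated on exact distribution moments.
#' For the uniform distribution (skewness 0, excess kurtosis -6/5) this is
#' exactly 5/9.
#'
#' @param skewness distribution skewness.
#' @param excess_kurtosis distribution excess kurtosis.
#' @return the asymptotic BC.
#' @export
bc_asymptotic <- function(skewness, excess_kurtosis) {
  (skewness^2 + 1) / (excess_kurtosis + 3)
}

#' Compare bimodality coefficients between two conditions
#'
#' BC is computed on the per-animal summary values (one number per animal)
#' within each condition. Significance of the difference is assessed by
#' permuting condition labels over animals (two-sided tail fraction of the
#' null `|delta BC|` distribution, with the +1 small-sample correction);
#' a case-resampling bootstrap over animals gives a CI for `delta BC`.
#'
#' @param a,b numeric vectors of per-animal values for conditions A and B.
#' @param n_perm label permutations (default 999).
#' @param n_boot bootstrap resamples for the CI (default 999).
#' @param seed RNG seed.
#' @param conf CI level (default 0.95).
#' @return list with `bc_a`, `bc_b`, `delta_bc` (B - A), `p` (permutation),
#'   `ci` (bootstrap), `crosses_crit` (logical 2-vector), `warnings`.
#' @export
compare_bc <- function(a, b, n_perm = 999L, n_boot = 999L, seed = 1L,
                       conf = 0.95) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  warn <- character(0)
  if (length(a) < 8 || length(b) < 8)
    warn <- c(warn, "fewer than 8 animals in a condition; BC is moment-based and unstable at small n")
  bc_a <- bimodality_coefficient(a)$bc
  bc_b <- bimodality_coefficient(b)$bc
  d_obs <- bc_b - bc_a
  with_preserved_rng({
    set.seed(seed)
    pool <- c(a, b)
    na <- length(a)
    d_null <- vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(length(pool), na)
      pa <- pool[idx]; pb <- pool[-idx]
      if (stats::var(pa) == 0 || stats::var(pb) == 0) return(NA_real_)
      bimodality_coefficient(pb)$bc - bimodality_coefficient(pa)$bc
    }, numeric(1))
    d_null <- d_null[!is.na(d_null)]
    p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + length(d_null))
    d_boot <- vapply(seq_len(n_boot), function(k) {
      ra <- sample(a, replace = TRUE); rb <- sample(b, replace = TRUE)
      if (stats::var(ra) == 0 || stats::var(rb) == 0) return(NA_real_)
      bimodality_coefficient(rb)$bc - bimodality_coefficient(ra)$bc
    }, numeric(1))
    d_boot <- d_boot[!is.na(d_boot)]
    qs <- stats::quantile(d_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
    list(bc_a = bc_a, bc_b = bc_b, delta_bc = d_obs, p = p,
         ci = qs, crosses_crit = c(a = bc_a > 5 / 9, b = bc_b > 5 / 9),
         n = c(a = length(a), b = length(b)), warnings = warn)
  })
}
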