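#' Configuration for the synthetic synaptosome particle generator
#'
#' Models imaged synaptosomes carrying two fluorescence markers (e.g. a
#' presynaptic and a postsynaptic label) as a mixture of four latent
#' populations: colocalized (both markers present), single-marker A or B,
#' and negative. Intensities are drawn log-normally per latent state and
#' exported on the linear scale, where quadrant gating operates.
#'
#' Within colocalized particles the two log intensities are drawn from a
#' bivariate Gaussian whose Pearson correlation is chosen via the Gaussian
#' copula identity `rho_pearson = 2 * sin(pi * rho_spearman / 6)` so that the
#' rank correlation targets `rho_coloc`.
#'
#' @param n_particles number of particles.
#' @param frac_colocalized fraction of *marker-positive* particles in the
#'   colocalized state; the marker-positive remainder is split evenly
#'   between A-only and B-only.
#' @param frac_negative fraction of all particles in the double-negative
#'   baseline state (debris / unlabelled events, gated into Q1
#'   downstream).
#' @param mu_pos,mu_neg log-scale mean intensity of a marker when present /
#'   absent; `mu_pos` must exceed `mu_neg`.
#' @param sigma_log log-scale intensity SD (all states).
#' @param rho_coloc target Spearman rank correlation of the two intensities
#'   within colocalized particles, in \[0, 1\].
#' @param seed RNG seed used by [generate_particles()].
#' @return A validated list of class `"synth_particle_config"`.
#' @export
synth_particle_config <- function(n_particles = 5000L,
                                  frac_colocalized = 0.8,
                                  mu_pos = log(1000),
                                  mu_neg = log(100),
                                  sigma_log = 0.4,
                                  rho_coloc = 0.5,
                                  frac_negative = 0.2,
                                  seed = 1L) {
  n_particles <- check_count(n_particles, "n_particles")
  check_proportion(frac_colocalized, "frac_colocalized")
  if (!is.numeric(mu_pos) || !is.numeric(mu_neg) || mu_pos <= mu_neg) {
    stop_config("mu_pos", "mu_pos must be greater than mu_neg")
  }
  check_positive(sigma_log, "sigma_log")
  check_proportion(rho_coloc, "rho_coloc")
  check_proportion(frac_negative, "frac_negative")
  structure(list(n_particles = n_particles,
                 frac_colocalized = frac_colocalized,
                 mu_pos = mu_pos, mu_neg = mu_neg,
                 sigma_log = sigma_log, rho_coloc = rho_coloc,
                 frac_negative = frac_negative,
                 seed = as.integer(seed)),
            class = "synth_particle_config")
}

#' Generate synthetic two-marker particle intensities
#'
#' @param cfg a [synth_particle_config()].
#' @return A data frame with `particle_id`, `intensity_a`, `intensity_b`
#'   (linear, background-corrected scale) and the latent state
#'   `latent_state` in `{colocalized, a_only, b_only, negative}`.
#' @examples
#' head(generate_particles(synth_particle_config(n_particles = 100)))
#' @export
generate_particles <- function(cfg) {
  if (!inherits(cfg, "synth_particle_config")) {
    cfg <- do.call(synth_particle_config, cfg)
  }
  with_seed_(cfg$seed, {
    n <- cfg$n_particles
    pos <- 1 - cfg$frac_negative
    single <- pos * (1 - cfg$frac_colocalized) / 2
    state <- sample(c("colocalized", "a_only", "b_only", "negative"), n,
                    replace = TRUE,
                    prob = c(pos * cfg$frac_colocalized, single, single,
                             cfg$frac_negative))
    la <- numeric(n)
    lb <- numeric(n)
    co <- state == "colocalized"
    if (any(co)) {
      # Gaussian copula: Pearson rho giving the target Spearman rho
      rho <- 2 * sin(pi * cfg$rho_coloc / 6)
      z1 <- rnorm(sum(co))
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(sum(co))
      la[co] <- cfg$mu_pos + cfg$sigma_log * z1
      lb[co] <- cfg$mu_pos + cfg$sigma_log * z2
    }
    for (s in c("a_only", "b_only", "negative")) {
      idx <- state == s
      if (!any(idx)) next
      mu_a <- if (s == "a_only") cfg$mu_pos else cfg$mu_neg
      mu_b <- if (s == "b_only") cfg$mu_pos else cfg$mu_neg
      la[idx] <- rnorm(sum(idx), mu_a, cfg$sigma_log)
      lb[idx] <- rnorm(sum(idx), mu_b, cfg$sigma_log)
    }
    data.frame(particle_id = sprintf("pt%06d", seq_len(n)),
               intensity_a = exp(la), intensity_b = exp(lb),
               latent_state = state, stringsAsFactors = FALSE)
  })
}
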