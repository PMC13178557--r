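#' Configuration for the synthetic dendrite/spine/puncta geometry generator
#'
#' Emulates deconvolved confocal stacks of traced dendrites carrying
#' dual-label spines: every spine of a labelled dendrite bears a YFP punctum
#' (total-input label), a planted fraction additionally bears a CFP punctum
#' (engram-input label), and a Grm5 punctum is present with a probability
#' that depends on the spine class (EE = YFP+CFP+, NE = YFP+CFP-). Puncta are
#' displaced from the spine terminal by isotropic Gaussian jitter.
#'
#' Defaults reflect the emulated dataset: 47 dendrites from 5 animals with
#' roughly 48 spines each, 61.2% of YFP+ spines also CFP+, and Grm5 presence
#' probabilities 0.397 (EE) vs 0.344 (NE), i.e. a planted colocalization odds
#' ratio of about 1.26.
#'
#' @param n_dendrites number of dendrites.
#' @param spines_per_dendrite spines per dendrite.
#' @param frac_cfp_positive fraction of YFP+ spines that are also CFP+.
#' @param p_grm5_given_EE,p_grm5_given_NE probability that a spine of the
#'   given class carries a Grm5 punctum.
#' @param spot_jitter_nm SD (nm, per axis) of puncta displacement from the
#'   spine terminal.
#' @param n_animals number of animals the dendrites are distributed over.
#' @param seed RNG seed used by [generate_geometry()].
#' @return A validated list of class `"synth_geometry_config"`.
#' @export
synth_geometry_config <- function(n_dendrites = 47L,
                                  spines_per_dendrite = 48L,
                                  frac_cfp_positive = 0.612,
                                  p_grm5_given_EE = 0.397,
                                  p_grm5_given_NE = 0.344,
                                  spot_jitter_nm = 50,
                                  n_animals = 5L,
                                  seed = 1L) {
  n_dendrites <- check_count(n_dendrites, "n_dendrites")
  spines_per_dendrite <- check_count(spines_per_dendrite,
                                     "spines_per_dendrite")
  check_proportion(frac_cfp_positive, "frac_cfp_positive")
  check_proportion(p_grm5_given_EE, "p_grm5_given_EE")
  check_proportion(p_grm5_given_NE, "p_grm5_given_NE")
  check_positive(spot_jitter_nm, "spot_jitter_nm", strict = FALSE)
  n_animals <- check_count(n_animals, "n_animals")
  structure(list(n_dendrites = n_dendrites,
                 spines_per_dendrite = spines_per_dendrite,
                 frac_cfp_positive = frac_cfp_positive,
                 p_grm5_given_EE = p_grm5_given_EE,
                 p_grm5_given_NE = p_grm5_given_NE,
                 spot_jitter_nm = spot_jitter_nm,
                 n_animals = n_animals,
                 seed = as.integer(seed)),
            class = "synth_geometry_config")
}

#' Generate synthetic filament traces, spine terminals and fluorescence spots
#'
#' Dendrites are random polylines in continuous nm coordinates (ordered
#' vertex lists). Spine terminals sit 50-150 nm off the polyline in a
#' random perpendicular direction: the polyline stands in for the traced
#' filament skeleton *including* spine branches, so true puncta lie within
#' the published spot-to-filament pre-filter distances. YFP spots are placed at every spine
#' terminal (plus jitter), CFP spots at the planted CFP+ fraction, and Grm5
#' spots per the class-conditional presence probabilities. Grm5 spots carry
#' log-normal integrated and average intensities.
#'
#' @param cfg a [synth_geometry_config()].
#' @return A list with components:
#'   \describe{
#'     \item{traces}{data frame of polyline vertices: `dendrite_id`,
#'       `animal_id`, `vertex`, `x`, `y`, `z` (nm).}
#'     \item{spines}{data frame: `spine_id`, `dendrite_id`, `animal_id`,
#'       terminal `x`, `y`, `z`, and planted truth flags
#'       `cfp_positive_true`, `grm5_true`.}
#'     \item{spots}{data frame: `spot_id`, `channel`
#'       (`YFP`/`CFP`/`GRM5`), `x`, `y`, `z`, `integrated_intensity`,
#'       `average_intensity` (NA outside the GRM5 channel), and the source
#'       `spine_id` (ground truth, not used by registration).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_geometry <- function(cfg) {
  if (!inherits(cfg, "synth_geometry_config")) {
    cfg <- do.call(synth_geometry_config, cfg)
  }
  with_seed_(cfg$seed, {
    nd <- cfg$n_dendrites
    ns <- cfg$spines_per_dendrite
    animal <- sprintf("a%02d", rep_len(seq_len(cfg$n_animals), nd))

    traces <- vector("list", nd)
    spines <- vector("list", nd)
    step_nm <- 1000
    n_vert <- 11L
    for (d in seq_len(nd)) {
      dendrite_id <- sprintf("d%03d", d)
      # random-walk polyline with gently drifting direction
      origin <- runif(3, 0, 50000)
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      verts <- matrix(NA_real_, n_vert, 3)
      verts[1, ] <- origin
      for (v in 2:n_vert) {
        dir <- dir + rnorm(3, 0, 0.15)
        dir <- dir / sqrt(sum(dir^2))
        verts[v, ] <- verts[v - 1, ] + step_nm * dir
      }
      traces[[d]] <- data.frame(dendrite_id = dendrite_id,
                                animal_id = animal[d],
                                vertex = seq_len(n_vert),
                                x = verts[, 1], y = verts[, 2], z = verts[, 3],
                                stringsAsFactors = FALSE)

      # spine base points uniformly along the polyline, terminals offset
      # perpendicular to the local segment direction
      seg <- sample.int(n_vert - 1L, ns, replace = TRUE)
      tt <- runif(ns)
      base <- verts[seg, , drop = FALSE] +
        tt * (verts[seg + 1L, , drop = FALSE] - verts[seg, , drop = FALSE])
      axis <- verts[seg + 1L, , drop = FALSE] - verts[seg, , drop = FALSE]
      axis <- axis / sqrt(rowSums(axis^2))
      rand <- matrix(rnorm(3 * ns), ns, 3)
      perp <- rand - axis * rowSums(rand * axis)
      perp <- perp / sqrt(rowSums(perp^2))
      neck <- runif(ns, 50, 150)
      term <- base + perp * neck
      spines[[d]] <- data.frame(
        spine_id = sprintf("%s_s%03d", dendrite_id, seq_len(ns)),
        dendrite_id = dendrite_id, animal_id = animal[d],
        x = term[, 1], y = term[, 2], z = term[, 3],
        cfp_positive_true = runif(ns) < cfg$frac_cfp_positive,
        stringsAsFactors = FALSE)
    }
    traces <- do.call(rbind, traces)
    spines <- do.call(rbind, spines)
    rownames(traces) <- rownames(spines) <- NULL
    p_grm5 <- ifelse(spines$cfp_positive_true,
                     cfg$p_grm5_given_EE, cfg$p_grm5_given_NE)
    spines$grm5_true <- runif(nrow(spines)) < p_grm5

    jitter_spot <- function(idx, channel, with_intensity = FALSE) {
      k <- length(idx)
      if (k == 0L) {
        return(data.frame(spot_id = character(), channel = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          integrated_intensity = numeric(),
                          average_intensity = numeric(),
                          spine_id = character(), stringsAsFactors = FALSE))
      }
      data.frame(
        spot_id = sprintf("%s_%05d", tolower(channel), seq_len(k)),
        channel = channel,
        x = spines$x[idx] + rnorm(k, 0, cfg$spot_jitter_nm),
        y = spines$y[idx] + rnorm(k, 0, cfg$spot_jitter_nm),
        z = spines$z[idx] + rnorm(k, 0, cfg$spot_jitter_nm),
        integrated_intensity = if (with_intensity)
          rlnorm(k, 12, 3.15) else NA_real_,
        average_intensity = if (with_intensity)
          rlnorm(k, 8.84, 0.53) else NA_real_,
        spine_id = spines$spine_id[idx],
        stringsAsFactors = FALSE)
    }
    spots <- rbind(
      jitter_spot(seq_len(nrow(spines)), "YFP"),
      jitter_spot(which(spines$cfp_positive_true), "CFP"),
      jitter_spot(which(spines$grm5_true), "GRM5", with_intensity = TRUE))
    rownames(spots) <- NULL
    list(traces = traces, spines = spines, spots = spots, config = cfg)
  })
}
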