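#' Shortest distance from a 3D point to a polyline
#'
#' Minimum Euclidean distance from `spot` to any segment of the ordered
#' vertex list `vertices`, using the closed-form point-to-segment
#' projection clamped to the segment ends. Zero-length segments are
#' skipped.
#'
#' @param spot numeric length-3 vector (nm).
#' @param vertices numeric matrix with 3 columns, ordered polyline
#'   vertices (nm), at least 2 rows.
#' @return Distance in nm.
#' @examples
#' seg <- rbind(c(-1, 0, 0), c(1, 0, 0))
#' spot_to_filament_distance(c(0, 1, 0), seg)  # 1
#' spot_to_filament_distance(c(2, 1, 0), seg)  # sqrt(2)
#' @export
spot_to_filament_distance <- function(spot, vertices) {
  d <- filament_distances(matrix(spot, 1L, 3L), vertices)
  d[[1L]]
}

# Distances from many points (n x 3 matrix) to one polyline; vectorised
# over points per segment.
filament_distances <- function(points, vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(points) == 3L, ncol(vertices) == 3L,
            nrow(vertices) >= 2L, all(is.finite(vertices)))
  best <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[s, ]
    ab <- vertices[s + 1L, ] - a
    len2 <- sum(ab^2)
    if (len2 == 0) next  # degenerate segment
    ap <- sweep(points, 2L, a)
    tt <- pmin(1, pmax(0, (ap %*% ab) / len2))
    proj <- outer(drop(tt), ab)
    best <- pmin(best, sqrt(rowSums((ap - proj)^2)))
  }
  best
}

#' Filter spots by shortest distance to their filament traces
#'
#' Keeps a spot when its minimum distance to any filament trace is
#' strictly below the channel-specific threshold, mirroring the puncta
#' pre-filter applied before spine registration (500 nm for eGRASP
#' channels, 200 nm for Grm5 by default).
#'
#' @param spots data frame with `x`, `y`, `z` and `channel`.
#' @param traces data frame of polyline vertices with `dendrite_id`, `x`,
#'   `y`, `z` (ordered within dendrite).
#' @param max_dist_nm named numeric vector of thresholds per channel.
#' @return `spots` subset to retained rows, with an added
#'   `filament_distance` column.
#' @export
filter_spots_by_filament <- function(spots, traces,
                                     max_dist_nm = c(YFP = 500, CFP = 500,
                                                     GRM5 = 200)) {
  pts <- as.matrix(spots[, c("x", "y", "z")])
  dmin <- rep(Inf, nrow(spots))
  for (d in unique(traces$dendrite_id)) {
    verts <- as.matrix(traces[traces$dendrite_id == d, c("x", "y", "z")])
    dmin <- pmin(dmin, filament_distances(pts, verts))
  }
  thr <- max_dist_nm[spots$channel]
  if (any(is.na(thr))) {
    stop("no distance threshold for channel(s): ",
         paste(unique(spots$channel[is.na(thr)]), collapse = ", "),
         call. = FALSE)
  }
  out <- spots[dmin < thr, , drop = FALSE]
  out$filament_distance <- dmin[dmin < thr]
  rownames(out) <- NULL
  out
}

#' Register spots to the nearest spine terminal within a distance cutoff
#'
#' A spot is assigned to a spine when the Euclidean distance between the
#' spine terminal and the spot position is strictly below `max_dist_nm`;
#' when several spines qualify, the nearest wins, with exact ties broken
#' by the lexicographically lower `spine_id`. Unassigned spots are
#' retained with `spine_id = NA`.
#'
#' @param spots data frame with `spot_id`, `x`, `y`, `z` (and typically
#'   `channel`).
#' @param spines data frame with `spine_id`, `x`, `y`, `z`.
#' @param max_dist_nm registration cutoff in nm (default 700).
#' @return Data frame: `spot_id`, (`channel`,) `spine_id`, `distance`,
#'   `assigned`.
#' @export
register_spots <- function(spots, spines, max_dist_nm = 700) {
  check_positive(max_dist_nm, "max_dist_nm")
  ord <- order(spines$spine_id)
  spines <- spines[ord, , drop = FALSE]
  sp <- as.matrix(spines[, c("x", "y", "z")])
  pts <- as.matrix(spots[, c("x", "y", "z")])
  n <- nrow(pts)
  nearest <- integer(n)
  ndist <- numeric(n)
  # distance matrix in blocks to bound memory on large spot sets
  block <- 2000L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rowSums(sp^2), "+") -
      2 * pts[idx, , drop = FALSE] %*% t(sp)
    d2[d2 < 0] <- 0
    # which.min returns the first minimum; spines are sorted by spine_id,
    # so exact ties resolve to the lower id
    nearest[idx] <- apply(d2, 1L, which.min)
    # recompute the winning distance by direct subtraction: the quadratic
    # expansion above can lose ~1e-3 nm at large coordinates
    ndist[idx] <- sqrt(rowSums((pts[idx, , drop = FALSE] -
                                  sp[nearest[idx], , drop = FALSE])^2))
  }
  assigned <- ndist < max_dist_nm
  out <- data.frame(spot_id = spots$spot_id,
                    spine_id = ifelse(assigned, spines$spine_id[nearest],
                                      NA_character_),
                    distance = ndist,
                    assigned = assigned,
                    stringsAsFactors = FALSE)
  if ("channel" %in% names(spots)) {
    out <- cbind(out[, "spot_id", drop = FALSE],
                 channel = spots$channel,
                 out[, c("spine_id", "distance", "assigned")])
  }
  rownames(out) <- NULL
  out
}

#' Dual-channel spine classification and per-dendrite overlap percentages
#'
#' Flags each spine YFP+ / CFP+ when at least one spot of that channel
#' registered to it, then computes per dendrite the percentage of YFP+
#' spines that are also CFP+ and the percentage of CFP+ spines that are
#' also YFP+, pooling as mean +/- SEM across dendrites. Dendrites with a
#' zero denominator are excluded from that percentage and listed.
#'
#' @param spines data frame with `spine_id`, `dendrite_id`.
#' @param assignments a [register_spots()] result (or a row-bound set of
#'   them) with a `channel` column covering `YFP` and `CFP`.
#' @return List of class `"overlap_result"`: `spine_flags` (per spine
#'   logicals `yfp`, `cfp`), `per_dendrite` (counts and percentages),
#'   `pooled` (means and SEMs), `excluded` (dendrite/metric pairs
#'   skipped).
#' @export
classify_and_overlap <- function(spines, assignments) {
  hits <- assignments[assignments$assigned, , drop = FALSE]
  yfp_ids <- unique(hits$spine_id[hits$channel == "YFP"])
  cfp_ids <- unique(hits$spine_id[hits$channel == "CFP"])
  flags <- data.frame(spine_id = spines$spine_id,
                      dendrite_id = spines$dendrite_id,
                      yfp = spines$spine_id %in% yfp_ids,
                      cfp = spines$spine_id %in% cfp_ids,
                      stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(split(flags, flags$dendrite_id), function(g) {
    n_yfp <- sum(g$yfp)
    n_cfp <- sum(g$cfp)
    n_both <- sum(g$yfp & g$cfp)
    data.frame(dendrite_id = g$dendrite_id[1],
               n_spines = nrow(g), n_yfp = n_yfp, n_cfp = n_cfp,
               n_both = n_both,
               pct_cfp_of_yfp = if (n_yfp > 0) 100 * n_both / n_yfp
                                else NA_real_,
               pct_yfp_of_cfp = if (n_cfp > 0) 100 * n_both / n_cfp
                                else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  excluded <- c(
    if (any(is.na(per$pct_cfp_of_yfp)))
      paste0(per$dendrite_id[is.na(per$pct_cfp_of_yfp)], ":no_yfp"),
    if (any(is.na(per$pct_yfp_of_cfp)))
      paste0(per$dendrite_id[is.na(per$pct_yfp_of_cfp)], ":no_cfp"))
  pool <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n_dendrites = length(v))
  }
  structure(list(spine_flags = flags, per_dendrite = per,
                 pooled = list(cfp_of_yfp = pool(per$pct_cfp_of_yfp),
                               yfp_of_cfp = pool(per$pct_yfp_of_cfp)),
                 excluded = excluded),
            class = "overlap_result")
}

#' Colocalization odds ratio with cluster-bootstrap confidence interval
#'
#' Cross-product odds ratio for punctum presence in engram-to-engram
#' (YFP+CFP+, `EE`) versus nonengram-to-engram (YFP+CFP-, `NE`) spines,
#' with a percentile confidence interval from a cluster bootstrap that
#' resamples dendrites with replacement within animals. This is the
#' declared stand-in for a hierarchical mixed-effects logistic model: the
#' bootstrap respects the dendrite/animal clustering without fitting
#' random effects. Zero cells get the Haldane-Anscombe 0.5 correction,
#' flagged in the output.
#'
#' @param spine_class character vector, `"EE"` or `"NE"` per spine.
#' @param present logical vector: punctum (e.g. Grm5) registered to the
#'   spine.
#' @param dendrite_id,animal_id cluster identifiers per spine.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return List of class `"coloc_or"`: `or`, `ci_low`, `ci_high`,
#'   `counts` (2 x 2), `corrected`, `n_boot`, `n_degenerate` (replicates
#'   without both classes, dropped).
#' @export
colocalization_or <- function(spine_class, present, dendrite_id, animal_id,
                              n_boot = 2000L, seed = NULL, conf = 0.95) {
  stopifnot(length(spine_class) == length(present),
            length(dendrite_id) == length(spine_class),
            length(animal_id) == length(spine_class))
  if (!all(spine_class %in% c("EE", "NE"))) {
    stop("spine_class must be 'EE' or 'NE'", call. = FALSE)
  }
  n_boot <- check_count(n_boot, "n_boot")
  or_from <- function(cls, pres) {
    a <- sum(cls == "EE" & pres)
    b <- sum(cls == "EE" & !pres)
    cc <- sum(cls == "NE" & pres)
    d <- sum(cls == "NE" & !pres)
    corrected <- any(c(a, b, cc, d) == 0)
    if (corrected) {
      a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    list(or = (a * d) / (b * cc), counts = c(EE_present = a, EE_absent = b,
                                             NE_present = cc, NE_absent = d),
         corrected = corrected)
  }
  point <- or_from(spine_class, present)
  lookup <- split(seq_along(spine_class), dendrite_id)
  animals <- split(unique(dendrite_id),
                   animal_id[match(unique(dendrite_id), dendrite_id)])
  alpha <- (1 - conf) / 2
  with_seed_(seed, {
    ors <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(animals, function(dd) {
        picked <- dd[sample.int(length(dd), length(dd), replace = TRUE)]
        unlist(lookup[picked], use.names = FALSE)
      }), use.names = FALSE)
      cls <- spine_class[idx]
      if (length(unique(cls)) < 2L) next  # degenerate resample
      ors[b] <- or_from(cls, present[idx])$or
    }
    n_degenerate <- sum(is.na(ors))
    ci <- quantile(ors, probs = c(alpha, 1 - alpha), na.rm = TRUE,
                   names = FALSE)
    structure(list(or = point$or, ci_low = ci[1], ci_high = ci[2],
                   counts = point$counts, corrected = point$corrected,
                   n_boot = n_boot, n_degenerate = n_degenerate),
              class = "coloc_or")
  })
}

#' Per-class log-intensity summaries of puncta
#'
#' Natural-log transform of integrated and average punctum intensities,
#' summarised per spine class by median and interquartile range. Classes
#' without puncta are skipped with a message.
#'
#' @param spots data frame with `spine_class`, `integrated_intensity`,
#'   `average_intensity`.
#' @return Data frame: `spine_class`, `n`, `log_median_integrated`,
#'   `log_iqr_integrated`, `log_median_average`, `log_iqr_average`.
#' @export
puncta_intensity_summary <- function(spots) {
  need <- c("spine_class", "integrated_intensity", "average_intensity")
  stopifnot(all(need %in% names(spots)))
  groups <- split(spots, spots$spine_class)
  rows <- lapply(names(groups), function(g) {
    s <- groups[[g]]
    s <- s[is.finite(s$integrated_intensity) & s$integrated_intensity > 0 &
             is.finite(s$average_intensity) & s$average_intensity > 0, ,
           drop = FALSE]
    if (nrow(s) == 0L) {
      message("no puncta in class ", g, "; skipped")
      return(NULL)
    }
    li <- log(s$integrated_intensity)
    la <- log(s$average_intensity)
    data.frame(spine_class = g, n = nrow(s),
               log_median_integrated = median(li),
               log_iqr_integrated = stats::IQR(li),
               log_median_average = median(la),
               log_iqr_average = stats::IQR(la),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
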