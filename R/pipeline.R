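#' Track bones across dynamic frames
#'
#' Produces the per-frame rigid transform chain for all five bones. When the
#' sequence carries per-frame point-cloud targets (e.g. from [degrade()] or
#' a real dynamic acquisition), each bone is registered to each frame with
#' point-to-plane ICP, initialized from the previous frame's pose (frame 1
#' from identity); when only poses are present they are passed through
#' unchanged. Landmarks are transported by these transforms and never
#' re-detected per frame.
#'
#' @param seq A `dynamic_sequence`.
#' @param subsample Use every `subsample`-th static vertex as ICP source
#'   points (speed/accuracy trade-off).
#' @param flag_residual_mm Frames whose RMS registration residual exceeds
#'   this value are flagged (default twice the dynamic-scan voxel diagonal,
#'   2 * |(0.59, 0.59, 0.50)| mm).
#' @param ... Passed to [rigid_register()].
#' @return A list with `transforms` (per frame, named list per bone),
#'   `rms` (frame x bone matrix, `NA` for pass-through) and `flagged`
#'   (logical per frame).
#' @export
track_sequence <- function(seq, subsample = 3L,
                           flag_residual_mm = 2 * sqrt(sum(c(0.59, 0.59,
                                                             0.50)^2)),
                           ...) {
  stopifnot(inherits(seq, "dynamic_sequence"))
  bones <- names(seq$static$meshes)
  n <- length(seq$poses)
  if (is.null(seq$targets)) {
    return(list(
      transforms = seq$poses,
      rms = matrix(NA_real_, n, length(bones),
                   dimnames = list(NULL, bones)),
      flagged = rep(FALSE, n)
    ))
  }
  rms <- matrix(NA_real_, n, length(bones), dimnames = list(NULL, bones))
  transforms <- vector("list", n)
  prev <- stats::setNames(rep(list(rigid_transform()), length(bones)), bones)
  for (i in seq_len(n)) {
    cur <- prev
    for (b in bones) {
      src <- seq$static$meshes[[b]]$vertices
      src <- src[seq(1L, nrow(src), by = subsample), , drop = FALSE]
      tr <- suppressWarnings(
        rigid_register(src, seq$targets[[i]][[b]], init = prev[[b]], ...)
      )
      cur[[b]] <- tr
      # report residual as mean point-to-cloud distance of the fit
      aligned <- transform_points(tr, src)
      nn <- nearest_neighbours(aligned, seq$targets[[i]][[b]])
      rms[i, b] <- sqrt(mean(nn$dist^2))
    }
    transforms[[i]] <- cur
    prev <- cur
  }
  list(transforms = transforms, rms = rms,
       flagged = apply(rms, 1, max) > flag_residual_mm)
}

#' Evaluate the four parameters over a dynamic sequence
#'
#' Detects the static landmark set once (or accepts provided landmarks),
#' transports landmarks and meshes by the per-frame transforms, and
#' computes the wrist angle, 3-D ulnar variance, ulnocarpal proximities and
#' both DRUJ stability parameters per frame, plus delta values relative to
#' the neutral frame. Per-frame failures yield `NA` samples with a warning,
#' not aborts.
#'
#' @param seq A `dynamic_sequence`.
#' @param transforms Per-frame transforms (e.g. from [track_sequence()]);
#'   default: the sequence's own poses.
#' @param landmarks Optional [landmark_set()] (or path to landmark JSON)
#'   bypassing automatic detection.
#' @param config Detector configuration, see [detect_landmarks()].
#' @return A parameter time-series data frame with columns `frame_index`,
#'   `time_s`, `movement`, `wrist_angle_deg`, `uv3d_mm`, `ucp_l_mm`,
#'   `ucp_t_mm`, `mru3d_pct`, `epi3d_pct`, `d_uv3d_mm`, `d_mru3d_pct`,
#'   `d_epi3d_pct`; measurement sites are in attribute `sites`.
#' @export
evaluate_sequence <- function(seq, transforms = NULL, landmarks = NULL,
                              config = list()) {
  stopifnot(inherits(seq, "dynamic_sequence"))
  if (is.null(transforms)) transforms <- seq$poses
  if (is.list(transforms) && !is.null(transforms$transforms)) {
    transforms <- transforms$transforms
  }
  meshes <- seq$static$meshes
  frame <- seq$static$frame
  lm <- detect_landmarks(meshes$radius, meshes$ulna, frame,
                         config = config, provided = landmarks)
  cap_axis <- principal_longitudinal_axis(meshes$capitate, frame)$direction
  cfg <- utils::modifyList(list(head_fraction = 0.15,
                                styloid_cylinder_radius = 4), config)

  rows <- vector("list", length(transforms))
  sites <- vector("list", length(transforms))
  for (i in seq_along(transforms)) {
    pose <- transforms[[i]]
    rows[[i]] <- tryCatch({
      lm_t <- transport_landmarks(lm, pose)
      frame_t <- frame_transform(frame, pose$radius)
      cap_axis_t <- as.numeric(pose$capitate$rotation %*% cap_axis)
      ang <- if (seq$movement == "PS") {
        wrist_angle("PS", frame_t,
                    styloid_tip = lm_t$points$ulnar_styloid_tip,
                    epicentre = lm_t$points$ulnar_epicentre)
      } else {
        wrist_angle(seq$movement, frame_t, capitate_axis = cap_axis_t)
      }
      ulna_t <- mesh_transform(meshes$ulna, pose$ulna)
      # the head palmar point is re-evaluated in the instantaneous frame
      # (the palmar direction rotates with the radius during PS)
      if (lm$source == "auto") {
        lm_t$points$ulnar_head_palmar_point <- ulnar_head_palmar_point(
          ulna_t, frame_t, cfg$head_fraction, cfg$styloid_cylinder_radius)
      }
      ucp_l <- ulnocarpal_proximity(ulna_t,
                                    mesh_transform(meshes$lunate,
                                                   pose$lunate))
      ucp_t <- ulnocarpal_proximity(ulna_t,
                                    mesh_transform(meshes$triquetrum,
                                                   pose$triquetrum))
      sites[[i]] <- list(ucp_l = ucp_l[c("site_ulna", "site_carpal")],
                         ucp_t = ucp_t[c("site_ulna", "site_carpal")])
      data.frame(
        frame_index = i, time_s = (i - 1) / seq$frame_rate,
        movement = seq$movement, wrist_angle_deg = ang,
        uv3d_mm = ulnar_variance_3d(lm_t$points$distal_ulnar_point,
                                    lm_t$points$sigmoid_distal_point,
                                    frame_t),
        ucp_l_mm = ucp_l$distance, ucp_t_mm = ucp_t$distance,
        mru3d_pct = mru_3d(lm_t, frame_t),
        epi3d_pct = epicentre_3d(lm_t, frame_t)
      )
    }, error = function(e) {
      warning(sprintf("frame %d failed: %s", i, conditionMessage(e)))
      data.frame(frame_index = i, time_s = (i - 1) / seq$frame_rate,
                 movement = seq$movement, wrist_angle_deg = NA_real_,
                 uv3d_mm = NA_real_, ucp_l_mm = NA_real_,
                 ucp_t_mm = NA_real_, mru3d_pct = NA_real_,
                 epi3d_pct = NA_real_)
    })
  }
  out <- delta_series(do.call(rbind, rows))
  attr(out, "sites") <- sites
  attr(out, "landmarks") <- lm
  out
}

#' Write or read a parameter time series as CSV
#'
#' RFC 4180 CSV with `.` as decimal separator and a fixed column order, so
#' identical runs produce byte-identical files.
#'
#' @param series Parameter series data frame (see [evaluate_sequence()]).
#' @param path File path.
#' @return `write_parameter_series()` returns `path` invisibly;
#'   `read_parameter_series()` returns the data frame.
#' @export
write_parameter_series <- function(series, path) {
  cols <- c("frame_index", "time_s", "movement", "wrist_angle_deg",
            "uv3d_mm", "ucp_l_mm", "ucp_t_mm", "mru3d_pct", "epi3d_pct",
            "d_uv3d_mm", "d_mru3d_pct", "d_epi3d_pct")
  for (cl in setdiff(cols, names(series))) series[[cl]] <- NA_real_
  out <- series[, cols]
  names(out)[1] <- "frame"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_parameter_series
#' @export
read_parameter_series <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(out)[1] == "frame") names(out)[1] <- "frame_index"
  out
}

#' Range of motion of a parameter trajectory
#'
#' Maximum minus minimum over a wrist's trajectory; `NA` frames are
#' dropped.
#'
#' @param values Numeric vector of one parameter across a wrist's frames.
#' @return Non-negative scalar range.
#' @export
motion_range <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("empty series")
  max(values) - min(values)
}

#' Pool per-wrist series into angle-binned cohort summaries
#'
#' Bins each wrist's samples by wrist angle; within each bin a wrist
#' contributes one value per parameter (its mean over the frames it has in
#' that bin), and the cohort summary is the median and IQR (linear
#' interpolation quartiles) across contributing wrists. Bins visited by
#' fewer than `min_count` wrists are masked: they report `NA` summaries,
#' mirroring cohort plots that only display the range of motion achieved by
#' a minimum number of wrists.
#'
#' @param series_list List of per-wrist parameter series data frames.
#' @param bin_width Bin width in degrees (default 5).
#' @param min_count Minimum wrists per reported bin (default 22).
#' @param parameters Parameter columns to summarize.
#' @return A `cohort_summary` data frame: `bin_center`, `n_wrists`,
#'   `masked`, and `<param>_median`, `<param>_q1`, `<param>_q3` columns.
#' @export
bin_by_angle <- function(series_list, bin_width = 5, min_count = 22,
                         parameters = c("uv3d_mm", "ucp_l_mm", "ucp_t_mm",
                                        "mru3d_pct", "epi3d_pct",
                                        "d_uv3d_mm", "d_mru3d_pct",
                                        "d_epi3d_pct")) {
  stopifnot(length(series_list) >= 1, bin_width > 0)
  parameters <- intersect(parameters, names(series_list[[1]]))
  per_wrist <- lapply(seq_along(series_list), function(w) {
    s <- series_list[[w]]
    s <- s[is.finite(s$wrist_angle_deg), , drop = FALSE]
    bin <- floor(s$wrist_angle_deg / bin_width)
    agg <- stats::aggregate(s[parameters], by = list(bin = bin), mean,
                            na.rm = TRUE)
    agg$wrist <- w
    agg
  })
  all_bins <- do.call(rbind, per_wrist)
  bins <- sort(unique(all_bins$bin))
  out <- lapply(bins, function(b) {
    sub <- all_bins[all_bins$bin == b, , drop = FALSE]
    n <- nrow(sub)
    masked <- n < min_count
    row <- data.frame(bin_center = (b + 0.5) * bin_width, n_wrists = n,
                      masked = masked)
    for (pcol in parameters) {
      if (masked) {
        row[[paste0(pcol, "_median")]] <- NA_real_
        row[[paste0(pcol, "_q1")]] <- NA_real_
        row[[paste0(pcol, "_q3")]] <- NA_real_
      } else {
        q <- stats::quantile(sub[[pcol]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                             type = 7, names = FALSE)
        row[[paste0(pcol, "_median")]] <- q[2]
        row[[paste0(pcol, "_q1")]] <- q[1]
        row[[paste0(pcol, "_q3")]] <- q[3]
      }
    }
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("cohort_summary", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "min_count") <- min_count
  out
}

#' Choose the reporting statistic by a normality gate
#'
#' Shapiro-Wilk test at `alpha`; non-normal samples are reported as median
#' with IQR (the conservative path), normal samples may be reported as mean
#' with SD. Sample sizes outside the test's 3..5000 support default to
#' median/IQR with a warning. Degenerate (constant) samples are reported as
#' median/IQR with a warning.
#'
#' @param values Numeric sample.
#' @param alpha Significance level (default 0.05).
#' @return A list with `decision` (`"report_median_iqr"` or
#'   `"report_mean_sd"`), `p_value`, and the corresponding `location` /
#'   `spread` values.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  med <- stats::median(values)
  iqr <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  fallback <- list(decision = "report_median_iqr", p_value = NA_real_,
                   location = med, spread = iqr)
  if (length(values) < 3 || length(values) > 5000) {
    warning("sample size outside 3..5000; defaulting to median/IQR")
    return(fallback)
  }
  if (stats::sd(values) == 0) {
    warning("constant sample; Shapiro-Wilk undefined, reporting median/IQR")
    return(fallback)
  }
  p <- stats::shapiro.test(values)$p.value
  if (p < alpha) {
    list(decision = "report_median_iqr", p_value = p, location = med,
         spread = iqr)
  } else {
    list(decision = "report_mean_sd", p_value = p, location = mean(values),
         spread = stats::sd(values))
  }
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n_wrists` phantoms with population variability (ulnar variance,
#' gaps, notch width, head size and coupling amplitudes jittered around the
#' defaults), simulates the requested movement for each, and returns the
#' wrists with their sequences. Fully reproducible from `seed`.
#'
#' @param movement `"FE"`, `"RUD"` or `"PS"`.
#' @param n_wrists Number of wrists (default 30 per movement).
#' @param seed Integer seed.
#' @param n_frames Frames per sequence.
#' @param vary Draw population variability (`FALSE` = identical wrists).
#' @param noise_sigma If > 0, [degrade()] each sequence with this vertex
#'   jitter.
#' @return List of lists with elements `wrist`, `motion`, `seq`.
#' @export
generate_cohort <- function(movement, n_wrists = 30L, seed = 1L,
                            n_frames = 11L, vary = TRUE, noise_sigma = 0) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  lapply(seq_len(n_wrists), function(i) {
    if (vary) {
      wp <- wrist_params(
        uv3d = clip(stats::rnorm(1, -0.4, 0.7), -1.8, 1.0),
        g_lunate = clip(stats::rnorm(1, 3.2, 0.5), 1.8, 4.6),
        g_triquetrum = clip(stats::rnorm(1, 6.9, 1.2), 4.5, 9.5),
        notch_width = clip(stats::rnorm(1, 18, 0.8), 15.5, 19.0),
        head_radius = clip(stats::rnorm(1, 10, 0.5), 9, 11),
        notch_depth = clip(stats::rnorm(1, 2.2, 0.15), 1.9, 2.6)
      )
      mp <- motion_params(movement, n_frames = n_frames,
                          coupling_scale = stats::runif(1, 0.8, 1.2))
    } else {
      wp <- wrist_params()
      mp <- motion_params(movement, n_frames = n_frames)
    }
    w <- generate_wrist(wp)
    s <- simulate_motion(w, mp)
    if (noise_sigma > 0) {
      s <- degrade(s, sigma = noise_sigma,
                   seed = (seed * 1000L + i) %% .Machine$integer.max)
    }
    list(wrist = w, motion = mp, seq = s)
  })
}
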