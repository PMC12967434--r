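#' Format and parse "median (IQR)" cells
#'
#' One-decimal formatting used by the cohort summary table, e.g.
#' `"-0.4 (-1.5 to 0.3)"`. `parse_median_iqr()` round-trips the three
#' numbers at that precision.
#'
#' @param m,q1,q3 Median and quartiles.
#' @param text A formatted cell.
#' @return A character scalar / a named numeric vector `c(median, q1, q3)`.
#' @export
format_median_iqr <- function(m, q1, q3) {
  sprintf("%.1f (%.1f to %.1f)", m, q1, q3)
}

#' @rdname format_median_iqr
#' @export
parse_median_iqr <- function(text) {
  mt <- regmatches(text,
                   regexec("^(-?[0-9.]+) \\((-?[0-9.]+) to (-?[0-9.]+)\\)$",
                           text))[[1]]
  if (length(mt) != 4) stop("cannot parse cell: ", text)
  stats::setNames(as.numeric(mt[2:4]), c("median", "q1", "q3"))
}

# Canonical extreme-position row labels (angles in degrees) per movement.
default_extremes <- function() {
  deg <- "\u00b0"
  out <- list(
    RUD = c(-25, 10), FE = c(60, -40), PS = c(50, -50)
  )
  names(out$RUD) <- paste0(c("25", "10"), deg,
                           c(" ulnar deviation", " radial deviation"))
  names(out$FE) <- paste0(c("60", "40"), deg, c(" extension", " flexion"))
  names(out$PS) <- paste0("50", deg, c(" supination", " pronation"))
  out
}

#' Cohort summary table in the standard layout
#'
#' Builds the movement-by-position table of the five reported quantities
#' (3-D ulnar variance, ulnocarpal proximities, 3-D epicentre, 3-D modified
#' radioulnar line): for each movement an extreme-position row per target
#' angle (taken from the nearest populated, unmasked angle bin) and a range
#' row (per-wrist max minus min, summarized as median/IQR across wrists).
#' Cells carry both machine-readable floats and the formatted
#' `"median (q1 to q3)"` string.
#'
#' @param cohorts Named list (names = movements) with elements `summary`
#'   (a [bin_by_angle()] cohort summary) and `series` (the list of
#'   per-wrist parameter series).
#' @param extremes Named list of target angles per movement; defaults to
#'   the canonical extreme positions.
#' @param path_csv,path_json Optional output paths.
#' @return A data frame with columns `movement`, `position`, and per
#'   parameter `<param>` (formatted string), `<param>_median`,
#'   `<param>_q1`, `<param>_q3`.
#' @export
write_summary_table <- function(cohorts, extremes = default_extremes(),
                                path_csv = NULL, path_json = NULL) {
  params <- c("uv3d_mm", "ucp_t_mm", "ucp_l_mm", "epi3d_pct", "mru3d_pct")
  rows <- list()
  for (mv in names(cohorts)) {
    summ <- cohorts[[mv]]$summary
    series <- cohorts[[mv]]$series
    bw <- attr(summ, "bin_width")
    for (lab in names(extremes[[mv]])) {
      target <- extremes[[mv]][[lab]]
      ok <- which(!summ$masked)
      row <- data.frame(movement = mv, position = lab)
      if (length(ok)) {
        d <- abs(summ$bin_center[ok] - target)
        near <- ok[which.min(d)]
        within <- min(d) <= bw
      } else {
        within <- FALSE
      }
      for (pcol in params) {
        if (within) {
          m <- summ[[paste0(pcol, "_median")]][near]
          q1 <- summ[[paste0(pcol, "_q1")]][near]
          q3 <- summ[[paste0(pcol, "_q3")]][near]
          row[[pcol]] <- format_median_iqr(m, q1, q3)
          row[[paste0(pcol, "_median")]] <- m
          row[[paste0(pcol, "_q1")]] <- q1
          row[[paste0(pcol, "_q3")]] <- q3
        } else {
          row[[pcol]] <- NA_character_
          row[[paste0(pcol, "_median")]] <- NA_real_
          row[[paste0(pcol, "_q1")]] <- NA_real_
          row[[paste0(pcol, "_q3")]] <- NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
    # range row: per-wrist motion range, pooled median/IQR
    row <- data.frame(movement = mv, position = "Range")
    for (pcol in params) {
      rng <- vapply(series, function(s) motion_range(s[[pcol]]), numeric(1))
      q <- stats::quantile(rng, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      row[[pcol]] <- format_median_iqr(q[2], q[1], q[3])
      row[[paste0(pcol, "_median")]] <- q[2]
      row[[paste0(pcol, "_q1")]] <- q[1]
      row[[paste0(pcol, "_q3")]] <- q[3]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(path_csv)) {
    utils::write.csv(out, path_csv, row.names = FALSE, eol = "\n")
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(out, path_json, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  out
}

#' Plot a parameter-versus-angle cohort curve
#'
#' Median curve with IQR ribbon against wrist angle; vertical dotted lines
#' mark the boundaries of the region where at least `min_count` wrists
#' contribute (bins outside are masked and not drawn).
#'
#' @param summary A [bin_by_angle()] cohort summary.
#' @param parameter Parameter column root, e.g. `"uv3d_mm"`.
#' @param movement Movement label for the x-axis title.
#' @param path Output file (`.png`, `.svg` or `.pdf`).
#' @param width,height Figure size in inches.
#' @return `path`, invisibly. The underlying ggplot object is attached as
#'   attribute `plot`.
#' @export
plot_parameter_curves <- function(summary, parameter, movement, path,
                                  width = 5, height = 3.5) {
  stopifnot(inherits(summary, "cohort_summary"))
  med <- paste0(parameter, "_median")
  if (!med %in% names(summary)) stop("unknown parameter: ", parameter)
  df <- data.frame(
    angle = summary$bin_center,
    median = summary[[med]],
    q1 = summary[[paste0(parameter, "_q1")]],
    q3 = summary[[paste0(parameter, "_q3")]],
    masked = summary$masked
  )
  shown <- df[!df$masked, , drop = FALSE]
  if (!nrow(shown)) stop("all bins are masked; nothing to plot")
  unit <- if (grepl("_mm$", parameter)) "mm" else "%"
  xlab <- switch(movement,
    FE = "Sagittal CR angle (\u00b0)",
    RUD = "Coronal CR angle (\u00b0)",
    PS = "Ulnoradial angle (\u00b0)")
  edges <- c(min(shown$angle), max(shown$angle))
  gp <- ggplot2::ggplot(shown, ggplot2::aes(x = angle)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = q1, ymax = q3),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = median), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = edges, linetype = "dotted") +
    ggplot2::labs(x = xlab,
                  y = sprintf("%s (%s)", sub("_(mm|pct)$", "", parameter),
                              unit)) +
    ggplot2::theme_classic()
  ext <- tolower(tools::file_ext(path))
  if (ext == "png" && !capabilities("png")) {
    path <- paste0(tools::file_path_sans_ext(path), ".svg")
    ext <- "svg"
  }
  dev_ok <- tryCatch({
    suppressMessages(ggplot2::ggsave(path, gp, width = width,
                                     height = height, dpi = 150))
    TRUE
  }, error = function(e) FALSE)
  if (!dev_ok) {
    # fall back to pdf if the requested graphics device is unavailable
    path <- paste0(tools::file_path_sans_ext(path), ".pdf")
    suppressMessages(ggplot2::ggsave(path, gp, width = width,
                                     height = height))
  }
  out <- invisible(path)
  attr(out, "plot") <- gp
  attr(out, "mask_edges") <- edges
  invisible(out)
}
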