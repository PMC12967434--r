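test_that("median (IQR) cells format to one decimal and round-trip", {
  expect_identical(format_median_iqr(-0.4, -1.5, 0.3), "-0.4 (-1.5 to 0.3)")
  for (x in list(c(-0.42, -1.54, 0.31), c(15.21, 11.6, 22.8))) {
    cell <- format_median_iqr(x[1], x[2], x[3])
    back <- parse_median_iqr(cell)
    expect_equal(unname(back), round(x, 1))
  }
  expect_error(parse_median_iqr("garbage"), "parse")
})

mk_series <- function(v, angles, jitter = 0) {
  vv <- v + jitter
  data.frame(wrist_angle_deg = angles, uv3d_mm = vv, ucp_l_mm = vv + 3,
             ucp_t_mm = vv + 7, mru3d_pct = vv * 10, epi3d_pct = vv * 5)
}

test_that("the summary table reports extreme positions from the nearest
           populated bin and ranges from motion_range", {
  angles <- seq(-25, 10, by = 5)
  series <- replicate(25, mk_series(-0.4, angles), simplify = FALSE)
  summ <- bin_by_angle(series, min_count = 22)
  tab <- write_summary_table(list(RUD = list(summary = summ,
                                             series = series)))
  row_ud <- tab[tab$position == "25° ulnar deviation", ]
  expect_identical(row_ud$uv3d_mm, "-0.4 (-0.4 to -0.4)")
  row_rng <- tab[tab$position == "Range", ]
  expect_identical(row_rng$uv3d_mm_median, 0) # constant trajectories
  # a wrist with known range drives the range row
  series2 <- replicate(25, mk_series(0, angles), simplify = FALSE)
  series2[[1]]$uv3d_mm <- seq(-0.4, 0.7, length.out = length(angles))
  tab2 <- write_summary_table(list(RUD = list(
    summary = bin_by_angle(series2, min_count = 22), series = series2)))
  rng <- vapply(series2, function(s) motion_range(s$uv3d_mm), numeric(1))
  expect_equal(tab2[tab2$position == "Range", "uv3d_mm_median"],
               median(rng))
  # positions with no populated bin are marked missing
  fe_series <- replicate(25, mk_series(1, seq(-10, 10, 5)), simplify = FALSE)
  tab3 <- write_summary_table(list(FE = list(
    summary = bin_by_angle(fe_series, min_count = 22), series = fe_series)))
  expect_true(is.na(tab3[tab3$position == "60° extension", "uv3d_mm"]))
})

test_that("summary files are written deterministically", {
  angles <- seq(-25, 10, by = 5)
  series <- replicate(23, mk_series(-0.4, angles), simplify = FALSE)
  summ <- bin_by_angle(series, min_count = 22)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_summary_table(list(RUD = list(summary = summ, series = series)),
                      path_csv = p1, path_json = pj)
  write_summary_table(list(RUD = list(summary = summ, series = series)),
                      path_csv = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_gt(file.size(pj), 0)
  parsed <- jsonlite::read_json(pj)
  expect_equal(length(parsed), nrow(write_summary_table(
    list(RUD = list(summary = summ, series = series)))))
})

test_that("cohort curve plots are written for every parameter and movement
           with mask edges matching the binning", {
  set.seed(21)
  angles_by_mv <- list(FE = seq(-40, 60, 5), RUD = seq(-25, 10, 5),
                       PS = seq(-50, 50, 10))
  dir <- withr::local_tempdir()
  for (mv in names(angles_by_mv)) {
    series <- replicate(25, mk_series(rnorm(1, 0, 0.3),
                                      angles_by_mv[[mv]]),
                        simplify = FALSE)
    summ <- bin_by_angle(series, min_count = 22)
    for (par in c("uv3d_mm", "ucp_l_mm", "ucp_t_mm", "mru3d_pct",
                  "epi3d_pct")) {
      f <- plot_parameter_curves(summ, par, mv,
                                 file.path(dir, paste0(mv, "_", par,
                                                       ".png")))
      expect_true(file.exists(as.character(f)))
      expect_gt(file.size(as.character(f)), 0)
      shown <- summ$bin_center[!summ$masked]
      expect_equal(attr(f, "mask_edges"), range(shown))
    }
  }
  # monotone input produces a monotone plotted median (data check)
  angles <- seq(-25, 10, by = 5)
  mono <- lapply(1:25, function(i) {
    mk_series(seq(0, 1, length.out = length(angles)), angles,
              jitter = rnorm(length(angles), 0, 1e-6))
  })
  summ <- bin_by_angle(mono, min_count = 22)
  f <- plot_parameter_curves(summ, "uv3d_mm", "RUD",
                             file.path(dir, "mono.png"))
  med <- summ$uv3d_mm_median[!summ$masked]
  expect_true(all(diff(med) > 0))
  expect_error(plot_parameter_curves(bin_by_angle(list(mk_series(1, angles)),
                                                  min_count = 22),
                                     "uv3d_mm", "RUD",
                                     file.path(dir, "x.png")),
               "masked")
})
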