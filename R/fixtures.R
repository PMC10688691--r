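#' Embedded reliability data sets
#'
#' Two classical paired strength/stress data sets, stored verbatim as
#' analysed in the PFFC stress-strength literature, each with its four
#' progressively first-failure censored sub-samples and their schemes.
#'
#' \describe{
#'   \item{`"jute"`}{Breaking strengths of jute fibre at gauge lengths
#'     15 mm (strength, `x`) and 20 mm (stress, `y`), 30 observations
#'     each (original strengths divided by 10). Grouped into n = 15
#'     groups of k = 2; four censoring schemes with m = 10 (schemes 1-3)
#'     and the uncensored m = n = 15 (scheme 4).}
#'   \item{`"insulation"`}{Failure times (seconds, scaled by 10) of two
#'     electrical-insulation types under continuously increasing voltage
#'     stress, 30 observations each. Grouped into n = 10 groups of
#'     k = 3; schemes 1-3 have m = 8, scheme 4 is the uncensored
#'     first-failure sample with m = n = 10.}
#' }
#'
#' Note: the published sub-samples contain small internal
#' inconsistencies with the published first-failure lists (values appear
#' in sub-samples that are absent from the lists); they are stored here
#' exactly as printed, without correction.
#'
#' @param name `"jute"` or `"insulation"`.
#' @return a list with elements `name`, `x`, `y` (the full 30-value
#'   samples), `first_failure` (list with `x`, `y` first-failure lists),
#'   and `schemes` — a list of four entries, each containing `scheme`
#'   (a [censoring_scheme()]) and `x`, `y` (`"pffc_sample"` objects).
#' @examples
#' jute <- pffc_dataset("jute")
#' ml_ssr(jute$schemes[[1]]$x, jute$schemes[[1]]$y)
#' @export
pffc_dataset <- function(name) {
  data <- ssripd_fixtures()
  if (!is.character(name) || length(name) != 1L || !name %in% names(data))
    stop("unknown data set; available: ",
         paste(names(data), collapse = ", "), call. = FALSE)
  data[[name]]
}

ssripd_fixtures <- function() {
  jute_x <- c(59.440, 20.275, 16.837, 57.486, 22.565, 7.638, 15.667, 12.781,
              81.387, 56.239, 46.847, 13.509, 7.224, 49.794, 35.556, 56.907,
              64.048, 20.042, 55.042, 74.875, 48.966, 67.806, 45.771, 10.673,
              71.630, 4.266, 8.040, 33.922, 7.009, 19.342)
  jute_y <- c(7.146, 41.902, 28.464, 58.557, 45.660, 11.385, 18.785, 68.816,
              66.266, 4.558, 57.862, 75.670, 59.429, 16.649, 9.972, 70.736,
              76.514, 18.713, 14.596, 35.070, 54.744, 11.699, 37.581, 58.160,
              11.986, 4.801, 20.016, 3.675, 24.453, 8.355)
  jute_ff_x <- c(4.266, 7.009, 7.224, 8.040, 10.673, 13.509, 15.667, 16.837,
                 19.342, 20.042, 20.275, 45.771, 46.847, 49.794, 56.239)
  jute_ff_y <- c(3.675, 4.558, 4.801, 8.355, 9.972, 11.699, 14.596, 18.713,
                 18.785, 20.016, 24.453, 28.464, 37.581, 54.744, 59.429)
  jg <- list(censoring_scheme(c(5, rep(0, 9)), k = 2),
             censoring_scheme(c(1, 0, 0, 1, 0, 0, 2, 0, 0, 1), k = 2),
             censoring_scheme(c(rep(0, 9), 5), k = 2),
             censoring_scheme(rep(0, 15), k = 2))
  jx <- list(c(4.266, 12.781, 13.509, 16.837, 19.342, 20.042, 22.565, 46.847,
               57.486, 71.630),
             c(4.266, 7.224, 7.638, 8.040, 12.781, 13.509, 16.837, 22.565,
               46.847, 48.966),
             c(4.266, 7.009, 7.224, 7.638, 8.040, 12.781, 13.509, 16.837,
               19.342, 20.275),
             c(4.266, 7.009, 7.224, 7.638, 8.040, 10.673, 12.781, 13.509,
               15.667, 19.342, 20.042, 22.565, 46.847, 49.794, 64.048))
  jy <- list(c(3.675, 11.385, 11.699, 11.986, 16.649, 24.453, 28.464, 45.660,
               58.160, 59.429),
             c(3.675, 4.801, 7.146, 8.355, 11.385, 11.986, 14.596, 24.453,
               28.464, 37.581),
             c(3.675, 4.558, 4.801, 7.146, 9.972, 11.385, 11.699, 11.986,
               16.649, 20.016),
             c(3.675, 4.558, 4.801, 8.355, 9.972, 11.385, 11.986, 16.649,
               18.713, 18.785, 24.453, 35.070, 41.902, 57.862, 66.266))

  ins_x <- c(0.97, 0.14, 0.30, 1.34, 2.40, 0.84, 1.46, 0.24, 0.45, 0.04,
             0.99, 2.77, 4.72, 0.94, 0.23, 1.46, 0.30, 0.31, 1.04, 1.05,
             0.36, 0.65, 0.22, 0.98, 1.78, 0.59, 0.14, 0.07, 0.07, 2.86)
  ins_y <- c(1.99, 2.52, 1.03, 4.55, 1.35, 3.48, 3.21, 1.66, 0.40, 0.27,
             5.19, 2.70, 0.08, 0.30, 0.84, 2.36, 3.15, 1.77, 2.68, 1.80,
             7.96, 2.45, 7.03, 0.45, 0.17, 8.21, 9.42, 3.14, 2.81, 6.52)
  ig <- list(censoring_scheme(c(2, rep(0, 7)), k = 3),
             censoring_scheme(c(1, rep(0, 6), 1), k = 3),
             censoring_scheme(c(rep(0, 7), 2), k = 3),
             censoring_scheme(rep(0, 10), k = 3))
  ix <- list(c(0.04, 0.22, 0.23, 0.30, 0.30, 0.36, 0.59, 0.65),
             c(0.04, 0.14, 0.22, 0.23, 0.24, 0.31, 0.45, 0.97),
             c(0.04, 0.07, 0.07, 0.14, 0.14, 0.23, 0.31, 0.45),
             c(0.04, 0.07, 0.07, 0.14, 0.14, 0.22, 0.23, 0.24, 0.30, 0.45))
  iy <- list(c(0.08, 0.30, 0.40, 0.45, 0.84, 1.03, 2.68, 3.15),
             c(0.08, 0.27, 0.40, 0.84, 1.03, 1.35, 1.66, 2.68),
             c(0.08, 0.17, 0.27, 0.30, 0.84, 1.03, 1.66, 1.80),
             c(0.08, 0.17, 0.27, 0.30, 0.40, 0.45, 1.35, 2.36, 2.52, 2.68))

  build <- function(name, x, y, ffx, ffy, schemes, xs, ys) {
    list(name = name, x = x, y = y,
         first_failure = list(x = ffx, y = ffy),
         schemes = lapply(seq_along(schemes), function(i)
           list(scheme = schemes[[i]],
                x = pffc_sample(xs[[i]], schemes[[i]]),
                y = pffc_sample(ys[[i]], schemes[[i]]))))
  }
  # insulation first-failure lists: the uncensored scheme-4 sub-samples
  # (zero removals, m = n) are by construction the first-failure samples
  list(jute = build("jute", jute_x, jute_y, jute_ff_x, jute_ff_y, jg, jx, jy),
       insulation = build("insulation", ins_x, ins_y, ix[[4]], iy[[4]],
                          ig, ix, iy))
}
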